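#' Parse a mixed-model formula into fixed terms and random-effect blocks
#'
#' The grammar follows the familiar mixed-model syntax: a response, fixed
#' terms (intercept implicit, `:` interactions allowed) and parenthesized
#' random-effect blocks `(terms | group)`. The grouping is either a single
#' factor `g`, an interaction `g1:g2`, or the nested shorthand `g1/g2`, which
#' expands to two blocks — one grouped by `g1` and one by `g1:g2` — each
#' carrying the block's full term list. A leading `0 +` or `-1` inside a block
#' suppresses that block's random intercept.
#'
#' @param formula A formula or a string containing exactly one `~`, e.g.
#'   `"photometry ~ IRI + (lick_latency | id/session)"`.
#' @return An object of class `flmm_formula`: a list with `response`,
#'   `fixed_terms` (term labels, intercept implicit and not listed) and
#'   `blocks`, each block a list with `terms`, `intercept` and `grouping`.
#' @export
#' @examples
#' spec <- parse_formula("photometry ~ IRI + (lick_latency | id/session)")
#' spec
#' format(spec)
parse_formula <- function(formula) {
  if (is.character(formula)) {
    if (length(formula) != 1L) abort("parse_formula: need a single string")
    if (lengths(regmatches(formula, gregexpr("~", formula, fixed = TRUE))) != 1L) {
      abort("parse_formula: formula must contain exactly one '~'")
    }
    f <- tryCatch(as.formula(formula),
                  error = function(e) {
                    abort(paste0("parse_formula: cannot parse formula: ",
                                 conditionMessage(e)))
                  })
  } else if (inherits(formula, "formula")) {
    f <- formula
  } else {
    abort("parse_formula: formula must be a string or a formula")
  }
  if (length(f) != 3L) abort("parse_formula: formula must have a response")
  response <- deparse1(f[[2]])
  if (!grepl("^[^ ~()|+]+$", response)) {
    abort(paste0("parse_formula: invalid response '", response, "'"))
  }

  parts <- split_plus(f[[3]])
  bar_exprs <- list()
  fixed_exprs <- list()
  for (p in parts) {
    if (is.call(p) && identical(p[[1]], as.name("(")) && length(p) == 2L &&
        is.call(p[[2]]) && identical(p[[2]][[1]], as.name("|"))) {
      bar_exprs <- c(bar_exprs, list(p[[2]]))
    } else if (is.call(p) && identical(p[[1]], as.name("|"))) {
      bar_exprs <- c(bar_exprs, list(p))
    } else if (is.call(p) && (identical(p[[1]], as.name("||")))) {
      abort("parse_formula: uncorrelated random blocks '||' are not supported")
    } else if (is.call(p) && identical(p[[1]], as.name("(")) && length(p) == 2L &&
               is.call(p[[2]]) && identical(p[[2]][[1]], as.name("||"))) {
      abort("parse_formula: uncorrelated random blocks '||' are not supported")
    } else {
      fixed_exprs <- c(fixed_exprs, list(p))
    }
  }

  fixed <- parse_term_list(fixed_exprs, context = "fixed part")
  if (!fixed$intercept && length(fixed$terms) == 0L) {
    abort("parse_formula: empty fixed part (only the intercept was removed)")
  }
  if (!fixed$intercept) {
    abort("parse_formula: suppressing the fixed intercept ('0 +') is not supported")
  }

  blocks <- list()
  for (b in bar_exprs) {
    lhs <- b[[2]]
    rhs <- b[[3]]
    term_part <- parse_term_list(split_plus(lhs), context = "random block")
    groupings <- parse_grouping(rhs)
    for (g in groupings) {
      blocks <- c(blocks, list(list(
        terms = term_part$terms,
        intercept = term_part$intercept,
        grouping = g
      )))
    }
  }
  for (blk in blocks) {
    if (!blk$intercept && length(blk$terms) == 0L) {
      abort("parse_formula: random block has no terms and no intercept")
    }
  }

  structure(
    list(response = response, fixed_terms = fixed$terms, blocks = blocks),
    class = "flmm_formula"
  )
}

# split a formula RHS expression on top-level `+` / `-` (keeping `- 1` marks)
split_plus <- function(e) {
  if (is.call(e) && identical(e[[1]], as.name("+")) && length(e) == 3L) {
    c(split_plus(e[[2]]), split_plus(e[[3]]))
  } else if (is.call(e) && identical(e[[1]], as.name("-")) && length(e) == 3L) {
    c(split_plus(e[[2]]), list(call("-", e[[3]])))
  } else {
    list(e)
  }
}

# classify a list of term expressions into intercept flag + term labels
parse_term_list <- function(exprs, context) {
  intercept <- TRUE
  terms <- character()
  for (e in exprs) {
    if (is.numeric(e) && length(e) == 1L) {
      if (e == 1) next
      if (e == 0) { intercept <- FALSE; next }
      abort(paste0("parse_formula: unexpected numeric term '", e,
                   "' in ", context))
    }
    if (is.call(e) && identical(e[[1]], as.name("-"))) {
      inner <- e[[2]]
      if (is.numeric(inner) && inner == 1) { intercept <- FALSE; next }
      abort(paste0("parse_formula: unsupported '-' term '", deparse1(e),
                   "' in ", context))
    }
    if (is.name(e)) {
      terms <- c(terms, as.character(e))
      next
    }
    if (is.call(e) && identical(e[[1]], as.name(":"))) {
      terms <- c(terms, deparse1(e))
      next
    }
    abort(paste0("parse_formula: unsupported term '", deparse1(e),
                 "' in ", context))
  }
  list(intercept = intercept, terms = unique(terms))
}

# grouping factor expression: g, g1:g2, or nested g1/g2 (expands to 2 blocks)
parse_grouping <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e) && identical(e[[1]], as.name(":")) &&
      is.name(e[[2]]) && is.name(e[[3]])) {
    return(paste0(as.character(e[[2]]), ":", as.character(e[[3]])))
  }
  if (is.call(e) && identical(e[[1]], as.name("/")) &&
      is.name(e[[2]]) && is.name(e[[3]])) {
    g1 <- as.character(e[[2]])
    g2 <- as.character(e[[3]])
    return(c(g1, paste0(g1, ":", g2)))
  }
  abort(paste0("parse_formula: unknown grouping syntax '", deparse1(e), "'"))
}

#' @export
format.flmm_formula <- function(x, ...) {
  fixed <- paste(c("1", x$fixed_terms), collapse = " + ")
  blocks <- vapply(x$blocks, function(b) {
    lhs <- paste(c(if (b$intercept) "1" else "0", b$terms), collapse = " + ")
    paste0("(", lhs, " | ", b$grouping, ")")
  }, character(1))
  paste(x$response, "~", paste(c(fixed, blocks), collapse = " + "))
}

#' @export
print.flmm_formula <- function(x, ...) {
  cat("<flmm_formula> ", format(x), "\n", sep = "")
  cat("  fixed terms: ", paste(c("(Intercept)", x$fixed_terms), collapse = ", "),
      "\n", sep = "")
  for (b in x$blocks) {
    cat("  random block: {", paste(c(if (b$intercept) "1", b$terms),
                                   collapse = ", "),
        "} grouped by ", b$grouping, "\n", sep = "")
  }
  invisible(x)
}

# all covariate columns a spec references (fixed, random terms, grouping)
spec_columns <- function(spec) {
  split_cols <- function(x) unlist(strsplit(x, ":", fixed = TRUE))
  unique(c(
    spec$response,
    split_cols(spec$fixed_terms),
    unlist(lapply(spec$blocks, function(b) c(split_cols(b$terms),
                                             split_cols(b$grouping))))
  ))
}

# lme4-style formula string for the pointwise fits, response rebound to `.y`
lmer_formula <- function(spec) {
  fixed <- paste(c("1", spec$fixed_terms), collapse = " + ")
  blocks <- vapply(spec$blocks, function(b) {
    lhs <- paste(c(if (b$intercept) "1" else "0", b$terms), collapse = " + ")
    paste0("(", lhs, " | ", b$grouping, ")")
  }, character(1))
  as.formula(paste(".y ~", paste(c(fixed, blocks), collapse = " + ")))
}

#' Build fixed- and random-effect design matrices from a parsed formula
#'
#' Categorical covariates are expanded to treatment-coded indicators with the
#' lexicographically first level as reference. Continuous covariates (numeric
#' with more than two distinct values) are optionally mean-centered.
#'
#' @param spec An [parse_formula()] result.
#' @param data A data frame of trial covariates (one row per trial).
#' @param center Mean-center continuous covariates (default `TRUE`).
#' @return A list with `X` (N x p fixed design), `blocks` (per random block:
#'   `Z` N x q design, `group` factor, `grouping` label, `colnames`), the
#'   applied `centers`, and the centered data frame `data`.
#' @export
build_design <- function(spec, data, center = TRUE) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(spec_columns(spec), c(names(data), spec$response))
  if (length(missing_cols)) {
    abort(paste0("build_design: columns not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (nm in names(data)) {
    if (is.character(data[[nm]]) || is.logical(data[[nm]])) {
      data[[nm]] <- as_sorted_factor(data[[nm]])
    } else if (is.factor(data[[nm]])) {
      data[[nm]] <- as_sorted_factor(data[[nm]])
    }
  }
  centers <- numeric(0)
  if (center) {
    cont <- vapply(data, function(v) {
      is.numeric(v) && length(unique(v[is.finite(v)])) > 2L
    }, logical(1))
    for (nm in names(data)[cont]) {
      centers[nm] <- mean(data[[nm]])
      data[[nm]] <- data[[nm]] - centers[nm]
    }
  }

  X <- model.matrix(reformulate(c("1", spec$fixed_terms)), data)
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    abort(paste0("build_design: fixed design is rank deficient; aliased ",
                 "column(s): ", paste(aliased, collapse = ", ")))
  }

  blocks <- lapply(spec$blocks, function(b) {
    Zb <- model.matrix(
      reformulate(c(if (b$intercept) "1" else "0", b$terms),
                  intercept = b$intercept), data)
    gvars <- strsplit(b$grouping, ":", fixed = TRUE)[[1]]
    grp <- if (length(gvars) == 1L) as_sorted_factor(data[[gvars]])
           else droplevels(interaction(data[gvars], sep = ":", lex.order = TRUE))
    list(Z = Zb, group = grp, grouping = b$grouping, colnames = colnames(Zb))
  })

  list(X = X, blocks = blocks, centers = centers, data = data)
}
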