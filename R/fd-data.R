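#' Construct a functional dataset of trial-aligned signals
#'
#' An `fd_data` object is a tibble with one row per trial: a subject
#' identifier, optionally a session identifier, scalar trial covariates, and
#' `S` signal columns sampled on a common, evenly spaced within-trial time
#' grid. It is the input container for [fit_flmm()] and all comparator
#' analyses.
#'
#' @param data A data frame with one row per trial.
#' @param signal_cols Character vector naming the `S` signal columns, in time
#'   order.
#' @param time_grid Numeric vector of length `S`: within-trial sample times in
#'   seconds, strictly increasing and evenly spaced. Defaults to an index grid
#'   `0, 1, ..., S-1`.
#' @param subject Name of the subject identifier column (default `"id"`).
#' @param session Optional name of the session identifier column. Each session
#'   level must belong to exactly one subject.
#'
#' @return A tibble of class `fd_data` carrying the signal matrix, covariates
#'   and grouping metadata as attributes.
#' @export
#' @examples
#' df <- data.frame(id = c("a", "a", "b", "b"), x = c(0, 1, 0, 1),
#'                  y_1 = rnorm(4), y_2 = rnorm(4), y_3 = rnorm(4))
#' fd <- fd_data(df, signal_cols = c("y_1", "y_2", "y_3"),
#'               time_grid = c(0, 0.5, 1))
#' signal_matrix(fd)
fd_data <- function(data, signal_cols, time_grid = NULL, subject = "id",
                    session = NULL) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(signal_cols, subject, session), names(data))
  if (length(missing_cols)) {
    abort(paste0("fd_data: columns not found: ",
                 paste(missing_cols, collapse = ", ")))
  }
  S <- length(signal_cols)
  if (S < 1L) abort("fd_data: need at least one signal column")
  if (is.null(time_grid)) time_grid <- seq_len(S) - 1
  if (length(time_grid) != S) {
    abort("fd_data: time_grid length must equal the number of signal columns")
  }
  if (S > 1L) {
    dt <- diff(time_grid)
    if (any(dt <= 0)) abort("fd_data: time_grid must be strictly increasing")
    if (diff(range(dt)) > 1e-8 * max(dt)) {
      abort("fd_data: time_grid must be evenly spaced")
    }
  }

  sig <- as.matrix(data[signal_cols])
  if (!is.numeric(sig)) {
    bad <- signal_cols[!vapply(data[signal_cols], is.numeric, logical(1))]
    abort(paste0("fd_data: non-numeric signal columns: ",
                 paste(bad, collapse = ", ")))
  }
  bad_rows <- which(rowSums(!is.finite(sig)) > 0)
  if (length(bad_rows)) {
    abort(paste0("fd_data: missing or non-finite signal values in trial row(s) ",
                 paste(head(bad_rows, 10), collapse = ", ")))
  }

  if (anyNA(data[[subject]])) abort("fd_data: subject column contains NA")
  data[[subject]] <- as_sorted_factor(data[[subject]])

  if (!is.null(session)) {
    if (anyNA(data[[session]])) abort("fd_data: session column contains NA")
    data[[session]] <- as_sorted_factor(data[[session]])
    n_subj_per_sess <- tapply(data[[subject]], data[[session]],
                              function(x) length(unique(x)))
    bad_sess <- names(n_subj_per_sess)[n_subj_per_sess > 1]
    if (length(bad_sess)) {
      abort(paste0("fd_data: session level(s) mapped to more than one subject: ",
                   paste(bad_sess, collapse = ", ")))
    }
  }

  structure(
    data,
    class = c("fd_data", class(data)),
    signal_cols = signal_cols,
    time_grid = as.numeric(time_grid),
    subject_col = subject,
    session_col = session
  )
}

as_sorted_factor <- function(x) {
  if (is.factor(x)) factor(x, levels = sort(levels(x)))
  else factor(x, levels = sort(unique(as.character(x))))
}

#' @export
print.fd_data <- function(x, ...) {
  tg <- time_grid(x)
  cat(sprintf(
    "<fd_data> %d trials x %d time-points (%.3g to %.3g s), %d subject(s)%s\n",
    nrow(x), length(tg), tg[1], tg[length(tg)],
    nlevels(x[[attr(x, "subject_col")]]),
    if (!is.null(attr(x, "session_col"))) {
      sprintf(", %d session(s)", nlevels(x[[attr(x, "session_col")]]))
    } else ""
  ))
  NextMethod()
}

#' Accessors for `fd_data` components
#'
#' @param x An [fd_data()] object.
#' @return `signal_matrix()` returns the trials-by-timepoints numeric matrix;
#'   `time_grid()` the within-trial sample times; `fd_covariates()` the
#'   covariate tibble (everything except signal and grouping columns);
#'   `fd_subject()` and `fd_session()` the grouping factors (`fd_session()` is
#'   `NULL` when absent).
#' @export
signal_matrix <- function(x) {
  stopifnot(inherits(x, "fd_data"))
  as.matrix(tibble::as_tibble(x)[attr(x, "signal_cols")])
}

#' @rdname signal_matrix
#' @export
time_grid <- function(x) attr(x, "time_grid")

#' @rdname signal_matrix
#' @export
fd_covariates <- function(x) {
  stopifnot(inherits(x, "fd_data"))
  drop <- c(attr(x, "signal_cols"), attr(x, "subject_col"),
            attr(x, "session_col"))
  tibble::as_tibble(x)[setdiff(names(x), drop)]
}

#' @rdname signal_matrix
#' @export
fd_subject <- function(x) x[[attr(x, "subject_col")]]

#' @rdname signal_matrix
#' @export
fd_session <- function(x) {
  sc <- attr(x, "session_col")
  if (is.null(sc)) NULL else x[[sc]]
}

#' Read a functional dataset from a long-format CSV
#'
#' One row per trial; signal columns are identified either by an explicit
#' `signal_cols` vector or by a common `signal_prefix` followed by an integer
#' index (`y_1, y_2, ...`), ordered by that index. Trials with missing signal
#' samples are rejected (whole trials may simply be absent from the file).
#'
#' @inheritParams fd_data
#' @param path Path to a CSV file.
#' @param signal_prefix Prefix identifying signal columns (default `"y_"`).
#' @param signal_cols Optional explicit signal column names (overrides the
#'   prefix).
#' @return An [fd_data()] object.
#' @export
read_fd_csv <- function(path, signal_prefix = "y_", signal_cols = NULL,
                        time_grid = NULL, subject = "id", session = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(signal_cols)) {
    pat <- paste0("^", signal_prefix, "([0-9]+)$")
    hits <- grep(pat, names(df), value = TRUE)
    if (!length(hits)) {
      abort(paste0("read_fd_csv: no columns match prefix '", signal_prefix, "'"))
    }
    idx <- as.integer(sub(pat, "\\1", hits))
    signal_cols <- hits[order(idx)]
  }
  if ("session" %in% names(df) && is.null(session)) session <- "session"
  fd_data(df, signal_cols = signal_cols, time_grid = time_grid,
          subject = subject, session = session)
}

#' Write a functional dataset to CSV
#'
#' Inverse of [read_fd_csv()]: writes one row per trial with subject, optional
#' session, covariates and the signal columns. The time grid is not stored in
#' the CSV; pass it back to [read_fd_csv()] when re-reading.
#'
#' @param x An [fd_data()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fd_csv <- function(x, path) {
  stopifnot(inherits(x, "fd_data"))
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
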