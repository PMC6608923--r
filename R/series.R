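#' Observed multivariate log-count series
#'
#' Container for a `T x C` matrix of natural-log monthly counts with
#' calendar month labels.  Months must be strictly increasing and
#' consecutive; `NA` rows/entries mark missing observations (skipped in the
#' Kalman measurement update).
#'
#' @param log_counts `T x C` numeric matrix of log counts (NA = missing).
#' @param months length-`T` character vector of `"YYYY-MM"` labels, or
#'   `Date`s (coerced to first-of-month labels).  Defaults to consecutive
#'   months starting at `start`.
#' @param series_names length-`C` character vector of series labels.
#' @param start first month label used when `months` is `NULL`.
#' @return an object of class `sutse_series`.
#' @export
observed_series <- function(log_counts, months = NULL, series_names = NULL,
                            start = "2007-01") {
  log_counts <- as.matrix(log_counts)
  T_ <- nrow(log_counts); C <- ncol(log_counts)
  if (T_ < 2) stop("need at least 2 time points")
  if (any(!is.finite(log_counts) & !is.na(log_counts)))
    stop("log_counts entries must be finite or NA")
  if (is.null(months)) {
    months <- month_seq(start, T_)
  } else {
    if (inherits(months, "Date")) months <- format(months, "%Y-%m")
    months <- as.character(months)
    if (length(months) != T_) stop("months must have length nrow(log_counts)")
    idx <- month_index(months)
    if (any(diff(idx) != 1L))
      stop("months must be strictly increasing and consecutive")
  }
  if (is.null(series_names)) {
    series_names <- colnames(log_counts)
    if (is.null(series_names)) series_names <- paste0("series_", seq_len(C))
  }
  if (length(series_names) != C) stop("series_names must have length ncol(log_counts)")
  colnames(log_counts) <- series_names
  rownames(log_counts) <- months
  structure(list(log_counts = log_counts, months = months,
                 series_names = series_names),
            class = "sutse_series")
}

# integer month number (years * 12 + month) from "YYYY-MM" labels
month_index <- function(months) {
  ok <- grepl("^\\d{4}-\\d{2}$", months)
  if (!all(ok))
    stop("month labels must be 'YYYY-MM'; offending: ",
         paste(utils::head(months[!ok], 3), collapse = ", "))
  y <- as.integer(substr(months, 1, 4))
  m <- as.integer(substr(months, 6, 7))
  if (any(m < 1 | m > 12)) stop("month number out of 1..12")
  y * 12L + (m - 1L)
}

month_seq <- function(start, n) {
  i0 <- month_index(start)
  idx <- i0 + seq_len(n) - 1L
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

#' @export
print.sutse_series <- function(x, ...) {
  cat(sprintf("sutse_series: %d months (%s .. %s) x %d series\n",
              nrow(x$log_counts), x$months[1], x$months[length(x$months)],
              ncol(x$log_counts)))
  invisible(x)
}
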