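#' Aggregate incident-level records to monthly counts
#'
#' Counts rows per (calendar month, category), restricted to a date range;
#' months inside the range with no incidents are emitted explicitly with
#' count 0.  Month boundaries follow the calendar date as written (no
#' timezone arithmetic); duplicate records count as given.
#'
#' @param incidents path to a CSV file, or a data frame, of incident-level
#'   records.
#' @param date_column name of the date column (parseable by [as.Date()],
#'   or `"YYYY-MM-DD..."` strings).
#' @param category_column name of the category column.
#' @param categories character vector of categories to keep (column order of
#'   the result).
#' @param date_range length-2 vector of `"YYYY-MM"` month labels (first and
#'   last month, inclusive); default spans the observed months.
#' @return a data frame with columns `month` (`"YYYY-MM"`), `series`, and
#'   `count`, one row per (month, series).
#' @export
aggregate_incidents <- function(incidents, date_column, category_column,
                                categories, date_range = NULL) {
  df <- if (is.character(incidents))
    utils::read.csv(incidents, stringsAsFactors = FALSE) else as.data.frame(incidents)
  if (!date_column %in% names(df)) stop("no column named ", date_column)
  if (!category_column %in% names(df)) stop("no column named ", category_column)
  if (length(categories) == 0) stop("categories must be non-empty")
  dates <- as.Date(substr(as.character(df[[date_column]]), 1, 10))
  if (anyNA(dates))
    stop("unparseable dates at rows: ",
         paste(utils::head(which(is.na(dates)), 10), collapse = ", "))
  cat_col <- as.character(df[[category_column]])
  unknown <- setdiff(categories, unique(cat_col))
  if (length(unknown) > 0)
    warning("categories not present in the data: ",
            paste(unknown, collapse = ", "))
  month <- format(dates, "%Y-%m")
  if (is.null(date_range)) date_range <- range(month)
  lo <- month_index(date_range[1]); hi <- month_index(date_range[2])
  keep <- month_index(month) >= lo & month_index(month) <= hi &
    cat_col %in% categories
  all_months <- month_seq(date_range[1], hi - lo + 1L)
  tab <- table(factor(month[keep], levels = all_months),
               factor(cat_col[keep], levels = categories))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("month", "series", "count")
  out <- out[order(match(out$series, categories), out$month), ]
  rownames(out) <- NULL
  out
}

#' Load a monthly-counts CSV as an observed log-count series
#'
#' The file must have columns `month` (`"YYYY-MM"`), `series`, `count`,
#' one row per (month, series), with consecutive months per series and all
#' counts >= 1 (the natural log is applied; a zero count has no log and
#' aborts with an explicit message rather than being offset silently).
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @param allow_missing treat absent (month, series) rows as missing
#'   observations (`NA`) instead of erroring on gaps.
#' @return a [observed_series()] object, series in file order.
#' @export
load_monthly_counts <- function(path, allow_missing = FALSE) {
  df <- if (is.character(path))
    utils::read.csv(path, stringsAsFactors = FALSE) else as.data.frame(path)
  need <- c("month", "series", "count")
  if (!all(need %in% names(df)))
    stop("monthly counts need columns: ", paste(need, collapse = ", "))
  series_names <- unique(df$series)
  months <- sort(unique(df$month))
  idx <- month_index(months)
  if (any(diff(idx) != 1L) && !allow_missing)
    stop("months are not consecutive; re-run with allow_missing = TRUE ",
         "to treat gaps as missing observations")
  all_months <- month_seq(months[1], idx[length(idx)] - idx[1] + 1L)
  y <- matrix(NA_real_, length(all_months), length(series_names),
              dimnames = list(all_months, series_names))
  key <- paste(df$month, df$series)
  if (anyDuplicated(key))
    stop("duplicate (month, series) rows: ", key[anyDuplicated(key)])
  cnt <- as.numeric(df$count)
  if (any(!is.finite(cnt)) || any(cnt != round(cnt)) || any(cnt < 0))
    stop("counts must be non-negative integers")
  if (any(cnt == 0))
    stop("zero counts cannot be log-transformed; aggregate to a coarser ",
         "period or drop the affected series")
  y[cbind(match(df$month, all_months), match(df$series, series_names))] <- log(cnt)
  complete <- stats::complete.cases(y)
  if (!all(complete) && !allow_missing)
    stop("series do not cover the same months (ragged panel); re-run with ",
         "allow_missing = TRUE to treat gaps as missing")
  observed_series(y, months = all_months, series_names = series_names)
}

#' Write monthly counts in the standard long CSV schema
#'
#' @param counts a `T x C` count matrix with month rownames and series
#'   colnames (e.g. `simulate_sutse()$counts`), or a long data frame with
#'   `month`, `series`, `count`.
#' @param path output CSV path.
#' @param months,series_names labels used when `counts` is an unlabeled
#'   matrix.
#' @return `path`, invisibly.
#' @export
write_monthly_counts <- function(counts, path, months = NULL,
                                 series_names = NULL) {
  if (is.data.frame(counts) && all(c("month", "series", "count") %in% names(counts))) {
    long <- counts[, c("month", "series", "count")]
  } else {
    x <- as.matrix(counts)
    if (is.null(months)) months <- rownames(x)
    if (is.null(series_names)) series_names <- colnames(x)
    if (is.null(months) || is.null(series_names))
      stop("matrix input needs month rownames and series colnames (or explicit labels)")
    long <- data.frame(month = rep(months, times = ncol(x)),
                       series = rep(series_names, each = nrow(x)),
                       count = as.vector(x))
  }
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run-metadata JSON sidecar
#'
#' Records configuration, seeds, package version, and the model dimensions
#' next to any output table so a run can be reproduced.
#'
#' @param path output JSON path.
#' @param ... named metadata entries (coerced by [jsonlite::toJSON()]).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, ...) {
  meta <- list(package = "sutse",
               version = as.character(utils::packageVersion("sutse")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               ...)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", digits = NA), path)
  invisible(path)
}
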