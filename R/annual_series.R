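#' Annual time series container
#'
#' An `annual_series` is a numeric vector of strictly positive observations
#' recorded at consecutive calendar years (step 1). It is the entry point of
#' every grey modelling routine in the package. Unless stated otherwise,
#' values are in units of 10^4 persons, matching the bundled Shanghai panel.
#'
#' @param values numeric vector of observations, length >= 4 and strictly
#'   positive for grey modelling (shorter or non-positive vectors are refused
#'   unless `validate = FALSE`).
#' @param start_year first calendar year (integer).
#' @param label free-text identifier, e.g. a district name.
#' @param validate if `FALSE`, skip the grey-modelling admissibility checks
#'   (used internally for derived sequences such as residuals).
#'
#' @return an object of class `annual_series`: the numeric vector with
#'   `start_year` and `label` attributes.
#' @examples
#' x <- annual_series(c(100.82, 100.63, 100.31, 99.98), 2006, "Jing'an")
#' years(x)
#' @export
annual_series <- function(values, start_year, label = "", validate = TRUE) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("annual_series: values contain NA")
  start_year <- as.integer(start_year)
  if (length(start_year) != 1L || is.na(start_year))
    stop("annual_series: 'start_year' must be a single integer year")
  if (validate) {
    if (length(values) < 4L)
      stop("annual_series: at least 4 observations are required for grey modelling")
    if (any(values <= 0))
      stop("annual_series: all values must be strictly positive")
  }
  structure(values, start_year = start_year, label = as.character(label)[1L],
            class = "annual_series")
}

#' Calendar years of an annual series
#' @param x an `annual_series`.
#' @return integer vector of consecutive years.
#' @export
years <- function(x) {
  stopifnot(inherits(x, "annual_series"))
  attr(x, "start_year") + seq_along(x) - 1L
}

#' @export
print.annual_series <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Annual series%s: %d observations, %d-%d\n",
              if (nzchar(lab)) paste0(" '", lab, "'") else "",
              length(x), attr(x, "start_year"), max(years(x))))
  v <- as.numeric(x)
  names(v) <- years(x)
  print(v, ...)
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = years(x), value = as.numeric(x))
}

#' Extract a sub-window of an annual series by calendar years
#'
#' @param x an `annual_series`.
#' @param from,to first and last calendar year to keep (inclusive). `NULL`
#'   means the corresponding end of the series.
#' @return an `annual_series` covering `from:to`.
#' @export
window_years <- function(x, from = NULL, to = NULL) {
  stopifnot(inherits(x, "annual_series"))
  yr <- years(x)
  if (is.null(from)) from <- yr[1L]
  if (is.null(to)) to <- yr[length(yr)]
  if (from < yr[1L] || to > yr[length(yr)] || from > to)
    stop(sprintf("window_years: requested %d-%d outside series range %d-%d",
                 from, to, yr[1L], yr[length(yr)]))
  keep <- yr >= from & yr <= to
  annual_series(as.numeric(x)[keep], from, attr(x, "label"), validate = FALSE)
}

#' Read an annual series from a two-column CSV file
#'
#' The file must have a header and two columns, year and value. Years must be
#' consecutive integers.
#'
#' @param path path to the CSV file.
#' @param label series label; defaults to the file name without extension.
#' @return an `annual_series`.
#' @export
read_annual_csv <- function(path, label = NULL) {
  if (!file.exists(path)) stop("read_annual_csv: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("read_annual_csv: expected two columns (year, value)")
  if (nrow(df) == 0L) stop("read_annual_csv: file contains no data rows")
  yr <- as.integer(df[[1L]])
  if (anyNA(yr) || (length(yr) > 1L && any(diff(yr) != 1L)))
    stop("read_annual_csv: years must be consecutive integers")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  annual_series(df[[2L]], yr[1L], label)
}

#' Write an annual series to a two-column CSV file
#'
#' Values are written with enough digits that reading the file back
#' reproduces the series to better than 1e-9.
#'
#' @param x an `annual_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annual_csv <- function(x, path) {
  stopifnot(inherits(x, "annual_series"))
  df <- data.frame(year = years(x),
                   value = format(as.numeric(x), digits = 15, trim = TRUE,
                                  scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
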