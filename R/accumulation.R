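#' Generalized binomial coefficient of fractional accumulation
#'
#' Weight of the m-th lag in an r-order accumulated generating operation
#' (r-AGO): the coefficient of `x(k - m)` inside `x^(r)(k)`. For `m = 0` it
#' is 1 by convention; for `m >= 1` it equals
#' `(r + m - 1)(r + m - 2) ... (r + 1) r / m!`, i.e.
#' `Gamma(r + m) / (Gamma(m + 1) Gamma(r))` whenever `r` is positive.
#'
#' The product form is exact for every real `r` (including non-positive `r`, where
#' the Gamma form has poles); for large lags (`m > 20`) with positive `r` the
#' computation switches to log-Gamma to avoid overflow.
#'
#' @param m non-negative integer lag(s), `k - i` in the accumulation sum.
#' @param r accumulation order (real scalar).
#' @return numeric vector of coefficients, one per element of `m`.
#' @examples
#' frac_coef(0:3, 0.9491)
#' frac_coef(2, 0.9491)            # (r + 1) r / 2
#' @export
frac_coef <- function(m, r) {
  m <- as.integer(m)
  if (any(m < 0)) stop("frac_coef: lag m must be non-negative")
  stopifnot(length(r) == 1L, is.finite(r))
  vapply(m, function(mm) {
    if (mm == 0L) return(1)
    if (mm > 20L && r > 0) {
      exp(lgamma(r + mm) - lgamma(mm + 1) - lgamma(r))
    } else {
      prod((r + seq_len(mm) - 1) / seq_len(mm))
    }
  }, numeric(1L))
}

#' Gamma-function form of the accumulation coefficient
#'
#' Reference evaluation `Gamma(r + m) / (Gamma(m + 1) Gamma(r))`, defined
#' only away from the poles of the Gamma function (requires positive `r`). Kept
#' as an independent cross-check of [frac_coef()].
#'
#' @inheritParams frac_coef
#' @return numeric vector of coefficients.
#' @export
frac_coef_gamma <- function(m, r) {
  m <- as.integer(m)
  if (any(m < 0)) stop("frac_coef_gamma: lag m must be non-negative")
  if (r <= 0) stop("frac_coef_gamma: Gamma form undefined at non-positive order r")
  exp(lgamma(r + m) - lgamma(m + 1) - lgamma(r))
}

## internal: r-AGO on a bare numeric vector
frac_accumulate_num <- function(x, r) {
  n <- length(x)
  if (n == 0L) stop("fractional accumulation: empty series")
  cf <- frac_coef(0:(n - 1L), r)
  vapply(seq_len(n), function(k) sum(cf[k:1L] * x[1:k]), numeric(1L))
}

## internal: inverse r-AGO = (1 - r)-AGO followed by first differencing,
## first element passed through
frac_difference_num <- function(y, r) {
  n <- length(y)
  if (n == 0L) stop("fractional difference: empty series")
  x1 <- frac_accumulate_num(y, 1 - r)
  c(x1[1L], diff(x1))
}

## internal test oracle: direct inverse via the (-r)-order coefficients
frac_difference_direct <- function(y, r) frac_accumulate_num(y, -r)

#' Fractional-order accumulated generating operation (r-AGO)
#'
#' Element k of the result is `sum_{i=1..k} C(k - i; r) * x(i)` where
#' `C(m; r)` is [frac_coef()]. At order 1 this is the cumulative sum; at
#' order 0 it is the identity. The first element always equals `x(1)`.
#'
#' @param x an `annual_series` or numeric vector.
#' @param r accumulation order. Orders in (0, 1) weight recent observations
#'   more heavily than older ones (new-information priority); orders above 1
#'   reverse the ordering.
#' @return an object of class `accumulated_series`: the accumulated numeric
#'   vector with attributes `order` (r) and `source_label`.
#' @examples
#' frac_accumulate(c(1, 2, 3), 1)        # 1 3 6
#' @export
frac_accumulate <- function(x, r) {
  lab <- if (inherits(x, "annual_series")) attr(x, "label") else ""
  sy <- if (inherits(x, "annual_series")) attr(x, "start_year") else NA_integer_
  out <- frac_accumulate_num(as.numeric(x), r)
  structure(out, order = r, source_label = lab, start_year = sy,
            class = "accumulated_series")
}

#' Inverse fractional accumulation (r-order subtractive reduction)
#'
#' Exact inverse of [frac_accumulate()] at the same order: apply the
#' `(1 - r)`-order accumulation and then first-difference, passing the first
#' element through. For order 1 this is ordinary first differencing with the
#' first element kept.
#'
#' @param y an `accumulated_series` or numeric vector.
#' @param r the order at which `y` was accumulated. If `y` carries an
#'   `order` attribute and `r` is missing, that order is used.
#' @return numeric vector of the restored series.
#' @examples
#' frac_difference(c(1, 3, 6), 1)        # 1 2 3
#' @export
frac_difference <- function(y, r) {
  if (missing(r)) {
    r <- attr(y, "order")
    if (is.null(r)) stop("frac_difference: order r not supplied and not stored on 'y'")
  }
  frac_difference_num(as.numeric(y), r)
}

#' Background values of an accumulated series
#'
#' The mean-generated sequence `z(k) = (x(k) + x(k-1)) / 2` for
#' `k = 2, ..., n`, used to discretize the grey whitening equation for least
#' squares. The result has length `n - 1`.
#'
#' @param x an `accumulated_series` or numeric vector, length >= 2.
#' @return numeric vector of background values.
#' @examples
#' background_values(c(2, 4))            # 3
#' @export
background_values <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("background_values: need at least 2 elements")
  (x[-1L] + x[-n]) / 2
}
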