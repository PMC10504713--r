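#' Grey models with fractional-order accumulation
#'
#' `fit_fgm()` fits the fractional grey model FGM(1,1) to a positive annual
#' series at accumulation order `r`. Two presentations are available:
#'
#' * **continuous** (the default, and the core of the GT-FGM pipeline): the
#'   whitening equation `dx/dt + a x = b` is discretized with background
#'   values, `(a, b)` are estimated by least squares, and fitted accumulated
#'   values follow the exponential time response
#'   `x^(r)(k+1) = (x(1) - b/a) exp(-a k) + b/a`.
#' * **discrete**: the two-parameter recursion
#'   `x^(r)(k+1) = beta1 x^(r)(k) + beta2`, estimated by regressing the
#'   accumulated series on its lag, iterated from `x^(r)(1)`.
#'
#' In both cases the fitted accumulated sequence is restored to the original
#' scale by the inverse accumulation [frac_difference()]. The first fitted
#' value is anchored at the first observation. `fit_gm11()` is the classical
#' GM(1,1), i.e. the continuous form at order 1.
#'
#' @param series an [annual_series()] (or positive numeric vector), at
#'   least 4 observations, strictly positive.
#' @param r accumulation order.
#' @param form `"continuous"` (whitening-equation time response) or
#'   `"discrete"` (affine recursion).
#' @return an object of class `grey_fit` with elements
#'   `params` (list: `a`, `b`, `beta1`, `beta2`, `r`, `form`),
#'   `fitted_accumulated`, `fitted` (restored scale, sample length),
#'   `series` (the input), and `model` (a display name).
#' @examples
#' x <- annual_series(5 * exp(0.1 * (1:10)), 2001)
#' f <- fit_gm11(x)
#' predict(f, horizon = 3)
#' @export
fit_fgm <- function(series, r, form = c("continuous", "discrete")) {
  form <- match.arg(form)
  x <- as_model_input(series)
  n <- length(x)
  xr <- frac_accumulate_num(as.numeric(x), r)

  if (form == "continuous") {
    z <- background_values(xr)
    B <- cbind(-z, 1)
    Y <- diff(xr)
    ab <- grey_lstsq(B, Y)
    a <- ab[1L]
    b <- ab[2L]
    if (!is.finite(a) || abs(a) < .Machine$double.eps^0.75)
      stop("fit_fgm: development coefficient a is (numerically) zero; the time response is undefined")
    params <- list(a = a, b = b, beta1 = NA_real_, beta2 = NA_real_,
                   r = r, form = "continuous")
  } else {
    B <- cbind(xr[-n], 1)
    Y <- xr[-1L]
    bb <- grey_lstsq(B, Y)
    params <- list(a = NA_real_, b = NA_real_, beta1 = bb[1L], beta2 = bb[2L],
                   r = r, form = "discrete")
  }

  acc <- grey_response(params, x1 = as.numeric(x)[1L], xr1 = xr[1L], len = n)
  restored <- frac_difference_num(acc, r)
  structure(list(
    params = params,
    fitted_accumulated = structure(acc, order = r, class = "accumulated_series"),
    fitted = restored,
    series = x,
    model = if (r == 1) "GM(1,1)" else sprintf("FGM(1,1) r=%.4g", r)
  ), class = "grey_fit")
}

#' @rdname fit_fgm
#' @export
fit_gm11 <- function(series) {
  f <- fit_fgm(series, r = 1, form = "continuous")
  f$model <- "GM(1,1)"
  f
}

## coerce model input, enforcing the grey admissibility invariants
as_model_input <- function(series) {
  if (inherits(series, "annual_series")) {
    if (length(series) < 4L)
      stop("grey fit: at least 4 observations are required")
    if (any(as.numeric(series) <= 0))
      stop("grey fit: series must be strictly positive")
    series
  } else {
    annual_series(series, start_year = 1L, label = "")
  }
}

## least squares via orthogonal (QR) decomposition; errors on a
## near-singular design instead of returning garbage
grey_lstsq <- function(B, Y) {
  sv <- svd(B, nu = 0L, nv = 0L)$d
  if (sv[length(sv)] <= 0 || (sv[1L] / sv[length(sv)])^2 > 1e12)
    stop("grey fit: design matrix is (near-)singular; the series is degenerate (e.g. constant)")
  drop(qr.solve(B, Y))
}

## evaluate the fitted accumulated sequence for 'len' time points
grey_response <- function(params, x1, xr1, len) {
  k <- seq_len(len - 1L)
  if (params$form == "continuous") {
    a <- params$a
    b <- params$b
    c(xr1, (x1 - b / a) * exp(-a * k) + b / a)
  } else {
    acc <- numeric(len)
    acc[1L] <- xr1
    for (i in k) acc[i + 1L] <- params$beta1 * acc[i] + params$beta2
    acc
  }
}

#' Predict from a fitted grey model
#'
#' Continues the fitted time response (or discrete recursion) `horizon`
#' steps beyond the sample and restores to the original scale. The result is
#' deterministic given the fit.
#'
#' @param object a `grey_fit`.
#' @param horizon non-negative number of steps beyond the sample.
#' @param ... unused.
#' @return an `annual_series` of length `horizon` starting the year after
#'   the sample ends (empty if `horizon = 0`).
#' @export
predict.grey_fit <- function(object, horizon = 1L, ...) {
  stopifnot(horizon >= 0)
  horizon <- as.integer(horizon)
  x <- object$series
  n <- length(x)
  sy <- attr(x, "start_year")
  if (horizon == 0L)
    return(annual_series(numeric(0L), sy + n, attr(x, "label"), validate = FALSE))
  acc <- grey_response(object$params, x1 = as.numeric(x)[1L],
                       xr1 = object$fitted_accumulated[1L], len = n + horizon)
  restored <- frac_difference_num(acc, object$params$r)
  annual_series(restored[(n + 1L):(n + horizon)], sy + n, attr(x, "label"),
                validate = FALSE)
}

#' In-sample fitted values of a grey model on the original scale
#' @param object a `grey_fit`.
#' @param ... unused.
#' @export
fitted.grey_fit <- function(object, ...) object$fitted

#' @export
print.grey_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("%s (%s form)\n", x$model, p$form))
  if (p$form == "continuous") {
    cat(sprintf("  a = %.6g, b = %.6g, r = %.6g\n", p$a, p$b, p$r))
  } else {
    cat(sprintf("  beta1 = %.6g, beta2 = %.6g, r = %.6g\n", p$beta1, p$beta2, p$r))
  }
  cat(sprintf("  n = %d, in-sample MAPE = %.4g%%\n", length(x$series),
              mean(abs(x$fitted - as.numeric(x$series)) / as.numeric(x$series)) * 100))
  invisible(x)
}

#' Serialize a grey fit (or GT-FGM fit) to JSON
#'
#' @param fit a `grey_fit` or `gtfgm_fit`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @param horizon horizon for the `predicted` field.
#' @return JSON string (invisibly, if written to `path`).
#' @export
fit_report_json <- function(fit, path = NULL, horizon = 0L) {
  rep <- fit_report(fit, horizon)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

fit_report <- function(fit, horizon = 0L) UseMethod("fit_report")

#' @export
fit_report.grey_fit <- function(fit, horizon = 0L) {
  p <- fit$params
  pred <- predict(fit, horizon)
  list(model = fit$model, form = p$form, r = p$r,
       a = p$a, b = p$b, beta1 = p$beta1, beta2 = p$beta2,
       years = years(fit$series),
       observed = as.numeric(fit$series),
       fitted = fit$fitted,
       predicted = as.numeric(pred),
       predicted_years = if (horizon > 0) years(pred) else integer(0L))
}
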