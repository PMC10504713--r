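#' Comparator models: grey Verhulst, logistic curve, SES
#'
#' Three standalone baselines used in the benchmark tables.
#'
#' `fit_verhulst()` fits the grey Verhulst model, taking the observed series
#' itself as the saturating state variable of the logistic-type whitening
#' equation `dx/dt + a x = b x^2`. The grey difference equation
#' `x(k) - x(k-1) + a z(k) = b z(k)^2` (with `z` the background values of
#' the raw series) is solved by least squares and the time response
#' `x(k+1) = a x(1) / (b x(1) + (a - b x(1)) exp(a k))` supplies fitted and
#' predicted values.
#'
#' `fit_logistic()` fits the three-parameter logistic curve
#' `L / (1 + exp(-k (t - t0)))` to the raw series by bounded
#' Levenberg-Marquardt least squares, with a deterministic initialization
#' (`L0 = 1.05 max(x)`, `k0` from the log-linearized slope, `t0` at the
#' sample midpoint).
#'
#' `fit_ses()` is standalone simple exponential smoothing of the raw series
#' with the smoothing constant chosen on the 0.01-step grid minimizing the
#' in-sample MAE; multi-step forecasts are flat at the last level.
#'
#' @param series an [annual_series()] or positive numeric vector
#'   (length >= 4 for Verhulst/logistic, >= 2 for SES).
#' @return an object of class `baseline_fit`: list with `model_name`,
#'   `parameters` (named list), `fitted` (sample length), and `series`.
#' @examples
#' x <- annual_series(100 / (1 + exp(-0.4 * (1:12 - 6))) + 1, 2001)
#' f <- fit_logistic(x)
#' predict(f, horizon = 2)
#' @export
fit_verhulst <- function(series) {
  x <- as_model_input(series)
  xn <- as.numeric(x)
  n <- length(xn)
  z <- background_values(xn)
  B <- cbind(-z, z^2)
  Y <- diff(xn)
  ab <- grey_lstsq(B, Y)
  a <- ab[1L]
  b <- ab[2L]
  fitted <- verhulst_response(a, b, xn[1L], n)
  new_baseline("verhulst", list(a = a, b = b), fitted, x)
}

verhulst_response <- function(a, b, x1, len) {
  k <- 0:(len - 1L)
  denom <- b * x1 + (a - b * x1) * exp(a * k)
  if (any(!is.finite(denom)) || any(denom == 0))
    stop("fit_verhulst: degenerate time response (division by zero)")
  a * x1 / denom
}

#' @rdname fit_verhulst
#' @export
fit_logistic <- function(series) {
  x <- as_model_input(series)
  xn <- as.numeric(x)
  n <- length(xn)
  t <- seq_len(n)
  if (diff(range(xn)) <= 1e-10 * mean(xn)) {
    # degenerate plateau: represent the constant as the upper asymptote
    # approached far to the left of the sample (k near zero, fitted flat)
    L <- mean(xn)
    k <- 1e-6
    t0 <- (n + 1) / 2 - 1e8
    return(new_baseline("logistic", list(L = L, k = k, t0 = t0),
                        L / (1 + exp(-k * (t - t0))), x))
  }
  L0 <- 1.05 * max(xn)
  lg <- log(pmax(xn, 1e-12) / pmax(L0 - xn, 1e-12))
  sl <- stats::coef(stats::lm.fit(cbind(1, t), lg))
  k0 <- unname(sl[2L])
  if (!is.finite(k0) || abs(k0) < 1e-4) k0 <- sign(k0 + 1e-12) * 1e-4
  df <- data.frame(t = t, y = xn)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (t - t0))), data = df,
                      start = list(L = L0, k = k0, t0 = (n + 1) / 2),
                      lower = c(L = 1e-8, k = -Inf, t0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit_logistic: curve fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  fitted <- cf[["L"]] / (1 + exp(-cf[["k"]] * (t - cf[["t0"]])))
  new_baseline("logistic", list(L = cf[["L"]], k = cf[["k"]], t0 = cf[["t0"]]),
               fitted, x)
}

#' @rdname fit_verhulst
#' @param alpha optional fixed smoothing constant in (0, 1]; `NULL` selects
#'   it on the grid.
#' @export
fit_ses <- function(series, alpha = NULL) {
  x <- if (inherits(series, "annual_series")) series
       else annual_series(series, 1L, validate = FALSE)
  xn <- as.numeric(x)
  if (length(xn) < 2L) stop("fit_ses: need at least 2 observations")
  if (is.null(alpha)) {
    grid <- alpha_grid_default()
    # one-step in-sample errors for every alpha at once (theta = 1 line)
    # theta = 1 makes the combined forecast the smoothed sequence itself
    best <- alpha_search(xn, xn, theta = 1, grey_fitted = rep(0, length(xn)),
                         grid = grid)
    alpha <- best$alpha
    smoothed <- best$smoothed
  } else {
    if (!(alpha > 0 && alpha <= 1)) stop("fit_ses: alpha must lie in (0, 1]")
    smoothed <- ses_smooth(xn, alpha)
  }
  level <- alpha * xn[length(xn)] + (1 - alpha) * smoothed[length(xn)]
  new_baseline("ses", list(alpha = alpha, level = level), smoothed, x)
}

new_baseline <- function(name, parameters, fitted, series) {
  structure(list(model_name = name, parameters = parameters,
                 fitted = fitted, series = series),
            class = "baseline_fit")
}

#' Predict from a baseline fit
#'
#' Verhulst and logistic fits extend their fitted curves; SES forecasts are
#' flat at the last smoothed level.
#'
#' @param object a `baseline_fit`.
#' @param horizon non-negative number of steps beyond the sample.
#' @param ... unused.
#' @return an `annual_series` of predictions.
#' @export
predict.baseline_fit <- function(object, horizon = 1L, ...) {
  stopifnot(horizon >= 0)
  horizon <- as.integer(horizon)
  x <- object$series
  n <- length(x)
  sy <- attr(x, "start_year")
  p <- object$parameters
  vals <- if (horizon == 0L) numeric(0L)
  else switch(object$model_name,
    verhulst = verhulst_response(p$a, p$b, as.numeric(x)[1L],
                                 n + horizon)[(n + 1L):(n + horizon)],
    logistic = {
      t <- (n + 1L):(n + horizon)
      p$L / (1 + exp(-p$k * (t - p$t0)))
    },
    ses = rep(p$level, horizon),
    stop("predict: unknown baseline model ", object$model_name))
  annual_series(vals, sy + n, attr(x, "label"), validate = FALSE)
}

#' @export
fitted.baseline_fit <- function(object, ...) object$fitted

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("Baseline fit '%s': %s\n", x$model_name,
              paste(names(x$parameters),
                    vapply(x$parameters, function(v) sprintf("%.6g", v), ""),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' @export
fit_report.baseline_fit <- function(fit, horizon = 0L) {
  pred <- predict(fit, horizon)
  list(model = fit$model_name, parameters = fit$parameters,
       years = years(fit$series),
       observed = as.numeric(fit$series),
       fitted = fit$fitted,
       predicted = as.numeric(pred),
       predicted_years = if (horizon > 0) years(pred) else integer(0L))
}
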