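#' Theta line of an observed series around a grey trend
#'
#' The Theta line amplifies (`theta > 1`) or damps (`theta < 1`) the local
#' curvature of the observations around a long-term trend:
#' `x_theta(k) = theta * x(k) + (1 - theta) * xhat(k)`, element-wise. In the
#' GT-FGM pipeline the trend is the restored grey fit, so the Theta line is
#' the observation plus `theta`-scaled grey residuals.
#'
#' @param observed observed series (`annual_series` or numeric).
#' @param grey_fitted trend values on the original scale, same length.
#' @param theta curvature parameter; the GT-FGM constraint is
#'   `1 < theta <= 5`, but any positive value is accepted here so the
#'   degenerate identity `theta = 1` is representable.
#' @return an object of class `theta_line`: numeric vector with attributes
#'   `theta` and `long_term` (the trend).
#' @examples
#' build_theta_line(c(10, 11, 12), c(10, 10.5, 12.5), theta = 2)
#' @export
build_theta_line <- function(observed, grey_fitted, theta) {
  x <- as.numeric(observed)
  f <- as.numeric(grey_fitted)
  if (length(x) != length(f))
    stop("build_theta_line: observed and trend must have equal length")
  stopifnot(length(theta) == 1L, is.finite(theta), theta > 0)
  structure(theta * x + (1 - theta) * f,
            theta = theta, long_term = f, class = "theta_line")
}

#' Simple exponential smoothing of a (Theta-)line
#'
#' Level-only recursion `s(k+1) = alpha * x(k) + (1 - alpha) * s(k)`,
#' initialized at `s(1) = x(1)`. At `alpha = 1` the smoothed sequence is the
#' lag-1 series. Out-of-sample continuation is flat at the last updated
#' level (the classical multi-step SES forecast).
#'
#' @param line a `theta_line` or numeric vector.
#' @param alpha smoothing constant, `0 < alpha <= 1`.
#' @param horizon number of flat continuation steps appended to the
#'   in-sample smoothed sequence.
#' @return numeric vector of length `length(line) + horizon`. The first
#'   `n` entries are the in-sample smoothed values `s(1), ..., s(n)`; the
#'   continuation entries all equal the level updated through `x(n)`.
#' @examples
#' ses_smooth(c(2, 4, 6), alpha = 0.5)   # 2 3 4.5
#' @export
ses_smooth <- function(line, alpha, horizon = 0L) {
  x <- as.numeric(line)
  if (!(length(alpha) == 1L && is.finite(alpha) && alpha > 0 && alpha <= 1))
    stop("ses_smooth: alpha must lie in (0, 1]")
  n <- length(x)
  if (n == 0L) stop("ses_smooth: empty input")
  s <- numeric(n)
  s[1L] <- x[1L]
  if (n > 1L) for (k in 1:(n - 1L)) s[k + 1L] <- alpha * x[k] + (1 - alpha) * s[k]
  if (horizon > 0L) {
    level <- alpha * x[n] + (1 - alpha) * s[n]
    s <- c(s, rep(level, horizon))
  }
  s
}

## default smoothing-constant grid: 0.01, 0.02, ..., 1.00
alpha_grid_default <- function() seq(0.01, 1, by = 0.01)

## vectorized in-sample search: for fixed (theta, trend), smooth the theta
## line at every alpha on the grid and score the combined forecast by MAE
## against the observations; ties go to the smallest alpha.
alpha_search <- function(x_theta, observed, theta, grey_fitted,
                         grid = alpha_grid_default()) {
  n <- length(observed)
  S <- matrix(0, nrow = length(grid), ncol = n)
  S[, 1L] <- x_theta[1L]
  if (n > 1L) for (k in 1:(n - 1L))
    S[, k + 1L] <- grid * x_theta[k] + (1 - grid) * S[, k]
  w <- (theta - 1) / theta
  Y <- w * matrix(grey_fitted, nrow = length(grid), ncol = n, byrow = TRUE) +
    (1 / theta) * S
  maes <- rowMeans(abs(sweep(Y, 2L, observed)))
  i <- which.min(maes)  # which.min returns the first (smallest-alpha) minimum
  list(alpha = grid[i], mae = maes[i], smoothed = S[i, ], combined = Y[i, ])
}

#' Select the SES smoothing constant for the GT-FGM combination
#'
#' Exhaustive grid search over `alpha` in {0.01, 0.02, ..., 1.00}: each
#' candidate smooths the Theta line, the combined forecast
#' `yhat = ((theta-1)/theta) * grey + (1/theta) * smoothed` is formed, and
#' the `alpha` minimizing the in-sample mean absolute error against the
#' observations is returned. Ties are broken to the smallest `alpha`. The
#' search is deterministic.
#'
#' @param line the Theta line ([build_theta_line()]) or numeric vector.
#' @param observed observed series, same length.
#' @param theta the curvature used to build the line.
#' @param grey_fitted the grey trend on the original scale.
#' @param grid alpha grid (default step 0.01 on (0, 1]).
#' @return the selected `alpha` (scalar).
#' @export
select_alpha <- function(line, observed, theta, grey_fitted,
                         grid = alpha_grid_default()) {
  x <- as.numeric(line)
  obs <- as.numeric(observed)
  gf <- as.numeric(grey_fitted)
  if (length(x) != length(obs) || length(x) != length(gf))
    stop("select_alpha: inputs must have equal length")
  alpha_search(x, obs, theta, gf, grid)$alpha
}

#' Grey Theta fractional-order model (GT-FGM)
#'
#' Runs the full pipeline: fractional accumulation at order `r`, continuous
#' FGM fit and restoration, Theta-line construction at curvature `theta`,
#' SES smoothing with grid-selected `alpha`, and the convex recombination
#' `yhat(k) = ((theta - 1)/theta) * xhat0(k) + (1/theta) * s(k)`.
#'
#' When `r` and/or `theta` are `NULL` they are optimized by particle swarm:
#' with the default staged scheme, `r` first minimizes the in-sample MAPE of
#' the plain fractional grey fit, then `theta` (with `alpha` nested on its
#' grid) minimizes the in-sample MAE of the combined forecast. Setting
#' `objective = "joint"` instead searches `(r, theta)` together on the
#' combined-MAE surface; see the package vignette for why the staged scheme
#' is the default.
#'
#' Out of sample, the grey component extrapolates its time response while
#' the smoothed Theta component is held flat at its last level
#' (`theta_forecast = "flat"`); `theta_forecast = "grey"` drops the flat
#' term and extends with the grey extrapolation alone.
#'
#' @param series an [annual_series()] (or positive numeric vector).
#' @param r accumulation order, or `NULL` to optimize.
#' @param theta curvature, `1 < theta <= 5`, or `NULL` to optimize.
#' @param alpha SES smoothing constant in (0, 1], or `NULL` (default) for
#'   the MAE-minimizing grid search.
#' @param horizon prediction steps beyond the sample stored on the result.
#' @param form grey-model form passed to [fit_fgm()].
#' @param objective `"staged"` (default) or `"joint"` hyperparameter search.
#' @param theta_forecast out-of-sample treatment of the smoothed component.
#' @param control a [pso_control()] list (bounds, swarm settings).
#' @param seed integer seed driving the particle swarm; the whole fit is
#'   reproducible from (`series`, arguments, `seed`).
#' @return an object of class `gtfgm_fit`: list with `grey_fit`, `r`,
#'   `theta`, `alpha`, `theta_line`, `smoothed`, `fitted` (combined
#'   in-sample forecast), `objective` (achieved in-sample MAE), `predicted`
#'   (length-`horizon` `annual_series`), `series`, and `meta` (search mode,
#'   seed, grid step).
#' @examples
#' x <- annual_series(c(21.4, 22.0, 22.8, 23.6, 24.7, 25.8, 27.2, 28.4),
#'                    2006, "toy")
#' f <- gt_fgm(x, r = 1, theta = 2, horizon = 2)
#' predict(f, horizon = 2)
#' @export
gt_fgm <- function(series, r = NULL, theta = NULL, alpha = NULL, horizon = 0L,
                   form = c("continuous", "discrete"),
                   objective = c("staged", "joint"),
                   theta_forecast = c("flat", "grey"),
                   control = pso_control(), seed = 1L) {
  form <- match.arg(form)
  objective <- match.arg(objective)
  theta_forecast <- match.arg(theta_forecast)
  x <- as_model_input(series)
  xnum <- as.numeric(x)

  if (is.null(r) || is.null(theta)) {
    hp <- select_hyperparameters(x, r = r, theta = theta, form = form,
                                 objective = objective, control = control,
                                 seed = seed)
    r <- hp$r
    theta <- hp$theta
  }
  if (!(theta > 1 && theta <= control$theta_max + 1e-9) && theta != 1)
    stop("gt_fgm: theta must satisfy 1 < theta <= theta_max (or exactly 1 for the degenerate line)")

  fit <- fit_fgm(x, r, form = form)
  xhat0 <- fit$fitted
  line <- build_theta_line(x, xhat0, theta)
  if (is.null(alpha)) {
    sel <- alpha_search(as.numeric(line), xnum, theta, xhat0)
    alpha <- sel$alpha
    smoothed <- sel$smoothed
    combined <- sel$combined
  } else {
    smoothed <- ses_smooth(line, alpha)
    combined <- (theta - 1) / theta * xhat0 + (1 / theta) * smoothed
  }
  obj <- mean(abs(combined - xnum))

  res <- structure(list(
    grey_fit = fit, r = r, theta = theta, alpha = alpha,
    theta_line = line, smoothed = smoothed, fitted = combined,
    objective = obj, series = x, predicted = NULL,
    meta = list(objective = objective, theta_forecast = theta_forecast,
                form = form, seed = seed,
                alpha_grid_step = 0.01, model = "GT-FGM")
  ), class = "gtfgm_fit")
  if (horizon > 0L) res$predicted <- predict(res, horizon)
  res
}

#' Predict from a fitted GT-FGM model
#'
#' @param object a `gtfgm_fit`.
#' @param horizon non-negative number of steps beyond the sample.
#' @param ... unused.
#' @return an `annual_series` of predictions (empty if `horizon = 0`).
#' @export
predict.gtfgm_fit <- function(object, horizon = 1L, ...) {
  stopifnot(horizon >= 0)
  horizon <- as.integer(horizon)
  x <- object$series
  n <- length(x)
  sy <- attr(x, "start_year")
  if (horizon == 0L)
    return(annual_series(numeric(0L), sy + n, attr(x, "label"), validate = FALSE))
  grey_ext <- as.numeric(predict(object$grey_fit, horizon))
  theta <- object$theta
  if (object$meta$theta_forecast == "grey") {
    pred <- grey_ext
  } else {
    level <- object$alpha * as.numeric(object$theta_line)[n] +
      (1 - object$alpha) * object$smoothed[n]
    pred <- (theta - 1) / theta * grey_ext + (1 / theta) * level
  }
  annual_series(pred, sy + n, attr(x, "label"), validate = FALSE)
}

#' @export
fitted.gtfgm_fit <- function(object, ...) object$fitted

#' @export
print.gtfgm_fit <- function(x, ...) {
  cat(sprintf("GT-FGM fit: r = %.4f, theta = %.4g, alpha = %.2f\n",
              x$r, x$theta, x$alpha))
  cat(sprintf("  combination weights: %.4g * grey + %.4g * smoothed theta line\n",
              (x$theta - 1) / x$theta, 1 / x$theta))
  obs <- as.numeric(x$series)
  cat(sprintf("  n = %d, in-sample MAE = %.4g, MAPE = %.4g%%\n", length(obs),
              x$objective, mean(abs(x$fitted - obs) / obs) * 100))
  invisible(x)
}

#' @export
fit_report.gtfgm_fit <- function(fit, horizon = 0L) {
  pred <- predict(fit, horizon)
  list(model = "GT-FGM", r = fit$r, theta = fit$theta, alpha = fit$alpha,
       a = fit$grey_fit$params$a, b = fit$grey_fit$params$b,
       beta1 = fit$grey_fit$params$beta1, beta2 = fit$grey_fit$params$beta2,
       form = fit$meta$form, objective_mae = fit$objective,
       search = fit$meta$objective, theta_forecast = fit$meta$theta_forecast,
       alpha_grid_step = fit$meta$alpha_grid_step, seed = fit$meta$seed,
       years = years(fit$series),
       observed = as.numeric(fit$series),
       fitted = fit$fitted,
       predicted = as.numeric(pred),
       predicted_years = if (horizon > 0) years(pred) else integer(0L))
}

#' Classical Theta decomposition with a linear long-term trend
#'
#' Reference implementation of the textbook Theta method: the long-term
#' component is the OLS line `A + B t`, the Theta line is
#' `theta * y + (1 - theta) * (A + B t)`, and the recombination uses the
#' same `((theta-1)/theta, 1/theta)` weights with an SES-smoothed Theta
#' line. Provided for regression comparisons; the GT-FGM pipeline replaces
#' the linear trend with the grey fit.
#'
#' @param observed an `annual_series` or numeric vector.
#' @param theta curvature, `theta > 1`.
#' @return list with `intercept`, `slope`, `line` (a `theta_line`),
#'   `alpha`, and `fitted` (the recombined in-sample forecast).
#' @export
theta_classical <- function(observed, theta = 2) {
  y <- as.numeric(observed)
  t <- seq_along(y)
  cf <- stats::coef(stats::lm.fit(cbind(1, t), y))
  trend <- cf[1L] + cf[2L] * t
  line <- build_theta_line(y, trend, theta)
  sel <- alpha_search(as.numeric(line), y, theta, trend)
  list(intercept = unname(cf[1L]), slope = unname(cf[2L]), line = line,
       alpha = sel$alpha, fitted = sel$combined)
}
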