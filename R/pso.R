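#' Particle swarm settings for GT-FGM hyperparameter search
#'
#' Canonical PSO with inertia `w`, cognitive/social accelerations
#' `c1 = c2 = 2`, velocities clipped per dimension to `vmax_frac` of the box
#' width, and absorbing boundaries (positions clamped to the box, the
#' offending velocity component zeroed). Absorbing boundaries matter here
#' because the curvature optimum frequently sits on the `theta = 5`
#' constraint boundary.
#'
#' @param particles swarm size.
#' @param iterations number of velocity/position updates.
#' @param w inertia weight.
#' @param c1,c2 cognitive and social acceleration constants.
#' @param vmax_frac velocity cap as a fraction of each dimension's range.
#' @param r_min,r_max admissible accumulation-order interval.
#' @param theta_min,theta_max admissible curvature interval (the model
#'   constraint is `1 < theta <= 5`; `theta_min` is an open-boundary proxy).
#' @return a list of class `pso_control`.
#' @export
pso_control <- function(particles = 30L, iterations = 100L, w = 0.8,
                        c1 = 2, c2 = 2, vmax_frac = 0.2,
                        r_min = 0.01, r_max = 2,
                        theta_min = 1 + 1e-6, theta_max = 5) {
  stopifnot(particles >= 1L, iterations >= 0L, vmax_frac > 0,
            r_min < r_max, theta_min < theta_max)
  structure(list(particles = as.integer(particles),
                 iterations = as.integer(iterations),
                 w = w, c1 = c1, c2 = c2, vmax_frac = vmax_frac,
                 r_min = r_min, r_max = r_max,
                 theta_min = theta_min, theta_max = theta_max),
            class = "pso_control")
}

## run 'expr' under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Minimize a box-constrained objective by particle swarm
#'
#' Velocity update `v <- w v + c1 r1 (p_best - x) + c2 r2 (g_best - x)`
#' with uniform `r1, r2` drawn per particle and dimension, followed by the
#' position update `x <- x + v`. Velocities are clipped to
#' `vmax_frac * (upper - lower)`; positions are clamped to the box with the
#' offending velocity component set to zero. The global best is tracked
#' monotonically and the whole trajectory is reproducible from `seed`.
#'
#' @param fn objective: takes a numeric vector of length `length(lower)`,
#'   returns a finite scalar (non-finite values are treated as a penalty).
#' @param lower,upper box bounds (equal length, `lower < upper`).
#' @param control a [pso_control()]; `particles`, `iterations`, `w`, `c1`,
#'   `c2` and `vmax_frac` are used.
#' @param seed integer seed for the swarm's random draws.
#' @return list with `par` (best position), `value` (best objective),
#'   `history` (global-best objective after initialization and after each
#'   iteration), and `evals` (number of objective evaluations).
#' @examples
#' pso_minimize(function(p) sum((p - c(0.5, 2))^2),
#'              lower = c(0, 1), upper = c(2, 5), seed = 1)
#' @export
pso_minimize <- function(fn, lower, upper, control = pso_control(), seed = 1L) {
  stopifnot(length(lower) == length(upper))
  if (any(!(lower < upper))) stop("pso_minimize: degenerate bounds (empty box)")
  d <- length(lower)
  np <- control$particles
  vmax <- control$vmax_frac * (upper - lower)

  eval1 <- function(p) {
    v <- tryCatch(fn(p), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  with_seed(seed, {
    X <- matrix(stats::runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
    V <- matrix(stats::runif(np * d, rep(-vmax, each = np), rep(vmax, each = np)),
                nrow = np)
    fX <- apply(X, 1L, eval1)
    P <- X                 # personal bests
    fP <- fX
    g <- which.min(fP)
    gbest <- P[g, ]
    fg <- fP[g]
    history <- numeric(control$iterations + 1L)
    history[1L] <- fg

    if (control$iterations > 0L) for (it in seq_len(control$iterations)) {
      R1 <- matrix(stats::runif(np * d), nrow = np)
      R2 <- matrix(stats::runif(np * d), nrow = np)
      V <- control$w * V +
        control$c1 * R1 * (P - X) +
        control$c2 * R2 * (matrix(gbest, np, d, byrow = TRUE) - X)
      V <- pmin(pmax(V, matrix(-vmax, np, d, byrow = TRUE)),
                matrix(vmax, np, d, byrow = TRUE))
      X <- X + V
      for (j in seq_len(d)) {     # absorbing boundaries
        lo <- X[, j] < lower[j]
        hi <- X[, j] > upper[j]
        X[lo, j] <- lower[j]
        X[hi, j] <- upper[j]
        V[lo | hi, j] <- 0
      }
      fX <- apply(X, 1L, eval1)
      better <- fX < fP
      fP[better] <- fX[better]
      P[better, ] <- X[better, , drop = FALSE]
      g <- which.min(fP)
      if (fP[g] < fg) {
        fg <- fP[g]
        gbest <- P[g, ]
      }
      history[it + 1L] <- fg
    }
    list(par = gbest, value = fg, history = history,
         evals = np * (control$iterations + 1L))
  })
}

#' In-sample objectives of the fractional grey pipeline
#'
#' `fgm_objective()` is the in-sample MAPE (%) of the plain fractional grey
#' fit at order `r` — the quantity the order search minimizes in the staged
#' scheme. `gtfgm_objective()` is the in-sample MAE of the full combined
#' forecast at `(r, theta)` with the smoothing constant `alpha` nested on
#' its grid — the formal GT-FGM optimization objective. Both map any fit
#' failure (degenerate design, inadmissible order) to `Inf` so optimizers
#' can treat it as a penalty, and both are deterministic.
#'
#' @param series an [annual_series()] or positive numeric vector.
#' @param r accumulation order.
#' @param theta curvature, `1 < theta <= 5`.
#' @param form grey-model form.
#' @return scalar objective value (`Inf` on failure).
#' @export
gtfgm_objective <- function(series, r, theta, form = "continuous") {
  x <- as.numeric(series)
  tryCatch({
    fit <- fit_fgm(as_model_input(series), r, form = form)
    alpha_search(theta * x + (1 - theta) * fit$fitted, x, theta, fit$fitted)$mae
  }, error = function(e) Inf)
}

#' @rdname gtfgm_objective
#' @export
fgm_objective <- function(series, r, form = "continuous") {
  x <- as.numeric(series)
  tryCatch({
    fit <- fit_fgm(as_model_input(series), r, form = form)
    mean(abs(fit$fitted - x) / x) * 100
  }, error = function(e) Inf)
}

## hyperparameter search driver used by gt_fgm()
##
## staged (default): r minimizes the plain grey fit's in-sample MAPE, then
## theta (alpha nested) minimizes the combined MAE at that r.
## joint: (r, theta) minimized together on the combined-MAE surface.
select_hyperparameters <- function(series, r = NULL, theta = NULL,
                                   form = "continuous",
                                   objective = c("staged", "joint"),
                                   control = pso_control(), seed = 1L) {
  objective <- match.arg(objective)
  seed2 <- (as.integer(seed) %% 2147483000L) + 1L
  if (objective == "joint" && is.null(r) && is.null(theta)) {
    opt <- pso_minimize(function(p) gtfgm_objective(series, p[1L], p[2L], form),
                        lower = c(control$r_min, control$theta_min),
                        upper = c(control$r_max, control$theta_max),
                        control = control, seed = seed)
    return(list(r = opt$par[1L], theta = opt$par[2L], value = opt$value))
  }
  if (is.null(r)) {
    fn_r <- if (objective == "staged") {
      function(p) fgm_objective(series, p[1L], form)
    } else {
      function(p) gtfgm_objective(series, p[1L], theta, form)
    }
    r <- pso_minimize(fn_r, lower = control$r_min, upper = control$r_max,
                      control = control, seed = seed)$par[1L]
  }
  value <- NA_real_
  if (is.null(theta)) {
    opt <- pso_minimize(function(p) gtfgm_objective(series, r, p[1L], form),
                        lower = control$theta_min, upper = control$theta_max,
                        control = control, seed = seed2)
    theta <- opt$par[1L]
    value <- opt$value
  }
  list(r = r, theta = theta, value = value)
}
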