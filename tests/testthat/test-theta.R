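test_that("the Theta line is the stated affine recombination", {
  obs <- c(10, 11, 12, 13)
  fit <- c(10, 10.5, 12.5, 12.8)
  expect_equal(as.numeric(build_theta_line(obs, fit, 1)), obs)
  expect_equal(as.numeric(build_theta_line(obs, fit, 5)), 5 * obs - 4 * fit)
  # perfect-fit degeneracy: the line equals the observations for every theta
  for (th in c(1.5, 2, 5))
    expect_equal(as.numeric(build_theta_line(obs, obs, th)), obs)
  expect_error(build_theta_line(obs, fit[-1], 2), "equal length")
})

test_that("SES smoothing follows the stated recursion and initialization", {
  # alpha = 1: the smoothed sequence is the lag-1 series
  x <- c(3, 7, 2, 9, 4)
  expect_equal(ses_smooth(x, 1), c(3, x[-5]))
  # constant input is a fixed point for any alpha
  for (al in c(0.2, 0.7, 1)) expect_equal(ses_smooth(rep(4, 6), al), rep(4, 6))
  # hand-unrolled at alpha = 0.5 on (2, 4, 6):
  #   s1 = 2; s2 = .5*2 + .5*2 = 2; s3 = .5*4 + .5*2 = 3; level = .5*6 + .5*3
  expect_equal(ses_smooth(c(2, 4, 6), 0.5), c(2, 2, 3))
  expect_equal(ses_smooth(c(2, 4, 6), 0.5, horizon = 2), c(2, 2, 3, 4.5, 4.5))
  expect_error(ses_smooth(x, 0), "alpha")
  expect_error(ses_smooth(x, 1.2), "alpha")
})

test_that("alpha selection minimizes the combined in-sample MAE on its grid", {
  # constructed instance with a unique zero of the objective at alpha = 0.3
  set.seed(11)
  line <- 50 + cumsum(rnorm(12))
  grey <- 50 + 0.5 * (1:12)
  theta <- 2.5
  s <- ses_smooth(line, 0.3)
  obs <- (theta - 1) / theta * grey + (1 / theta) * s
  expect_equal(select_alpha(line, obs, theta, grey), 0.3)

  # grid dominance on an arbitrary series
  obs2 <- as.numeric(random_series(10, seed = 9))
  line2 <- as.numeric(build_theta_line(obs2, rev(sort(obs2)), 2))
  a_star <- select_alpha(line2, obs2, 2, rev(sort(obs2)))
  mae_at <- function(al) {
    s <- ses_smooth(line2, al)
    mean(abs(0.5 * rev(sort(obs2)) + 0.5 * s - obs2))
  }
  best <- mae_at(a_star)
  for (al in seq(0.01, 1, by = 0.01)) expect_lte(best, mae_at(al) + 1e-12)

  # flat objective (everything constant): tie broken to the smallest alpha
  expect_equal(select_alpha(rep(5, 8), rep(5, 8), 2, rep(5, 8)), 0.01)
})

test_that("the combined forecast uses the (theta-1)/theta, 1/theta weights", {
  f <- gt_fgm(jingan_totals(), r = 0.9491, theta = 5)
  expect_equal(f$fitted,
               4 / 5 * f$grey_fit$fitted + 1 / 5 * f$smoothed,
               tolerance = 1e-12)
  # anchored first point: yhat(1) = x(1)
  expect_equal(f$fitted[1], as.numeric(jingan_totals())[1], tolerance = 1e-10)
  # convexity: each combined value lies between its two components
  g <- gt_fgm(jingan_totals(), r = 0.9491, theta = 2.5)
  lo <- pmin(g$grey_fit$fitted, g$smoothed)
  hi <- pmax(g$grey_fit$fitted, g$smoothed)
  expect_true(all(g$fitted >= lo - 1e-12 & g$fitted <= hi + 1e-12))
})

test_that("theta limits recover the pure grey fit and pure SES", {
  x <- jingan_totals()
  ctrl <- pso_control(theta_max = 1e6)
  big <- gt_fgm(x, r = 0.9491, theta = 1e6, control = ctrl)
  expect_equal(big$fitted, big$grey_fit$fitted, tolerance = 1e-4)
  near1 <- gt_fgm(x, r = 0.9491, theta = 1 + 1e-9)
  expect_equal(near1$fitted,
               ses_smooth(as.numeric(x), near1$alpha), tolerance = 1e-5)
})

test_that("zero grey residuals collapse the theta line onto the observations", {
  x <- generate_synthetic("grey_exact", list(a = 0.01, b = 8, x1 = 12, r = 1),
                          n = 10)
  xn <- as.numeric(x)
  for (th in c(2, 5)) {
    f <- gt_fgm(x, r = 1, theta = th)
    # residuals are (near) zero, so the theta line reduces to the data
    expect_equal(as.numeric(f$theta_line), xn, tolerance = 1e-4)
    # the SES term can still lag a trending line: the combined error is
    # bounded by the down-weighted one-step drift, not by zero
    expect_lte(f$objective, mean(abs(diff(xn))) / th + 1e-6)
  }
})

test_that("the theta correction does not worsen the in-sample MAE objective", {
  for (s in list(jingan_totals(), jingan_elderly(), xuhui_elderly())) {
    f <- gt_fgm(s, r = 0.9491)
    fgm_mae <- mean(abs(fit_fgm(s, 0.9491)$fitted - as.numeric(s)))
    expect_lte(f$objective, fgm_mae + 1e-12)
  }
})

test_that("GT-FGM results are reproducible from the seed", {
  f1 <- gt_fgm(jingan_totals(), seed = 42, horizon = 3)
  f2 <- gt_fgm(jingan_totals(), seed = 42, horizon = 3)
  expect_identical(f1$r, f2$r)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(as.numeric(f1$predicted), as.numeric(f2$predicted))
})

test_that("out-of-sample extension follows the configured rule", {
  f <- gt_fgm(jingan_totals(), r = 0.9491, theta = 5, horizon = 4)
  grey_ext <- as.numeric(predict(f$grey_fit, 4))
  level <- f$alpha * as.numeric(f$theta_line)[15] +
    (1 - f$alpha) * f$smoothed[15]
  expect_equal(as.numeric(f$predicted), 0.8 * grey_ext + 0.2 * level,
               tolerance = 1e-12)
  g <- gt_fgm(jingan_totals(), r = 0.9491, theta = 5, theta_forecast = "grey")
  expect_equal(as.numeric(predict(g, 4)), grey_ext, tolerance = 1e-12)
  expect_length(predict(f, 0), 0)
})

test_that("the classical Theta reference uses the OLS trend", {
  y <- 10 + 1.5 * (1:12) + sin(1:12)
  th <- theta_classical(y, theta = 2)
  ols <- stats::lm(y ~ t, data = data.frame(t = 1:12, y = y))
  expect_equal(th$intercept, unname(coef(ols)[1]), tolerance = 1e-9)
  expect_equal(th$slope, unname(coef(ols)[2]), tolerance = 1e-9)
  trend <- th$intercept + th$slope * (1:12)
  expect_equal(as.numeric(th$line), 2 * y - trend, tolerance = 1e-9)
})
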