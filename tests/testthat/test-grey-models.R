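test_that("least squares recovers the generating parameters of exact grey data", {
  for (r in c(0.5, 1, 1.3)) {
    x <- generate_synthetic("grey_exact", list(a = 0.05, b = 10, x1 = 10, r = r),
                            n = 10)
    f <- fit_fgm(x, r)
    expect_equal(f$params$a, 0.05, tolerance = 1e-6)
    expect_equal(f$params$b, 10, tolerance = 1e-6)
    # the fitted values come from the continuous response, whose decay
    # e^(-a) differs from the estimating recursion's (1-a/2)/(1+a/2) by
    # O(a^3): exact parameter recovery, near-exact (not exact) fit
    expect_equal(f$fitted, as.numeric(x), tolerance = 1e-3)
  }
})

test_that("the continuous fit reproduces the worked-example parameters", {
  f <- fit_fgm(jingan_totals(), 0.9491)
  expect_equal(round(f$params$a, 4), 0.0170)
  # the published b (97.1287) stems from the unrounded optimum order; at
  # r = 0.9491 exactly the estimate agrees to ~5e-5 relative
  expect_equal(f$params$b, 97.1287, tolerance = 1e-4)
  expect_equal(as.numeric(f$fitted_accumulated[1:4]),
               c(100.82, 195.42, 288.43, 379.87), tolerance = 1e-4)
})

test_that("the discrete form solves an exact affine recursion exactly", {
  # accumulated sequence with x(k+1) = 1.1 x(k) + 2 at r = 1
  acc <- numeric(8)
  acc[1] <- 10
  for (k in 1:7) acc[k + 1] <- 1.1 * acc[k] + 2
  x <- annual_series(c(acc[1], diff(acc)), 2001)
  f <- fit_fgm(x, 1, form = "discrete")
  expect_equal(f$params$beta1, 1.1, tolerance = 1e-10)
  expect_equal(f$params$beta2, 2, tolerance = 1e-9)
  expect_equal(f$fitted, as.numeric(x), tolerance = 1e-8)
})

test_that("a constant series is reproduced by the discrete form and rejected by the continuous one", {
  x <- annual_series(rep(6, 8), 2001)
  fd <- fit_fgm(x, 1, form = "discrete")
  expect_equal(fd$fitted, rep(6, 8), tolerance = 1e-8)
  expect_equal(as.numeric(predict(fd, 3)), rep(6, 3), tolerance = 1e-8)
  # continuous time response needs a != 0, which a flat series cannot give
  expect_error(fit_fgm(x, 1, form = "continuous"))
})

test_that("fits anchor at the first observation", {
  x <- jingan_totals()
  expect_identical(fit_fgm(x, 0.9491)$fitted[1], as.numeric(x)[1])
  expect_identical(fit_fgm(x, 0.7, form = "discrete")$fitted[1],
                   as.numeric(x)[1])
})

test_that("fits are scale-equivariant", {
  x <- random_series(10, seed = 7)
  cx <- annual_series(3.5 * as.numeric(x), 2001)
  for (form in c("continuous", "discrete")) {
    f1 <- fit_fgm(x, 0.8, form = form)
    f2 <- fit_fgm(cx, 0.8, form = form)
    if (form == "continuous") {
      expect_equal(f2$params$a, f1$params$a, tolerance = 1e-9)
      expect_equal(f2$params$b, 3.5 * f1$params$b, tolerance = 1e-9)
    } else {
      expect_equal(f2$params$beta1, f1$params$beta1, tolerance = 1e-9)
      expect_equal(f2$params$beta2, 3.5 * f1$params$beta2, tolerance = 1e-9)
    }
    expect_equal(f2$fitted, 3.5 * f1$fitted, tolerance = 1e-8)
  }
})

test_that("GM(1,1) is near-exact on exponential data", {
  x <- annual_series(5 * exp(0.05 * (1:10)), 2001)
  f <- fit_gm11(x)
  expect_lt(mean(abs(f$fitted - as.numeric(x)) / as.numeric(x)) * 100, 0.1)
})

test_that("GM(1,1) hold-out predictions match the published comparison table", {
  train <- window_years(jingan_totals(), 2006, 2016)
  f <- fit_gm11(train)
  p <- predict(f, horizon = 4)
  expect_identical(years(p), 2017:2020)
  expect_equal(round(as.numeric(p), 2), c(95.41, 94.85, 94.30, 93.74))
})

test_that("continuous and discrete forms agree on near-exponential data", {
  fc <- fit_fgm(jingan_totals(), 0.9491, form = "continuous")
  fd <- fit_fgm(jingan_totals(), 0.9491, form = "discrete")
  expect_lt(max(abs(fc$fitted - fd$fitted) / fc$fitted), 0.005)
  # first-order relation between the two parameterizations at small a
  a <- fc$params$a
  expect_equal(fd$params$beta1, (1 - a / 2) / (1 + a / 2), tolerance = 1e-3)
})

test_that("short input and zero horizon are handled per contract", {
  expect_error(fit_gm11(annual_series(c(5, 6), 2001, validate = FALSE)),
               "at least 4")
  f <- fit_gm11(annual_series(5 * exp(0.1 * (1:8)), 2001))
  p0 <- predict(f, horizon = 0)
  expect_length(p0, 0)
})

test_that("a unit-root discrete fit continues the accumulated series arithmetically", {
  acc <- seq(10, by = 2, length.out = 8)     # x(k+1) = x(k) + 2
  x <- annual_series(c(acc[1], diff(acc)), 2001)
  f <- fit_fgm(x, 1, form = "discrete")
  expect_equal(f$params$beta1, 1, tolerance = 1e-9)
  expect_equal(as.numeric(predict(f, 3)), rep(2, 3), tolerance = 1e-8)
})

test_that("fit reports serialize to parseable JSON", {
  f <- fit_fgm(jingan_totals(), 0.9491)
  js <- jsonlite::fromJSON(fit_report_json(f, horizon = 2))
  expect_equal(js$r, 0.9491)
  expect_length(js$predicted, 2)
  expect_equal(js$fitted, f$fitted, tolerance = 1e-12)
  expect_identical(js$predicted_years, c(2021L, 2022L))
})
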