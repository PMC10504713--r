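# Shared fixtures: the bundled Shanghai panel (loaded once) and small
# generators used across test files.

fixture_panel <- load_district_panel()

jingan_totals <- function() panel_series(fixture_panel, "Jing'an", "totals")
jingan_elderly <- function() panel_series(fixture_panel, "Jing'an", "elderly")
xuhui_elderly <- function() panel_series(fixture_panel, "Xuhui", "elderly")

# positive random series for property loops
random_series <- function(n = 10, seed = 1, base = 50, jitter = 5) {
  set.seed(seed)
  annual_series(base + cumsum(stats::rnorm(n, 0, jitter / 3)) + jitter,
                2001, validate = FALSE)
}

# series whose background-value Verhulst equation
#   x(k) - x(k-1) + a z(k) = b z(k)^2,  z(k) = (x(k) + x(k-1)) / 2
# holds exactly: each step solves the implicit quadratic for x(k), so the
# least-squares Verhulst fit must recover (a, b) to solver tolerance.
verhulst_exact_series <- function(a, b, x1, n) {
  x <- numeric(n)
  x[1] <- x1
  for (k in 2:n) {
    p <- x[k - 1]
    # (b/4) u^2 - (1 + a/2) u + 2 p = 0, u = x(k) + p; root continuous in b -> 0
    disc <- (1 + a / 2)^2 - 2 * p * b
    stopifnot(disc > 0)
    u <- ((1 + a / 2) - sqrt(disc)) * 2 / b
    x[k] <- u - p
  }
  x
}
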