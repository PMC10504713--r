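#' District names of the bundled Shanghai panel
#'
#' The 16 administrative districts, in the order used throughout the panel
#' (Huangpu through Chongming).
#'
#' @return character vector of length 16.
#' @export
shanghai_districts <- function() {
  c("Huangpu", "Xuhui", "Changning", "Jing'an", "Putuo", "Hongkou",
    "Yangpu", "Minhang", "Baoshan", "Jiading", "Pudongxin", "Jinshan",
    "Songjiang", "Qingpu", "Fengxian", "Chongming")
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "greytheta")
  if (!nzchar(p)) stop("bundled data file not found: ", file)
  p
}

## verify a bundled file against the checksum manifest shipped alongside it
check_fixture <- function(file) {
  man <- jsonlite::read_json(extdata_path("manifest.json"))
  path <- extdata_path(file)
  expected <- man[[file]]
  if (is.null(expected)) stop("fixture not listed in manifest: ", file)
  got <- unname(tools::md5sum(path))
  if (!identical(got, expected))
    stop("fixture checksum mismatch for ", file,
         " (file corrupted or modified); expected ", expected, ", got ", got)
  path
}

#' Shanghai district population panel, 2006-2020
#'
#' Annual permanent-resident totals and 60+ (elderly) counts for the 16
#' districts of Shanghai, 2006-2020, in units of 10^4 persons, transcribed
#' from the Shanghai Statistical Yearbook figures used in the case study.
#' Files are verified against a checksum manifest on every load.
#'
#' @return an object of class `district_panel`: list with `years`
#'   (2006:2020), `districts` (16 names), and matrices `totals` and
#'   `elderly` (years x districts).
#' @examples
#' \donttest{
#' panel <- load_district_panel()
#' panel$totals["2006", "Jing'an"]   # 100.82
#' }
#' @export
load_district_panel <- function() {
  read_mat <- function(file) {
    df <- utils::read.csv(check_fixture(file), check.names = FALSE)
    m <- as.matrix(df[, -1L])
    rownames(m) <- df$year
    m
  }
  totals <- read_mat("shanghai_totals.csv")
  elderly <- read_mat("shanghai_elderly.csv")
  stopifnot(identical(colnames(totals), shanghai_districts()),
            identical(dim(totals), dim(elderly)))
  if (any(elderly > totals))
    stop("district panel: elderly counts exceed totals (corrupt fixture)")
  structure(list(years = as.integer(rownames(totals)),
                 districts = colnames(totals),
                 totals = totals, elderly = elderly),
            class = "district_panel")
}

#' @export
print.district_panel <- function(x, ...) {
  cat(sprintf("Shanghai district panel: %d districts, %d-%d (10^4 persons)\n",
              length(x$districts), min(x$years), max(x$years)))
  invisible(x)
}

#' One district series from the panel
#'
#' @param panel a `district_panel` from [load_district_panel()].
#' @param district district name (see [shanghai_districts()]).
#' @param what `"totals"` or `"elderly"`.
#' @return an [annual_series()].
#' @export
panel_series <- function(panel, district, what = c("totals", "elderly")) {
  what <- match.arg(what)
  stopifnot(inherits(panel, "district_panel"))
  if (!district %in% panel$districts) stop("unknown district: ", district)
  annual_series(panel[[what]][, district], panel$years[1L],
                paste(district, what))
}

#' Shanghai elderly age-structure table, 2006-2020
#'
#' City-level totals and elderly age-band counts (60+, 60-69, 70-79, 80+),
#' 2006-2020, 10^4 persons.
#'
#' @return data.frame with columns `year`, `total_population`, `age60plus`,
#'   `age60_69`, `age70_79`, `age80plus`.
#' @export
load_age_structure <- function() {
  df <- utils::read.csv(check_fixture("shanghai_age_structure.csv"))
  bands <- c("age60_69", "age70_79", "age80plus")
  if (any(df$age60plus < df[, bands]))
    stop("age structure: a sub-band exceeds the 60+ total (corrupt fixture)")
  df
}

#' Synthetic annual series for property tests
#'
#' Reproducible generators of known-structure series:
#' * `exponential`: `c0 * exp(g * k)`, `k = 1..n` (params `c0`, `g`);
#' * `logistic`: `L / (1 + exp(-k * (t - t0)))` (params `L`, `k`, `t0`);
#' * `grey_exact`: the exponential grey response at order `r` whose
#'   accumulated sequence satisfies the background-value difference equation
#'   `x(k) - x(k-1) + a z(k) = b` exactly (params `a`, `b`, `x1`, `r`), so
#'   the least-squares fit recovers `(a, b)` to solver tolerance;
#' * `noisy_grey`: `grey_exact` with multiplicative Gaussian noise of
#'   coefficient of variation `cv` (seeded; `cv = 0` reproduces
#'   `grey_exact` exactly).
#'
#' @param kind generator name.
#' @param params named list of generator parameters (see above; missing
#'   entries take the defaults documented in `formals`-style below:
#'   `c0 = 10, g = 0.05, L = 100, k = 0.3, t0 = (n+1)/2, a = 0.05, b = 10,
#'   x1 = 10, r = 1, cv = 0.05`).
#' @param n series length (>= 4).
#' @param seed integer seed (used by `noisy_grey` only).
#' @param start_year first calendar year of the output.
#' @return an [annual_series()].
#' @examples
#' x <- generate_synthetic("grey_exact", list(a = 0.05, b = 10), n = 12)
#' fit_gm11(x)$params$a
#' @export
generate_synthetic <- function(kind = c("exponential", "logistic",
                                        "grey_exact", "noisy_grey"),
                               params = list(), n = 12L, seed = 1L,
                               start_year = 2001L) {
  if (!is.character(kind) || !kind[1L] %in%
      c("exponential", "logistic", "grey_exact", "noisy_grey"))
    stop("generate_synthetic: unknown kind '", kind[1L], "'")
  kind <- kind[1L]
  n <- as.integer(n)
  if (n < 4L) stop("generate_synthetic: n must be at least 4")
  p <- utils::modifyList(list(c0 = 10, g = 0.05, L = 100, k = 0.3,
                              t0 = (n + 1) / 2, a = 0.05, b = 10,
                              x1 = 10, r = 1, cv = 0.05), params)
  vals <- switch(kind,
    exponential = p$c0 * exp(p$g * seq_len(n)),
    logistic = p$L / (1 + exp(-p$k * (seq_len(n) - p$t0))),
    grey_exact = grey_exact_series(p$a, p$b, p$x1, p$r, n),
    noisy_grey = {
      base <- grey_exact_series(p$a, p$b, p$x1, p$r, n)
      if (p$cv == 0) base
      else with_seed(seed, base * (1 + p$cv * stats::rnorm(n)))
    })
  if (any(vals <= 0))
    stop("generate_synthetic: parameters produced a non-positive series")
  annual_series(vals, start_year, sprintf("synthetic %s", kind))
}

## accumulated sequence satisfying x(k) - x(k-1) + a*(x(k)+x(k-1))/2 = b
## exactly, restored to the original scale at order r
grey_exact_series <- function(a, b, x1, r, n) {
  acc <- numeric(n)
  acc[1L] <- x1
  for (k in 2:n) acc[k] <- ((1 - a / 2) * acc[k - 1L] + b) / (1 + a / 2)
  frac_difference_num(acc, r)
}

#' Forecast every district of the panel with GT-FGM
#'
#' Fits the GT-FGM pipeline independently to each district's full 2006-2020
#' series (hyperparameters re-optimized per district) and extrapolates to
#' `to_year`. Per-district searches use child seeds `seed + column index`,
#' so the panel run is reproducible while districts stay independent.
#'
#' @param panel a `district_panel`.
#' @param what `"totals"` or `"elderly"`.
#' @param to_year last forecast year (> last panel year).
#' @param seed base integer seed.
#' @param control a [pso_control()].
#' @return matrix of forecasts (rows: years after the sample through
#'   `to_year`; columns: districts).
#' @export
forecast_panel <- function(panel, what = c("totals", "elderly"),
                           to_year = 2030L, seed = 1L,
                           control = pso_control()) {
  what <- match.arg(what)
  stopifnot(inherits(panel, "district_panel"))
  last <- max(panel$years)
  h <- as.integer(to_year) - last
  if (h < 1L) stop("forecast_panel: to_year must exceed the panel's last year")
  out <- sapply(seq_along(panel$districts), function(i) {
    s <- panel_series(panel, panel$districts[i], what)
    fit <- gt_fgm(s, control = control, seed = as.integer(seed) + i)
    as.numeric(predict(fit, horizon = h))
  })
  rownames(out) <- as.character((last + 1L):to_year)
  colnames(out) <- panel$districts
  out
}

#' Forecast elderly population density per district
#'
#' Density is the ratio of the elderly forecast to the total-population
#' forecast for each district-year, each produced by an independent GT-FGM
#' run, expressed as a percentage.
#'
#' @inheritParams forecast_panel
#' @param totals,elderly optional pre-computed forecast matrices from
#'   [forecast_panel()] (same shape); computed if `NULL`.
#' @return matrix of densities in percent (rows: forecast years; columns:
#'   districts).
#' @export
forecast_density <- function(panel, to_year = 2030L, seed = 1L,
                             control = pso_control(),
                             totals = NULL, elderly = NULL) {
  if (is.null(totals))
    totals <- forecast_panel(panel, "totals", to_year, seed, control)
  if (is.null(elderly))
    elderly <- forecast_panel(panel, "elderly", to_year, seed, control)
  stopifnot(identical(dim(totals), dim(elderly)))
  if (any(totals == 0)) stop("forecast_density: zero total-population forecast")
  elderly / totals * 100
}
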