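test_that("the bundled panel matches the published tables spot-checked", {
  p <- fixture_panel
  expect_identical(dim(p$totals), c(15L, 16L))
  expect_identical(p$years, 2006:2020)
  expect_identical(p$districts, shanghai_districts())
  expect_equal(p$totals["2006", "Jing'an"], 100.82)
  expect_equal(p$totals["2020", "Pudongxin"], 312.66)
  expect_equal(p$elderly["2020", "Xuhui"], 33.48)
  expect_equal(p$elderly["2006", "Huangpu"], 19.78)
  expect_true(all(p$elderly <= p$totals))
})

test_that("the age-structure table is coherent and spot-checked", {
  a <- load_age_structure()
  expect_identical(nrow(a), 15L)
  expect_equal(a$age60plus[a$year == 2020], 533.49)
  expect_equal(a$total_population[a$year == 2020], 1478.09)
  for (band in c("age60_69", "age70_79", "age80plus"))
    expect_true(all(a$age60plus >= a[[band]]))
})

test_that("fixture files verify against the checksum manifest", {
  man <- jsonlite::read_json(system.file("extdata", "manifest.json",
                                         package = "greytheta"))
  expect_setequal(names(man),
                  c("shanghai_totals.csv", "shanghai_elderly.csv",
                    "shanghai_age_structure.csv"))
  for (f in names(man)) {
    path <- system.file("extdata", f, package = "greytheta")
    expect_identical(unname(tools::md5sum(path)), man[[f]])
  }
  # a corrupted copy is rejected by the same check the loaders use
  expect_error(greytheta:::check_fixture("manifest.json"), "not listed")
})

test_that("panel series extraction labels and aligns correctly", {
  s <- panel_series(fixture_panel, "Qingpu", "elderly")
  expect_identical(years(s), 2006:2020)
  expect_equal(as.numeric(s)[15], 16.57)
  expect_match(attr(s, "label"), "Qingpu")
  expect_error(panel_series(fixture_panel, "Atlantis"), "unknown district")
})

test_that("synthetic generators are reproducible and well-defined", {
  a <- generate_synthetic("noisy_grey", list(cv = 0.05), n = 10, seed = 7)
  b <- generate_synthetic("noisy_grey", list(cv = 0.05), n = 10, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  c_ <- generate_synthetic("noisy_grey", list(cv = 0.05), n = 10, seed = 8)
  expect_false(identical(as.numeric(a), as.numeric(c_)))
  # zero noise reproduces the exact generator for any seed
  g0 <- generate_synthetic("noisy_grey", list(cv = 0), n = 10, seed = 3)
  ge <- generate_synthetic("grey_exact", n = 10, seed = 99)
  expect_identical(as.numeric(g0), as.numeric(ge))
  expect_error(generate_synthetic("fractal"), "unknown kind")
  expect_error(generate_synthetic("exponential", n = 3), "at least 4")
})

test_that("synthetic generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_synthetic("noisy_grey", n = 8, seed = 5))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("density is the element-wise forecast ratio in percent", {
  tot <- matrix(c(80, 40), 2, 2, dimnames = list(2021:2022, c("A", "B")))
  eld <- matrix(c(40, 40), 2, 2, dimnames = list(2021:2022, c("A", "B")))
  d <- forecast_density(fixture_panel, totals = tot, elderly = eld)
  expect_equal(d[, "A"], c("2021" = 50, "2022" = 100))
  zero <- eld * 0
  expect_equal(unname(forecast_density(fixture_panel, totals = tot,
                                       elderly = zero)[1, ]), c(0, 0))
  expect_error(forecast_density(fixture_panel, totals = tot * 0,
                                elderly = eld), "zero total")
})
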