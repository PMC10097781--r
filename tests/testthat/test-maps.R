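test_that("map interpolant reproduces node values exactly", {
  tb <- seq(-30, 30, by = 15); td <- seq(60, 150, by = 15)
  vals <- outer(tb, td, function(b, d) sin(b / 20) + cos(d / 40))
  mp <- helix_map(tb, td, vals)
  f <- map_interpolant(mp)
  for (i in seq_along(tb)) for (j in seq_along(td))
    expect_equal(f(tb[i], td[j]), vals[i, j], tolerance = 1e-12)
})

test_that("optima of analytic surfaces are recovered within half grid spacing", {
  tb <- seq(-30, 30, by = 5); td <- seq(70, 130, by = 5)
  vals <- outer(tb, td, function(b, d) -(b - 5)^2 - (d - 100)^2)
  mp <- helix_map(tb, td, vals)
  opt <- find_optimal_point(mp, "max")
  expect_lt(abs(opt$tau_bar - 5), 0.5)
  expect_lt(abs(opt$tau_diff - 100), 0.5)
  expect_false(opt$boundary)
  # duality: min of the negated surface is the same point
  mneg <- helix_map(tb, td, -vals)
  opt2 <- find_optimal_point(mneg, "min")
  expect_equal(opt2$tau_bar, opt$tau_bar, tolerance = 0.5)
  expect_equal(opt2$value, -opt$value, tolerance = 1e-6)
  # monotone surface: optimum flagged on the hull edge
  mono <- helix_map(tb, td, outer(tb, td, function(b, d) b + 0 * d))
  opt3 <- find_optimal_point(mono, "max")
  expect_true(opt3$boundary)
  expect_equal(opt3$tau_bar, max(tb), tolerance = 1e-3)
  expect_error(find_optimal_point(helix_map(tb, td, 0 * vals)), "flat")
})

test_that("SSIM has its identity, continuity and error contracts", {
  tb <- seq(-30, 30, by = 15); td <- seq(60, 150, by = 15)
  vals <- outer(tb, td, function(b, d) b * d / 1000)
  a <- helix_map(tb, td, vals)
  expect_equal(map_ssim(a, a), 1)
  set.seed(5)
  b <- helix_map(tb, td, vals + rnorm(length(vals), 0, 1e-10))
  expect_gt(map_ssim(a, b), 0.999999)
  c_ <- helix_map(tb, td, -vals)
  expect_lt(map_ssim(a, c_), map_ssim(a, b))
  other <- helix_map(tb + 1, td, vals)
  expect_error(map_ssim(a, other), "grids")
})

test_that("sweeps mask failures, bound the failure rate, and match direct runs", {
  ev <- function(cfg) {
    if (cfg$tau_bar == 0 && cfg$tau_diff == 120) stop("synthetic failure")
    list(m1 = cfg$tau_bar + cfg$tau_diff, m2 = cfg$tau_bar * cfg$tau_diff)
  }
  maps <- sweep_helix_map(ev, c(-15, 0, 15), c(105, 120, 135))
  expect_true(is.na(maps$m1$values[2, 2]))
  expect_equal(maps$m1$values[1, 1], -15 + 105)
  expect_equal(length(attr(maps, "failures")), 1L)
  # single-point grid equals the direct metric
  one <- sweep_helix_map(function(cfg) list(m = 42), 10, 123)
  expect_equal(one$m$values[1, 1], 42)
  # too many failures -> error
  expect_error(sweep_helix_map(function(cfg) stop("no"), c(0, 15), c(100, 120)),
               "failed")
})

test_that("map export writes both CSV and JSON faithfully", {
  tb <- c(-15, 0, 15); td <- c(105, 120)
  mp <- helix_map(tb, td, matrix(1:6, 3, 2), metric = "stroke_work")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_helix_map(mp, csv, js, optimum = list(tau_bar = 0, tau_diff = 120))
  back <- read.csv(csv)
  expect_equal(back$value, as.vector(mp$values))
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$metric, "stroke_work")
  expect_equal(matrix(unlist(j$values), 3, 2), unname(mp$values))
})
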