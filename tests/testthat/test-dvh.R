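test_that("cumulative DVH matches direct voxel enumeration", {
  g <- tiny_grid(2)  # 8 voxels
  arr <- array(c(rep(50, 4), rep(60, 4)), g$shape)
  dvh <- compute_dvh(dose_grid(arr, g), full_mask(g), bin_width = 1)
  expect_equal(dvh$cum_volume[1], 1)
  expect_true(all(diff(dvh$cum_volume) <= 0))
  # V(55 Gy) = half the volume
  k <- findInterval(55, dvh$bin_edges)
  expect_equal(dvh$cum_volume[k], 0.5)
  # uniform dose: all volume below the dose, none above
  dvh_u <- compute_dvh(uniform_dose(60), full_mask(), bin_width = 0.06)
  expect_equal(dvh_u$cum_volume[findInterval(59.9, dvh_u$bin_edges)], 1)
  expect_equal(dvh_u$cum_volume[findInterval(60.2, dvh_u$bin_edges)], 0)
})

test_that("DVH rejects empty masks and mismatched grids", {
  g <- tiny_grid()
  empty <- structure_mask(array(FALSE, g$shape), g)
  expect_error(compute_dvh(uniform_dose(60, g), empty, 0.1), "empty")
  g2 <- grid_spec(g$shape, g$spacing * 2)
  expect_error(compute_dvh(uniform_dose(60, g), full_mask(g2), 0.1), "mismatch")
})

test_that("dose percentiles are monotone and match enumeration", {
  g <- tiny_grid(2)
  arr <- array(c(rep(50, 4), rep(60, 4)), g$shape)
  dvh <- compute_dvh(dose_grid(arr, g), full_mask(g), bin_width = 0.1)
  expect_lt(abs(dose_percentile(dvh, 98) - 50), 0.2)
  expect_gte(dose_percentile(dvh, 50), 50)
  xs <- c(1, 25, 50, 75, 98, 99.9, 100)
  ds <- vapply(xs, function(x) dose_percentile(dvh, x), numeric(1))
  expect_true(all(diff(ds) <= 1e-9))  # x1 < x2 => Dx1 >= Dx2
  dvh_u <- compute_dvh(uniform_dose(60), full_mask(), bin_width = 0.06)
  expect_lt(abs(dose_percentile(dvh_u, 50) - 60), 0.1)
  # D100 is the minimum binned dose
  expect_lt(abs(dose_percentile(dvh, 100) - 50), 0.2)
  expect_error(dose_percentile(dvh, 0), "0, 100")
  expect_error(dose_percentile(dvh, 101), "0, 100")
})

test_that("d_min finds the minimum voxel with deterministic tie-break", {
  g <- tiny_grid()
  expect_equal(d_min(uniform_dose(42, g), full_mask(g))$dose, 42)
  expect_equal(d_min(uniform_dose(42, g), full_mask(g))$index, 1L)
  arr <- array(60, g$shape); arr[3, 4, 5] <- 30
  dm <- d_min(dose_grid(arr, g), full_mask(g))
  expect_equal(dm$dose, 30)
  expect_equal(as.integer(dm$ijk), c(3L, 4L, 5L))
  # brute force on random grids
  set.seed(1)
  for (rep in 1:5) {
    arr <- array(runif(prod(g$shape), 30, 70), g$shape)
    m <- array(runif(prod(g$shape)) < 0.4, g$shape)
    if (!any(m)) next
    dm <- d_min(dose_grid(arr, g), structure_mask(m, g))
    expect_equal(dm$dose, min(arr[m]))
  }
  expect_error(d_min(uniform_dose(1, g), structure_mask(array(FALSE, g$shape), g)),
               "empty")
})

test_that("gEUD reproduces the power-mean and its limits", {
  dvh_u <- compute_dvh(uniform_dose(57.3), full_mask(), bin_width = 0.06)
  for (a in c(-100, -20, -5, 1, 2)) {
    expect_equal(geud(dvh_u, a), 57.3, tolerance = 1e-9)
  }
  g <- tiny_grid(2)
  arr <- array(c(rep(60, 4), rep(30, 4)), g$shape)
  dvh <- compute_dvh(dose_grid(arr, g), full_mask(g), 0.06)
  expect_equal(geud(dvh, -20), (0.5 * 60^-20 + 0.5 * 30^-20)^(-1 / 20),
               tolerance = 1e-9)
  expect_equal(geud(dvh, 1), 45, tolerance = 1e-9)  # arithmetic mean
  # monotone approach to the minimum as a decreases
  gs <- vapply(c(-5, -20, -100), function(a) geud(dvh, a), numeric(1))
  expect_true(all(diff(gs) < 0))
  expect_true(all(gs > 30) && all(gs < 45))
  expect_error(geud(dvh, 0), "nonzero")
  # zero-dose bin with a < 0 dominates
  arr[1, 1, 1] <- 0
  dvh0 <- compute_dvh(dose_grid(arr, g), full_mask(g), 0.06)
  expect_warning(g0 <- geud(dvh0, -20), "zero-dose")
  expect_equal(g0, 0)
})

test_that("SF2 calibration solves the Poisson TCP condition", {
  expect_equal(calibrate_sf2(0.5, 60, 2, 1e8), 0.534598229, tolerance = 1e-8)
  # n0 = 1, tcp = 1/e forces sf2 = 1 boundary of the model
  expect_equal(calibrate_sf2(exp(-1), 30, 2, 1), 1, tolerance = 1e-12)
  # single fraction closed form
  expect_equal(calibrate_sf2(0.5, 2, 2, 1e8), log(2) / 1e8, tolerance = 1e-18)
  expect_error(calibrate_sf2(1.2, 60, 2, 1e8), "0,1")
  expect_error(calibrate_sf2(0.5, 61, 2, 1e8), "whole number")
})

test_that("survival EUD is the identity on uniform dose and matches a grid-search oracle", {
  p <- sf_model_params(sf2 = 0.534598229, alpha_beta = 4, n_fractions = 30)
  dvh2 <- compute_dvh(uniform_dose(2), full_mask(), bin_width = 0.002)
  expect_equal(eud_sf(dvh2, p), 60, tolerance = 1e-6)
  dvh18 <- compute_dvh(uniform_dose(1.8), full_mask(), bin_width = 0.002)
  expect_equal(eud_sf(dvh18, p), 54, tolerance = 1e-6)
  # calibration round trip: uniform prescription-scale DVH returns prescription
  p_cal <- sf_model_params(sf2 = calibrate_sf2(0.5, 60, 2, 1e8))
  expect_equal(eud_sf(dvh2, p_cal), 60, tolerance = 1e-6)

  # two-bin DVH vs dense grid-search oracle over the uniform dose
  g <- tiny_grid(2)
  arr <- array(c(rep(2.0, 4), rep(1.2, 4)), g$shape)
  dvh <- compute_dvh(dose_grid(arr, g), full_mask(g), 0.002)
  got <- eud_sf(dvh, p)
  s <- function(d) p$sf2^((d / 2) * (4 + d) / 6)
  S <- 0.5 * s(2.0)^30 + 0.5 * s(1.2)^30
  du_grid <- seq(0.5, 2.5, by = 1e-5)
  oracle <- 30 * du_grid[which.min(abs(s(du_grid)^30 - S))]
  expect_equal(got, oracle, tolerance = 0.01)

  # uncorrected variant: plain sf2^(d/2) scaling
  got_u <- eud_sf(dvh, p, fraction_size_correction = FALSE)
  su <- function(d) p$sf2^(d / 2)
  Su <- 0.5 * su(2.0)^30 + 0.5 * su(1.2)^30
  oracle_u <- 30 * 2 * log(Su^(1 / 30)) / log(p$sf2)
  expect_equal(got_u, oracle_u, tolerance = 1e-6)
})

test_that("gEUD and survival EUD rank fractions consistently", {
  # property over perturbed distributions: both measures are strongly
  # rank-correlated, as expected when both penalize the same cold spots
  set.seed(7)
  g <- tiny_grid(4)
  p <- sf_model_params()
  vals <- t(replicate(30, {
    base <- 60 * runif(1, 0.95, 1.03)
    arr <- array(base, g$shape)
    ncold <- sample(0:10, 1)
    if (ncold > 0) arr[sample(prod(g$shape), ncold)] <- 60 * runif(ncold, 0.5, 1)
    dvh <- compute_dvh(dose_grid(arr, g), full_mask(g), 0.06)
    dvh$bin_edges <- dvh$bin_edges * 2 / 60
    dvh$bin_dose <- dvh$bin_dose * 2 / 60
    c(geud(dvh, -20) / 60, eud_sf(dvh, p) / 60)
  }))
  expect_gt(spearman_rank(vals[, 1], vals[, 2])$rho, 0.9)
})
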