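test_that("field inversion is exact for trivial fields and tight for smooth ones", {
  g <- grid_spec(c(32, 32, 32), c(2, 2, 2))
  inv0 <- invert_field(zero_field(g))
  expect_true(all(unclass(inv0$field) == 0))
  expect_equal(inv0$rms_mm, 0)
  # constant translation inverts to the negated translation
  invt <- invert_field(constant_field(g, c(3, -1, 2)))
  interior <- unclass(invt$field)[5:28, 5:28, 5:28, ]
  expect_equal(max(abs(interior[, , , 1] + 3)), 0, tolerance = 1e-6)
  expect_equal(max(abs(interior[, , , 2] - 1)), 0, tolerance = 1e-6)
  expect_equal(max(abs(interior[, , , 3] + 2)), 0, tolerance = 1e-6)
  # smooth random field: composition residual under 0.1 mm RMS
  f <- generate_fraction_field(g, c(0, 0, 0), c(3, 3, 3), 30, seed = 21)
  inv <- invert_field(f)
  expect_lt(inv$rms_mm, 0.1)
})

test_that("dose pullback shifts a step dose and respects interpolation bounds", {
  g <- grid_spec(c(24, 24, 24), c(2, 2, 2))
  # zero field: identity, voxel exact
  arr <- array(runif(prod(g$shape), 30, 70), g$shape)
  dose <- dose_grid(arr, g)
  expect_identical(unclass(pullback_dose(dose, zero_field(g)))[1:24, 1:24, 1:24],
                   arr)
  # 2-voxel translation of a z-step moves the step by 2 voxels
  step <- array(0, g$shape); step[, , 13:24] <- 60
  stepd <- dose_grid(step, g)
  pb <- suppressWarnings(pullback_dose(stepd, constant_field(g, c(0, 0, 4))))
  expect_equal(unclass(pb)[1:24, 1:24, 1:22], step[, , 3:24])
  # interpolation convexity: bounded by the input range
  f <- generate_fraction_field(g, c(1, 1, 1), c(2, 2, 2), 20, seed = 3)
  pb2 <- suppressWarnings(pullback_dose(dose, f))
  expect_gte(min(pb2), min(arr))
  expect_lte(max(pb2), max(arr))
})

test_that("accumulation is the identity for zero deformation", {
  cfg0 <- cohort_config(n_patients = 1, fractions_range = c(4, 4),
                        ctv_volume_range = c(40, 50),
                        systematic_sd = c(0, 0, 0), random_sd = c(0, 0, 0),
                        large_excursion_prob = 0,
                        grid = grid_spec(c(32, 32, 32), c(2.5, 2.5, 2.5)),
                        seed = 31L)
  s <- generate_cohort(cfg0)[[1]]
  acc <- accumulate_dose(s)
  expect_equal(unclass(acc$dose)[1:32, 1:32, 1:32],
               unclass(s$plan_dose)[1:32, 1:32, 1:32], tolerance = 1e-12)
  dvh <- compute_dvh(s$plan_dose, s$ctv_plan, 0.06)
  expect_equal(acc$geud_acc_norm, geud(dvh, -20) / s$prescription,
               tolerance = 1e-9)
  # single fraction: accumulation equals the pullback of that fraction
  s1 <- s; s1$fractions <- s1$fractions[1]
  acc1 <- accumulate_dose(s1)
  expect_equal(unclass(acc1$dose)[1:32, 1:32, 1:32],
               unclass(pullback_dose(s$plan_dose, s$fractions[[1]]$field))[1:32, 1:32, 1:32])
})

test_that("accumulation averages away a single cold fraction", {
  # constructed 2-fraction series: one aligned, one shifted into the falloff;
  # the accumulated gEUD exceeds the worst per-fraction gEUD
  g <- grid_spec(c(40, 40, 40), c(2, 2, 2))
  ctv <- generate_ctv(g, 50, seed = 17)
  pl <- generate_plan_dose(ctv, 5, 60, 8, 3, plateau = 1.02)
  s <- list(patient_id = "T", grid = g, ctv_plan = ctv, plan_dose = pl$dose,
            prescription = 60,
            fractions = list(
              list(field = zero_field(g), ctv = ctv),
              list(field = constant_field(g, c(0, 0, 10)), ctv = ctv)))
  class(s) <- "patient_series"
  acc <- suppressWarnings(accumulate_dose(s))
  geud_i <- vapply(s$fractions, function(fr) {
    pb <- suppressWarnings(pullback_dose(s$plan_dose, fr$field))
    geud(compute_dvh(pb, ctv, 0.06), -20) / 60
  }, numeric(1))
  expect_gte(acc$geud_acc_norm, min(geud_i))
  # mass-like bounds
  expect_gte(min(acc$dose), 0)
  expect_lte(max(acc$dose), max(pl$dose) + 1e-9)
})

test_that("gamma analysis agrees with a brute-force oracle", {
  g <- grid_spec(c(10, 10, 10), c(2, 2, 2))
  set.seed(6)
  ref_arr <- array(60 * (0.7 + 0.3 * runif(1000)), g$shape)
  ev_arr <- ref_arr * array(1 + rnorm(1000, 0, 0.03), g$shape)
  ref <- dose_grid(ref_arr, g); ev <- dose_grid(ev_arr, g)
  roi <- full_mask(g)
  res <- gamma_pass_rate(ref, ev, roi, dta_mm = 3, dd = 0.03,
                         dose_threshold = 0.1, norm_dose = 60)
  # exhaustive R oracle over the same lattice search
  coords <- as.matrix(expand.grid(1:10, 1:10, 1:10)) * 2
  gam_oracle <- array(NA_real_, g$shape)
  for (l in seq_len(1000)) {
    p <- coords[l, ]
    if (ref_arr[l] < 6) next
    d2 <- colSums((t(coords) - p)^2)
    keep <- d2 <= 81  # search radius 9 mm = 3 * DTA
    gam_oracle[l] <- sqrt(min((ev_arr[keep] - ref_arr[l])^2 / (0.03 * 60)^2 +
                                d2[keep] / 9))
  }
  expect_equal(res$gamma[!is.na(res$gamma)], gam_oracle[!is.na(gam_oracle)],
               tolerance = 1e-9)
  expect_identical(res$gamma <= 1, gam_oracle <= 1)
  # identical distributions pass everywhere
  expect_equal(gamma_pass_rate(ref, ref, roi, norm_dose = 60)$pass_rate, 1)
  # a uniform +2% offset passes a 3%/3mm criterion at zero distance
  ev_off <- dose_grid(ref_arr + 0.02 * 60, g)
  expect_equal(gamma_pass_rate(ref, ev_off, roi, norm_dose = 60)$pass_rate, 1)
  expect_error(gamma_pass_rate(ref, ev, structure_mask(array(FALSE, g$shape), g)),
               "empty ROI")
})
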