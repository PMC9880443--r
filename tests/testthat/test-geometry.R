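test_that("hausdorff expansion equals brute force on constructed masks", {
  g <- grid_spec(c(20, 20, 20), c(2, 2, 2))
  cube <- box_mask(g, c(5, 5, 5), c(14, 14, 14))
  expect_equal(hausdorff_expansion(cube, cube)$hdd_mm, 0)
  inner <- box_mask(g, c(7, 7, 7), c(12, 12, 12))
  expect_equal(hausdorff_expansion(cube, inner)$hdd_mm, 0)  # containment
  shifted <- box_mask(g, c(5, 5, 8), c(14, 14, 17))  # 3 voxels = 6 mm along z
  h <- hausdorff_expansion(cube, shifted)
  expect_equal(h$hdd_mm, 6)
  expect_equal(h$hdd_mm, brute_hausdorff(cube, shifted))
  expect_error(hausdorff_expansion(cube, structure_mask(array(FALSE, g$shape), g)),
               "nonempty")
})

test_that("hausdorff expansion is translation-bounded", {
  # shifting ctv_i by t changes HDD by at most |t|
  g <- grid_spec(c(24, 24, 24), c(2, 2, 2))
  a <- box_mask(g, c(8, 8, 8), c(15, 15, 15))
  b <- box_mask(g, c(10, 9, 8), c(17, 16, 15))
  h0 <- hausdorff_expansion(a, b)$hdd_mm
  b1 <- box_mask(g, c(10, 9, 9), c(17, 16, 16))  # +2 mm along z
  h1 <- hausdorff_expansion(a, b1)$hdd_mm
  expect_lte(abs(h1 - h0), 2 + 1e-9)
})

test_that("worst Hausdorff fraction uses argmax with earliest-fraction ties", {
  mk <- function(hdd, pt) list(hdd_mm = hdd, point = pt, index = 1L)
  hs <- list(mk(3, c(0, 0, 0)), mk(7, c(1, 1, 1)), mk(5, c(2, 2, 2)))
  w <- hdp_worst(hs)
  expect_equal(w$fraction, 2L)
  expect_equal(w$point, c(1, 1, 1))
  hs_tie <- list(mk(4, c(9, 9, 9)), mk(4, c(1, 1, 1)))
  expect_equal(hdp_worst(hs_tie)$fraction, 1L)
  # linear-scan oracle on random lists
  set.seed(2)
  for (rep in 1:10) {
    hdds <- runif(8)
    hs <- lapply(hdds, function(h) mk(h, rnorm(3)))
    expect_equal(hdp_worst(hs)$fraction, which.max(hdds))
  }
  expect_error(hdp_worst(list()), "at least one")
})

test_that("point propagation and inversion are exact for constant translations", {
  g <- grid_spec(c(24, 24, 24), c(2, 2, 2))
  t_vec <- c(3, -2, 5)
  f <- constant_field(g, t_vec)
  dose <- dose_grid(array(rep(seq_len(24), each = 24 * 24) * 0 +
                            rep(1:24, each = 576), g$shape), g)
  p <- c(20, 20, 20)
  pr <- propagate_point(p, f, uniform_dose(60, g))
  expect_equal(pr$point, p + t_vec)
  expect_equal(pr$dose, 60)
  # inverse of a translation is exact
  q <- p + t_vec
  expect_equal(invert_point(q, f), p, tolerance = 1e-6)
  # zero field: fixed point
  expect_equal(invert_point(p, zero_field(g)), p)
})

test_that("propagated dose follows a linear ramp under a z shift", {
  # 3 %/mm ramp along z, 4 mm shift: dose drops 12% of prescription
  g <- grid_spec(c(16, 16, 32), c(2, 2, 2))
  z_mm <- (rep(1:32, each = 1) - 1) * 2
  frac <- 1 - 0.03 * z_mm
  arr <- array(rep(frac, each = 16 * 16), g$shape)
  dose <- dose_grid(60 * arr, g)
  f <- constant_field(g, c(0, 0, 4))
  p <- c(10, 10, 20)
  pr <- propagate_point(p, f, dose)
  expect_equal((sample_at(dose, p) - pr$dose) / 60, 0.12, tolerance = 1e-9)
  # trilinear convexity: sampled value within the 8 neighbour range
  set.seed(4)
  for (rep in 1:10) {
    pt <- runif(3, 5, 25)
    v <- sample_at(dose, pt)
    ijk0 <- floor(world_to_index(g, pt))
    nb <- expand.grid(0:1, 0:1, 0:1)
    vals <- apply(nb, 1, function(o) {
      idx <- pmin(pmax(ijk0 + as.numeric(o), 1), g$shape)
      unclass(dose)[idx[1], idx[2], idx[3]]
    })
    expect_gte(v, min(vals) - 1e-9)
    expect_lte(v, max(vals) + 1e-9)
  }
})

test_that("global minimum-dose point maps back through the inverse field", {
  g <- grid_spec(c(24, 24, 24), c(2, 2, 2))
  # dose ramp along z so the argmin is at the lowest z voxel of the mask
  arr <- array(rep(1:24, each = 576) * 1.0, g$shape)
  dose <- dose_grid(arr, g)
  ctv <- box_mask(g, c(8, 8, 8), c(16, 16, 16))
  # zero fields: PD_min_global is the planning argmin inside CTV_plan
  series0 <- list(plan_dose = dose, grid = g, prescription = 60,
                  fractions = list(list(field = zero_field(g), ctv = ctv),
                                   list(field = zero_field(g), ctv = ctv)))
  pg0 <- pd_min_global(series0)
  expect_equal(pg0$fraction, 1L)  # tie -> earliest
  expect_equal(pg0$point_plan, d_min(dose, ctv)$point)
  # constant translation: argmin point minus the translation
  t_vec <- c(4, 0, 6)
  ctv_shift <- box_mask(g, c(10, 8, 11), c(18, 16, 19))
  series1 <- list(plan_dose = dose, grid = g, prescription = 60,
                  fractions = list(list(field = constant_field(g, t_vec),
                                        ctv = ctv_shift)))
  pg1 <- pd_min_global(series1)
  expect_equal(pg1$point_plan, d_min(dose, ctv_shift)$point - t_vec,
               tolerance = 1e-6)
})

test_that("scalar projection onto the worst-fraction direction", {
  g <- grid_spec(c(8, 8, 8), c(2, 2, 2))
  p <- c(7, 7, 7)
  f_i <- constant_field(g, c(3, 0, 0))
  f_x <- constant_field(g, c(6, 8, 0))
  expect_equal(scalar_pdmin(p, f_i, f_x), 1.8)  # 18 / 10
  # projection of a vector on its own direction is its length
  expect_equal(scalar_pdmin(p, f_x, f_x), 10)
  # orthogonal vectors project to zero
  expect_equal(scalar_pdmin(p, constant_field(g, c(0, 0, 5)), f_x), 0)
  # |projection| <= |v_i|
  set.seed(5)
  for (rep in 1:10) {
    vi <- rnorm(3); vx <- rnorm(3)
    s <- scalar_pdmin(p, constant_field(g, vi), constant_field(g, vx))
    expect_lte(abs(s), sqrt(sum(vi^2)) + 1e-9)
  }
  expect_warning(s0 <- scalar_pdmin(p, f_i, zero_field(g)), "degenerate")
  expect_equal(s0, 0)
})

test_that("deformation length at the worst Hausdorff point", {
  g <- grid_spec(c(8, 8, 8), c(2, 2, 2))
  expect_equal(delta_l_hdp_worst(c(7, 7, 7), zero_field(g)), 0)
  expect_equal(delta_l_hdp_worst(c(7, 7, 7), constant_field(g, c(1.7, 3.0, 2.3))),
               sqrt(1.7^2 + 3.0^2 + 2.3^2))
  # norm invariant under axis permutation of the vector
  expect_equal(delta_l_hdp_worst(c(7, 7, 7), constant_field(g, c(2.3, 1.7, 3.0))),
               delta_l_hdp_worst(c(7, 7, 7), constant_field(g, c(1.7, 3.0, 2.3))))
})

test_that("variance decomposition separates systematic and random parts", {
  # identical vectors everywhere: both components zero
  d0 <- data.frame(patient = rep(1:3, each = 4), dx = 1, dy = 2, dz = 3)
  vd0 <- deformation_variance_decomposition(d0)
  expect_equal(unname(vd0$systematic_sd), c(0, 0, 0))
  expect_equal(unname(vd0$random_sd), c(0, 0, 0))
  # constant per-patient offsets: random 0, systematic = SD of the offsets
  d1 <- data.frame(patient = rep(1:2, each = 3),
                   dx = rep(c(1, 5), each = 3),
                   dy = rep(c(-2, 2), each = 3),
                   dz = rep(c(0, 3), each = 3))
  vd1 <- deformation_variance_decomposition(d1)
  expect_equal(unname(vd1$random_sd), c(0, 0, 0))
  expect_equal(unname(vd1$systematic_sd),
               c(sd(c(1, 5)), sd(c(-2, 2)), sd(c(0, 3))))
  expect_error(deformation_variance_decomposition(
    data.frame(patient = 1:2, dx = 1:2, dy = 1:2, dz = 1:2)), "single fraction")
})

test_that("feature extraction on a zero-deformation series is degenerate", {
  cfg0 <- cohort_config(n_patients = 1, fractions_range = c(3, 3),
                        ctv_volume_range = c(40, 50),
                        systematic_sd = c(0, 0, 0), random_sd = c(0, 0, 0),
                        large_excursion_prob = 0,
                        grid = grid_spec(c(32, 32, 32), c(2.5, 2.5, 2.5)),
                        seed = 13L)
  s <- generate_cohort(cfg0)[[1]]
  # degenerate reference direction warns; values must still be exact zeros
  ft <- suppressWarnings(extract_fraction_features(s))
  expect_equal(nrow(ft), 3)
  expect_equal(ft$hdd_mm, rep(0, 3))
  expect_equal(ft$dl_hdpworst_mm, rep(0, 3))
  expect_equal(ft$scalar_pdmin_mm, rep(0, 3))
  expect_equal(ft$d_pdmin_global, ft$d_min, tolerance = 1e-9)
  expect_equal(ft$geud, rep(ft$geud[1], 3))
})
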