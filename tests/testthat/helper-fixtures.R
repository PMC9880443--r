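# shared in-code fixtures for the test suite

tiny_grid <- function(n = 8, sp = 2) grid_spec(rep(n, 3), rep(sp, 3))

uniform_dose <- function(value, grid = tiny_grid()) {
  dose_grid(array(value, grid$shape), grid)
}

full_mask <- function(grid = tiny_grid()) {
  structure_mask(array(TRUE, grid$shape), grid)
}

box_mask <- function(grid, from, to) {
  a <- array(FALSE, grid$shape)
  a[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  structure_mask(a, grid)
}

random_blob_mask <- function(grid, n_seeds = 3, radius_vox = 2.5) {
  # union of balls around random seed voxels; nonempty by construction
  coords <- as.matrix(expand.grid(seq_len(grid$shape[1]),
                                  seq_len(grid$shape[2]),
                                  seq_len(grid$shape[3])))
  inside <- rep(FALSE, nrow(coords))
  for (s in seq_len(n_seeds)) {
    c0 <- sapply(grid$shape, function(n) sample.int(n, 1))
    inside <- inside | rowSums(sweep(coords, 2, c0)^2) <= radius_vox^2
  }
  structure_mask(array(inside, grid$shape), grid)
}

constant_field <- function(grid, v) {
  f <- array(0, c(grid$shape, 3))
  for (c in 1:3) f[, , , c] <- v[c]
  displacement_field(f, grid)
}

zero_field <- function(grid) constant_field(grid, c(0, 0, 0))

# O(N^2) brute-force directed Hausdorff oracle (max over b of min dist to a)
brute_hausdorff <- function(ctv_plan, ctv_i) {
  g <- grid_of(ctv_plan)
  pa <- index_to_world(g, ijk_of_linear_test(g, which(as.logical(ctv_plan))))
  pb <- index_to_world(g, ijk_of_linear_test(g, which(as.logical(ctv_i))))
  d2 <- outer(rowSums(pb^2), rowSums(pa^2), "+") - 2 * pb %*% t(pa)
  max(sqrt(pmax(apply(d2, 1, min), 0)))
}

ijk_of_linear_test <- function(grid, l) {
  s <- grid$shape
  l0 <- l - 1L
  cbind(l0 %% s[1], (l0 %/% s[1]) %% s[2], l0 %/% (s[1] * s[2])) + 1L
}

# small cohort reused across test files (built once per test run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_patients = 3, fractions_range = c(4, 6),
                           ctv_volume_range = c(60, 100),
                           grid = grid_spec(c(40, 40, 40), c(2.5, 2.5, 2.5)),
                           large_excursion_prob = 0.2, seed = 42L)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

# feature table where the target is a noisy monotone function of d_min:
# the synthetic functional-relationship cohort for the prediction study
make_prediction_table <- function(n_patients = 10, n_frac = 22, seed = 1,
                                  noise_sd = 0.01) {
  set.seed(seed)
  rows <- lapply(seq_len(n_patients), function(p) {
    mu <- runif(1, 0.6, 0.95)
    d_min <- pmin(pmax(rnorm(n_frac, mu, 0.15), 0.35), 1.05)
    # smooth monotone dose-effect shape: stable plateau above ~0.95,
    # steep decline below, spanning the clinically observed range
    geud <- 1.02 - 0.45 * (1 - pmin(d_min / 0.95, 1))^1.3 +
      rnorm(n_frac, 0, noise_sd)
    data.frame(patient_id = sprintf("P%02d", p), fraction = seq_len(n_frac),
               d_min = d_min, geud = geud,
               scalar_pdmin_mm = 5 * (1 - d_min) + rnorm(n_frac, 0, 2),
               d_pdmin_global = d_min + rnorm(n_frac, 0, 0.1),
               hdd_mm = runif(n_frac, 2, 12),
               dl_hdpworst_mm = runif(n_frac, 0, 10),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
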