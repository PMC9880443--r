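test_that("cold-fraction weights follow the banded rule", {
  expect_equal(make_weights(c(0.85, 0.92, 1.01)), c(10, 2, 1))
  expect_equal(make_weights(c(0.899999, 0.90, 0.949999, 0.95)),
               c(10, 2, 2, 1))
  expect_error(make_weights(c(0.9, NA)), "finite")
})

test_that("Fisher-transform confidence intervals match the closed form", {
  x <- seq_len(10); y <- 2 * x
  pc <- pearson_with_fisher_ci(x, y)
  expect_equal(pc$r, 1)
  # frozen closed-form values: n = 103, r = 0.5
  set.seed(1)
  n <- 103
  # construct data with exactly r = 0.5 via Gram-Schmidt
  a <- rnorm(n); b <- rnorm(n)
  b <- residuals(lm(b ~ a)); b <- b / sd(b) * sqrt(1 - 0.5^2)
  y2 <- 0.5 * scale(a)[, 1] + b
  pc2 <- pearson_with_fisher_ci(scale(a)[, 1], y2)
  expect_equal(pc2$r, 0.5, tolerance = 1e-9)
  expect_equal(pc2$lo, 0.339313, tolerance = 1e-4)
  expect_equal(pc2$hi, 0.632337, tolerance = 1e-4)
  # symmetry under swapping
  expect_equal(pearson_with_fisher_ci(y2, scale(a)[, 1])$r, pc2$r)
  expect_error(pearson_with_fisher_ci(rep(1, 10), seq_len(10)), "constant")
})

test_that("Steiger's Z behaves correctly in the degenerate directions", {
  z0 <- steiger_z_dependent(0.6, 0.6, 0.4, 100)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  z1 <- steiger_z_dependent(0.7, 0.5, 0.4, 100)
  z2 <- steiger_z_dependent(0.5, 0.7, 0.4, 100)
  expect_equal(z1$z, -z2$z)
  expect_equal(z1$p, z2$p)
  expect_gt(z1$z, 0)
  expect_lt(z1$p, 0.05)  # clearly different correlations at n = 100
  expect_error(steiger_z_dependent(1, 0.5, 0.4, 100))
})

test_that("cross-validated variance explained matches hand computation", {
  y <- c(1, 2, 3, 4)
  expect_equal(ve_cv(y, y), 1)
  expect_equal(ve_cv(y, rep(mean(y), 4)), 0)
  expect_equal(ve_cv(y, c(1.1, 1.9, 3.2, 3.9)), 1 - 0.07 / 5)
  expect_lt(ve_cv(y, rev(y)), 0)  # worse than the mean predictor
  expect_error(ve_cv(rep(2, 4), y), "constant")
})

test_that("stepwise polynomial fit recovers the generating degree", {
  set.seed(11)
  x <- runif(120, -2, 2)
  y <- x^3 + rnorm(120, 0, 0.3)
  fit <- stepwise_poly_fit(x, y)
  expect_equal(fit$degree, 3L)
  expect_gt(fit$r_squared, 0.9)
  expect_gt(fit$f_value, 10)
  # exactly linear data
  fit_lin <- stepwise_poly_fit(x, 2 * x + 1)
  expect_equal(fit_lin$degree, 1L)
  expect_equal(fit_lin$r_squared, 1, tolerance = 1e-9)
  # pure noise: no significant leading term
  y_noise <- rnorm(120)
  fit_noise <- stepwise_poly_fit(x, y_noise)
  expect_lte(fit_noise$r_squared, 0.1)
})

test_that("Kruskal-Wallis wrapper matches a hand-ranked oracle", {
  v <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  kw <- kruskal_wallis_groups(v, g)
  # ranks 1..6, group mean ranks 2 and 5:
  # H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)
  expect_equal(kw$df, 1L)
  expect_warning(kw_id <- kruskal_wallis_groups(rep(5, 6), g), "identical")
  expect_equal(kw_id$p, 1)
  expect_error(kruskal_wallis_groups(v, rep("a", 6)), "two groups")
})

test_that("rank statistics handle monotone transforms and exact enumeration", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 0.9)
  expect_equal(spearman_rank(x, exp(x))$rho, 1)
  expect_equal(spearman_rank(x, -x^3)$rho, -1)
  expect_error(spearman_rank(x, rep(1, 6)), "constant")

  # signed-rank: exhaustive sign-flip enumeration oracle on 5 untied pairs
  a <- c(2.3, 1.1, 4.0, 3.3, 0.2)
  b <- c(1.0, 1.5, 1.8, 2.5, 1.9)
  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  v_all <- signs %*% r
  p_oracle <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  expect_equal(signed_rank_test(a, b)$p, p_oracle)
})

test_that("near-minimum percentile surrogates degrade away from D_min", {
  set.seed(3)
  n <- 60
  d_min <- runif(n, 0.5, 1)
  tbl <- data.frame(
    d_min = d_min,
    d999 = d_min,                                  # identical -> r = 1
    d99 = d_min + rnorm(n, 0, 0.05),
    d98 = d_min + rnorm(n, 0, 0.12),
    d50 = runif(n, 0.9, 1.1))                      # independent -> r ~ 0
  cors <- dmin_surrogate_correlation(tbl, k_lowest = 20)
  expect_equal(unname(cors["d999"]), 1)
  expect_lt(abs(cors["d50"]), 0.5)
  expect_true(cors["d999"] >= cors["d99"])
  expect_error(dmin_surrogate_correlation(tbl, k_lowest = 100), "exceeds")
})
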