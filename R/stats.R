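#' Sample weights emphasizing cold fractions
#'
#' Relative regression weights used to sensitize the classifiers to the
#' clinically relevant cold fractions: weight 10 for normalized gEUD below
#' 0.90, weight 2 in [0.90, 0.95), and 1 otherwise.
#'
#' @param geud_norm numeric vector of normalized gEUD values.
#' @param thresholds lower band edges (default `c(0.90, 0.95)`).
#' @param weights weights for the bands below each threshold and above
#'   (default `c(10, 2, 1)`).
#' @return numeric vector of weights.
#' @export
make_weights <- function(geud_norm, thresholds = c(0.90, 0.95),
                         weights = c(10, 2, 1)) {
  stopifnot(all(is.finite(geud_norm)), length(thresholds) == 2,
            length(weights) == 3, all(weights >= 1))
  ifelse(geud_norm < thresholds[1], weights[1],
         ifelse(geud_norm < thresholds[2], weights[2], weights[3]))
}

#' Pearson correlation with a Fisher-transform confidence interval
#'
#' @param x,y numeric vectors (n >= 4, nonconstant).
#' @param conf confidence level.
#' @return list with `r`, `lo`, `hi`, `n`.
#' @export
pearson_with_fisher_ci <- function(x, y, conf = 0.95) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  r <- cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zc <- qnorm(1 - (1 - conf) / 2)
  list(r = r, lo = tanh(z - zc * se), hi = tanh(z + zc * se), n = n)
}

#' Z-test for two dependent correlations sharing one variable
#'
#' Steiger's Z for comparing r(a,b) and r(a,c) measured on the same sample,
#' accounting for the dependence through r(b,c) (Steiger 1980, Z1*-bar with
#' Fisher-transformed correlations). Two-sided p-value.
#'
#' @param r_ab,r_ac the two correlations with the common criterion a.
#' @param r_bc correlation between the two predictors.
#' @param n sample size (> 3).
#' @return list with `z` and `p`.
#' @export
steiger_z_dependent <- function(r_ab, r_ac, r_bc, n) {
  stopifnot(n > 3, abs(r_ab) < 1, abs(r_ac) < 1, abs(r_bc) <= 1)
  rbar <- (r_ab + r_ac) / 2
  psi <- r_bc * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_bc^2)
  sbar <- psi / (1 - rbar^2)^2
  z <- (atanh(r_ab) - atanh(r_ac)) * sqrt((n - 3) / (2 - 2 * sbar))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Cross-validated variance explained
#'
#' `VE_cv = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` computed on
#' held-out predictions; may be negative when the model underperforms the
#' mean predictor.
#'
#' @param y_true observed values (nonconstant).
#' @param y_pred held-out predictions, same length.
#' @return scalar.
#' @export
ve_cv <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("constant y_true: variance explained undefined")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Stepwise polynomial fit up to the highest significant degree
#'
#' Fits raw polynomials of increasing degree and retains the highest degree
#' whose leading coefficient is significant at `alpha` (t-test); reports the
#' fit's coefficients, R-squared and overall F statistic. Degree 0 (the
#' intercept-only model) is returned when no leading term is significant.
#' Rank-deficient fits reduce the admissible degree with a warning.
#'
#' @param x,y numeric vectors, `length(x) > max_degree + 1`.
#' @param max_degree largest degree tried.
#' @param alpha significance level for the leading term.
#' @return list with `degree`, `coefficients`, `r_squared`, `f_value`,
#'   `p_leading` (per-degree leading-term p-values) and `model` (the lm fit,
#'   NULL for degree 0).
#' @export
stepwise_poly_fit <- function(x, y, max_degree = 5, alpha = 0.05) {
  n <- length(x)
  stopifnot(length(y) == n, n > max_degree + 1)
  poly_fit <- function(deg) {
    X <- outer(x, seq_len(deg), "^")
    colnames(X) <- paste0("x^", seq_len(deg))
    lm(y ~ X)
  }
  p_lead <- rep(NA_real_, max_degree)
  for (deg in seq_len(max_degree)) {
    fit <- poly_fit(deg)
    sm <- suppressWarnings(summary(fit))
    cf <- sm$coefficients
    # leading term is the last coefficient row when the fit has full rank
    if (anyNA(coef(fit)) || nrow(cf) != deg + 1L) {
      warning(sprintf("rank-deficient fit at degree %d; degree not admissible", deg))
      next
    }
    p_lead[deg] <- cf[nrow(cf), "Pr(>|t|)"]
    # an (essentially) exact fit: higher-degree leading terms would only
    # chase floating-point noise
    if (sm$sigma <= 1e-10 * max(sd(y), .Machine$double.eps)) break
  }
  sig <- which(!is.na(p_lead) & p_lead < alpha)
  if (length(sig) == 0) {
    return(list(degree = 0L, coefficients = c(`(Intercept)` = mean(y)),
                r_squared = 0, f_value = NA_real_, p_leading = p_lead,
                model = NULL))
  }
  degree <- max(sig)
  fit <- poly_fit(degree)
  sm <- suppressWarnings(summary(fit))
  list(degree = degree, coefficients = coef(fit), r_squared = sm$r.squared,
       f_value = unname(sm$fstatistic["value"]), p_leading = p_lead,
       model = fit)
}

#' Kruskal-Wallis test across patient groups
#'
#' Rank-based H statistic with tie correction and chi-square p-value,
#' wrapping [stats::kruskal.test()]. All values identical across groups is
#' degenerate: H = 0 and p = 1 are returned with a warning.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length (>= 2 groups).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (length(unique(values)) == 1) {
    warning("all values identical; H = 0, p = 1 by convention")
    return(list(H = 0, p = 1, df = nlevels(droplevels(groups)) - 1L))
  }
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors (n >= 3, nonconstant).
#' @return list with `rho` and `p` (asymptotic, tie-corrected).
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' @param a,b paired numeric vectors (>= 5 pairs).
#' @return list with `V` and `p` (exact when possible).
#' @export
signed_rank_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
  list(V = unname(wt$statistic), p = wt$p.value)
}

#' Correlation of near-minimum DVH percentiles with the minimum dose
#'
#' Restricted to the `k_lowest` fractions with the smallest normalized
#' minimum dose, computes the Pearson correlation of `d_min` with D99.9,
#' D99, D98 and D50 — quantifying how quickly DVH percentiles lose the
#' information carried by the voxel-level minimum.
#'
#' @param features feature table from [extract_cohort_features()] (columns
#'   `d_min`, `d999`, `d99`, `d98`, `d50`).
#' @param k_lowest number of lowest-`d_min` fractions used.
#' @return named numeric vector of correlations (`d999`, `d99`, `d98`, `d50`).
#' @export
dmin_surrogate_correlation <- function(features, k_lowest = 20) {
  need <- c("d_min", "d999", "d99", "d98", "d50")
  stopifnot(all(need %in% names(features)))
  if (k_lowest > nrow(features))
    stop("k_lowest exceeds the number of fractions")
  sub <- features[order(features$d_min), ][seq_len(k_lowest), ]
  vapply(c("d999", "d99", "d98", "d50"),
         function(cl) cor(sub$d_min, sub[[cl]]), numeric(1))
}
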