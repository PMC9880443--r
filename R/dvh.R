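#' Cumulative dose-volume histogram of a structure
#'
#' Bins the voxel doses inside `mask` with equal voxel weighting (uniform
#' cell density). The histogram stores, at each ascending bin edge, the
#' fraction of the structure volume receiving at least that dose
#' (`cum_volume[1] == 1`), plus the exact mean dose of the voxels falling in
#' each bin. Effectiveness measures ([geud()], [eud_sf()]) are evaluated on
#' the differential histogram using those exact bin mean doses, so a uniform
#' dose distribution reproduces its dose exactly rather than to bin
#' resolution.
#'
#' @param dose a `dose_grid`.
#' @param mask a nonempty `structure_mask` on the same grid.
#' @param bin_width histogram bin width in Gy; the default corresponds to
#'   0.1% of a 60 Gy prescription.
#' @return An object of class `dvh`: list with `bin_edges` (Gy, ascending),
#'   `cum_volume` (fraction receiving >= edge), `bin_dose` (mean voxel dose
#'   per bin), `diff_volume` (volume fraction per bin) and `n_voxels`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.06) {
  stop_if_grid_mismatch(dose, mask, c("dose", "mask"))
  if (!any(mask)) stop("cannot compute a DVH for an empty mask")
  stopifnot(bin_width > 0)
  d <- as.numeric(dose)[as.logical(mask)]
  if (any(d < 0)) stop("negative dose inside structure")
  n <- length(d)
  nbins <- max(1L, ceiling((max(d) + 1e-12) / bin_width))
  edges <- seq(0, by = bin_width, length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(d, edges, rightmost.closed = FALSE), 1L), nbins)
  counts <- tabulate(bin, nbins)
  sums <- as.numeric(rowsum(d, bin, reorder = TRUE))
  bin_dose <- rep(NA_real_, nbins)
  bin_dose[sort(unique(bin))] <- sums / counts[counts > 0]
  # midpoint fallback for empty bins (never used by the differential sums)
  empty <- is.na(bin_dose)
  bin_dose[empty] <- edges[which(empty)] + bin_width / 2
  diff_volume <- counts / n
  cum <- c(rev(cumsum(rev(diff_volume))), 0)
  structure(list(bin_edges = edges, cum_volume = cum, bin_dose = bin_dose,
                 diff_volume = diff_volume, n_voxels = n),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh: %d voxels, %d bins, dose range [%.2f, %.2f] Gy>\n",
              x$n_voxels, length(x$bin_dose),
              min(x$bin_dose[x$diff_volume > 0]),
              max(x$bin_dose[x$diff_volume > 0])))
  invisible(x)
}

#' Dose percentile Dx from a cumulative DVH
#'
#' `Dx` is the dose received by the hottest x% of the structure volume
#' (D99.9, D99, D98, D50 ...), read off the cumulative histogram by linear
#' interpolation between bin edges; `D100` returns the lower edge of the
#' lowest occupied bin. Monotone: `x1 < x2` implies `Dx1 >= Dx2`.
#'
#' @param dvh a [compute_dvh()] result.
#' @param x percentage of volume in (0, 100].
#' @return dose in Gy.
#' @export
dose_percentile <- function(dvh, x) {
  if (!is.numeric(x) || x <= 0 || x > 100) stop("x must be in (0, 100]")
  v <- x / 100
  cum <- dvh$cum_volume
  edges <- dvh$bin_edges
  if (v >= cum[1]) {  # whole volume: minimum binned dose
    return(edges[which(dvh$diff_volume > 0)[1]])
  }
  # last edge with cum >= v, then interpolate within the following bin
  k <- max(which(cum >= v))
  if (k == length(cum)) return(edges[length(edges)])
  if (cum[k] == cum[k + 1]) return(edges[k])
  edges[k] + (cum[k] - v) / (cum[k] - cum[k + 1]) * (edges[k + 1] - edges[k])
}

#' Minimum dose inside a structure
#'
#' Returns the minimum voxel dose over the mask together with the achieving
#' voxel (ties broken deterministically by lowest linear index) and its world
#' coordinate. This is the voxel-level minimum, deliberately distinct from
#' near-minimum DVH percentiles such as D99.9.
#'
#' @param dose a `dose_grid`.
#' @param mask a nonempty `structure_mask` on the same grid.
#' @return list with `dose` (Gy), `index` (1-based linear voxel index),
#'   `ijk` (1-based voxel index triple) and `point` (world mm).
#' @export
d_min <- function(dose, mask) {
  stop_if_grid_mismatch(dose, mask, c("dose", "mask"))
  if (!any(mask)) stop("cannot take the minimum over an empty mask")
  g <- grid_of(dose)
  idx <- which(as.logical(mask))
  d <- as.numeric(dose)[idx]
  best <- idx[which.min(d)]  # which.min returns the first minimum
  ijk <- ijk_of_linear(g, best)
  list(dose = min(d), index = best, ijk = ijk,
       point = as.numeric(index_to_world(g, ijk)))
}

#' Generalized equivalent uniform dose (power-law gEUD)
#'
#' The generalized mean of the voxel doses with exponent `a`,
#' \deqn{gEUD = \left(\sum_i v_i D_i^a\right)^{1/a},}
#' evaluated on the differential DVH with exact per-bin mean doses. For
#' tumors `a = -20`, which emphasizes cold spots; as `a` decreases the gEUD
#' approaches the minimum dose. A bin with exactly zero dose and `a < 0`
#' returns 0 with a warning (a complete cold spot dominates).
#'
#' @param dvh a [compute_dvh()] result.
#' @param a nonzero exponent (default -20, tumor).
#' @return gEUD in Gy.
#' @export
geud <- function(dvh, a = -20) {
  if (!is.numeric(a) || a == 0) stop("exponent a must be nonzero")
  occ <- dvh$diff_volume > 0
  v <- dvh$diff_volume[occ]
  d <- dvh$bin_dose[occ]
  if (a < 0 && any(d == 0)) {
    warning("structure contains zero-dose voxels; gEUD with a < 0 is 0")
    return(0)
  }
  # log-sum-exp guard: with a = -20 the coldest bin dominates
  la <- a * log(d)
  m <- max(la)
  exp((m + log(sum(v * exp(la - m)))) / a)
}

#' Calibrate SF2 from the Poisson tumor control probability model
#'
#' Solves \eqn{TCP = \exp(-N_0 \cdot SF_2^{D/d})} for the surviving fraction
#' at the reference fraction dose, i.e. the per-fraction survival such that a
#' course of `total_dose` delivered in fractions of `dose_per_fraction`
#' controls the tumor with probability `tcp_target`:
#' \deqn{SF_2 = \left(\ln(1/TCP)/N_0\right)^{d/D}.}
#' With the default tumor model (50% control at 60 Gy in 2 Gy fractions,
#' 1e8 clonogens) this gives SF2 = 0.534598229.
#'
#' @param tcp_target target control probability in (0, 1).
#' @param total_dose total course dose in Gy.
#' @param dose_per_fraction fraction dose in Gy; `total_dose` must be a whole
#'   number of fractions.
#' @param n0 clonogen number (>= 1).
#' @return SF2, the surviving fraction per reference fraction.
#' @export
calibrate_sf2 <- function(tcp_target = 0.5, total_dose = 60,
                          dose_per_fraction = 2, n0 = 1e8) {
  if (!(tcp_target > 0 && tcp_target < 1)) stop("tcp_target must be in (0,1)")
  stopifnot(total_dose > 0, dose_per_fraction > 0, n0 >= 1)
  nfx <- total_dose / dose_per_fraction
  if (abs(nfx - round(nfx)) > 1e-9)
    stop("total_dose must be a whole number of fractions")
  (log(1 / tcp_target) / n0)^(dose_per_fraction / total_dose)
}

#' Cell-survival parameters for the survival-based EUD
#'
#' @param sf2 surviving fraction at the reference fraction dose, in (0, 1).
#' @param alpha_beta linear-quadratic alpha/beta ratio in Gy (tumor: 4 Gy).
#' @param n0 clonogen number (only used for calibration provenance).
#' @param n_fractions number of fractions of the standardized course.
#' @param d_ref reference fraction dose in Gy.
#' @return list of class `sf_model_params`.
#' @export
sf_model_params <- function(sf2 = calibrate_sf2(), alpha_beta = 4, n0 = 1e8,
                            n_fractions = 30, d_ref = 2) {
  stopifnot(sf2 > 0, sf2 < 1, alpha_beta > 0, n0 >= 1,
            n_fractions >= 1, d_ref > 0)
  structure(list(sf2 = sf2, alpha_beta = alpha_beta, n0 = n0,
                 n_fractions = as.integer(n_fractions), d_ref = d_ref),
            class = "sf_model_params")
}

# per-fraction surviving fraction at dose d (Gy) under the LQ model with
# fraction-size correction, parameterized by SF at d_ref:
#   s(d) = sf2 ^ [ (d/d_ref) * (alpha_beta + d) / (alpha_beta + d_ref) ]
# with correct = FALSE the plain exponential scaling sf2^(d/d_ref) is used.
survival_per_fraction <- function(d, params, correct = TRUE) {
  expo <- if (correct) {
    (d / params$d_ref) * (params$alpha_beta + d) /
      (params$alpha_beta + params$d_ref)
  } else d / params$d_ref
  params$sf2^expo
}

#' Survival-model equivalent uniform dose (EUD_SF)
#'
#' The uniform total dose that, delivered in `n_fractions` equal fractions,
#' leaves the same clonogen surviving fraction as repeatedly applying the
#' given inhomogeneous per-fraction dose distribution for the whole course.
#' Per-fraction cell survival follows the linear-quadratic model with
#' fraction-size correction, parameterized by SF2 and alpha/beta:
#' \deqn{s(d) = SF_2^{(d/d_{ref})\,(\alpha/\beta + d)/(\alpha/\beta + d_{ref})}}
#' The course survival is \eqn{S = \sum_i v_i\, s(d_i)^{n}} over the DVH bins
#' and the equivalent uniform fraction dose solves \eqn{s(d_u)^{n} = S} by
#' monotone root-finding; the returned EUD_SF is \eqn{n\, d_u}.
#'
#' @param dvh_per_fraction DVH of the per-fraction dose distribution (doses
#'   on the scale of `d_ref`, i.e. around 2 Gy).
#' @param params [sf_model_params()].
#' @param fraction_size_correction if `FALSE`, use plain `sf2^(d/d_ref)`
#'   survival scaling without the LQ fraction-size term.
#' @return total-course equivalent uniform dose in Gy.
#' @export
eud_sf <- function(dvh_per_fraction, params = sf_model_params(),
                   fraction_size_correction = TRUE) {
  occ <- dvh_per_fraction$diff_volume > 0
  v <- dvh_per_fraction$diff_volume[occ]
  d <- dvh_per_fraction$bin_dose[occ]
  n <- params$n_fractions
  # course log-survival per bin, summed in a numerically safe way
  ls_bin <- n * log(survival_per_fraction(d, params, fraction_size_correction))
  m <- max(ls_bin)
  logS <- m + log(sum(v * exp(ls_bin - m)))
  if (!is.finite(logS) || logS > 0) {
    warning("course survival clamped to (0, 1)")
    logS <- min(logS, -1e-12)
  }
  # target per-fraction log-survival
  target <- logS / n
  lsf <- log(params$sf2)
  if (fraction_size_correction) {
    # (du/d_ref) (ab+du)/(ab+d_ref) * log(sf2) = target : monotone in du
    f <- function(du) (du / params$d_ref) * (params$alpha_beta + du) /
      (params$alpha_beta + params$d_ref) * lsf - target
  } else {
    f <- function(du) (du / params$d_ref) * lsf - target
  }
  # f is decreasing in du (lsf < 0, exponent increasing): bracket the root
  upper <- max(d) * 2 + 10
  while (f(upper) > 0) upper <- upper * 2
  root <- uniroot(f, c(0, upper), tol = 1e-10)
  if (!is.finite(root$root) || abs(root$f.root) > 1e-6)
    stop("EUD_SF root-finding did not converge")
  n * root$root
}
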