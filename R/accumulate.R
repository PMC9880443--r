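#' Invert a displacement field
#'
#' Computes the inverse displacement field v of u (both in mm) such that the
#' composed warp `(id + u) o (id + v)` is the identity, by per-voxel
#' fixed-point iteration `v(q) <- -u(q + v(q))` with trilinear sampling of u.
#' The composition residual is reported; a root-mean-square residual above
#' `tol_rms_mm` over the grid is an error (the worst voxel residual is
#' included in the message).
#'
#' @param field a `displacement_field` (planning to fraction geometry).
#' @param maxit maximum fixed-point sweeps.
#' @param tol_mm per-voxel convergence tolerance for the iteration.
#' @param tol_rms_mm acceptance threshold on the composition residual RMS.
#' @param quiet suppress the residual check error and return regardless
#'   (used internally where the caller inspects the residual itself).
#' @return list with `field` (the inverse `displacement_field`), `rms_mm`,
#'   `worst_mm` and `iterations`.
#' @export
invert_field <- function(field, maxit = 30, tol_mm = 1e-3, tol_rms_mm = 0.1,
                         quiet = FALSE) {
  g <- grid_of(field)
  res <- cpp_invert_field(as.numeric(field), g$shape, g$spacing,
                          as.integer(maxit), tol_mm)
  inv <- displacement_field(array(res$field, c(g$shape, 3)), g)
  if (!quiet && res$rms_mm > tol_rms_mm)
    stop(sprintf(paste0("field inversion residual too large: RMS %.3f mm ",
                        "(worst voxel %.3f mm) after %d iterations"),
                 res$rms_mm, res$worst_mm, res$iterations))
  list(field = inv, rms_mm = res$rms_mm, worst_mm = res$worst_mm,
       iterations = res$iterations)
}

#' Pull a dose grid through a displacement field
#'
#' Resamples the dose at `q + u(q)` for every voxel center q by trilinear
#' interpolation. Sample points leaving the grid take the clamped boundary
#' value; their count is reported in attribute `n_clamped` (with a warning
#' when nonzero). Pulling the planning dose through the planning-to-fraction
#' field yields the dose received by each planning-geometry tissue element
#' under the static dose cloud approximation — identical to deforming the
#' dose cube with the inverse field.
#'
#' @param dose a `dose_grid`.
#' @param field a `displacement_field` on the same grid.
#' @return a `dose_grid` with attribute `n_clamped`.
#' @export
pullback_dose <- function(dose, field) {
  stop_if_grid_mismatch(dose, field, c("dose", "field"))
  g <- grid_of(dose)
  res <- cpp_pull_dose(as.numeric(dose), as.numeric(field), g$shape, g$spacing)
  out <- dose_grid(array(res$dose, g$shape), g)
  attr(out, "n_clamped") <- res$n_clamped
  if (res$n_clamped > 0)
    warning(sprintf("%d sample points left the dose grid and were clamped to the boundary",
                    res$n_clamped))
  out
}

#' Accumulate the delivered dose over a patient series
#'
#' Under the static dose cloud approximation and uniform fractionation, the
#' per-fraction dose is the planning dose divided by the number of fractions,
#' and the tissue element at planning voxel p receives, at fraction i, the
#' planned dose at its displaced position `p + u_i(p)`. The accumulated
#' distribution is the sum of these pulled-back per-fraction doses on the
#' planning grid; gEUD and minimum dose of the accumulated distribution are
#' evaluated on the planning CTV and normalized by the prescription.
#'
#' @param series a `patient_series`.
#' @param a gEUD exponent.
#' @param bin_rel DVH bin width as a fraction of prescription.
#' @return list with `dose` (accumulated `dose_grid`, Gy), `geud_acc_norm`,
#'   `d_min_acc_norm` and `n_fractions`.
#' @export
accumulate_dose <- function(series, a = -20, bin_rel = 0.001) {
  nf <- length(series$fractions)
  if (nf < 1) stop("series has no fractions")
  g <- series$grid
  acc <- array(0, g$shape)
  n_clamped <- 0L
  for (fr in series$fractions) {
    pb <- suppressWarnings(pullback_dose(series$plan_dose, fr$field))
    n_clamped <- n_clamped + attr(pb, "n_clamped")
    acc <- acc + unclass(pb) / nf
  }
  attributes(acc) <- list(dim = g$shape)
  acc <- dose_grid(acc, g)
  P <- series$prescription
  dvh <- compute_dvh(acc, series$ctv_plan, bin_rel * P)
  list(dose = acc,
       geud_acc_norm = geud(dvh, a) / P,
       d_min_acc_norm = d_min(acc, series$ctv_plan)$dose / P,
       n_fractions = nf,
       n_clamped = n_clamped)
}

#' Gamma-index pass rate between two dose distributions
#'
#' Global-normalization gamma analysis: for every ROI voxel of the reference
#' with dose at least `dose_threshold` of the normalization dose, the gamma
#' index is the minimum over lattice offsets r within the search radius of
#' \deqn{\gamma = \sqrt{(\Delta d / DD)^2 + (|r| / DTA)^2},}
#' where the dose difference DD criterion is `dd` times the normalization
#' dose and the distance-to-agreement criterion is `dta_mm`. A voxel passes
#' when gamma <= 1; the pass rate is the passing fraction of evaluated
#' voxels. The search is exhaustive on the voxel lattice within
#' `search_factor * dta_mm`.
#'
#' @param reference,evaluated `dose_grid`s on the same grid.
#' @param roi a nonempty `structure_mask` restricting the analysis.
#' @param dta_mm distance-to-agreement in mm (> 0).
#' @param dd dose-difference criterion as a fraction of `norm_dose` (> 0).
#' @param dose_threshold low-dose exclusion threshold as a fraction of
#'   `norm_dose`.
#' @param norm_dose normalization dose in Gy; defaults to the maximum
#'   reference dose.
#' @param search_factor search radius in units of `dta_mm` (>= 3 recommended).
#' @return list with `pass_rate`, `n_evaluated`, `gamma` (array, NA outside
#'   the evaluated set) and the criteria.
#' @export
gamma_pass_rate <- function(reference, evaluated, roi, dta_mm = 3, dd = 0.03,
                            dose_threshold = 0.1, norm_dose = NULL,
                            search_factor = 3) {
  stop_if_grid_mismatch(reference, evaluated, c("reference", "evaluated"))
  stop_if_grid_mismatch(reference, roi, c("reference", "roi"))
  stopifnot(dta_mm > 0, dd > 0, search_factor > 0)
  if (!any(roi)) stop("empty ROI")
  g <- grid_of(reference)
  if (is.null(norm_dose)) norm_dose <- max(reference)
  stopifnot(norm_dose > 0)
  thr <- dose_threshold * norm_dose
  if (!any(as.logical(roi) & as.numeric(reference) >= thr))
    stop("no ROI voxel above the dose threshold")
  gam <- cpp_gamma(as.numeric(reference), as.numeric(evaluated), g$shape,
                   g$spacing, as.logical(roi), dta_mm, dd * norm_dose, thr,
                   search_factor * dta_mm)
  gam <- array(gam, g$shape)
  ev <- !is.na(gam)
  list(pass_rate = mean(gam[ev] <= 1), n_evaluated = sum(ev), gamma = gam,
       criteria = list(dta_mm = dta_mm, dd = dd, dose_threshold = dose_threshold,
                       norm_dose = norm_dose, search_factor = search_factor))
}
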