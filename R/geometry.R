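#' Directed Hausdorff distance by minimal isotropic expansion
#'
#' The Hausdorff distance HDD between a deformed structure `ctv_i` and the
#' planning structure `ctv_plan` is the radius of the minimal isotropic
#' expansion of `ctv_plan` that contains `ctv_i` — equivalently the maximum,
#' over voxels of `ctv_i`, of the Euclidean distance (mm) to the nearest
#' voxel of `ctv_plan`, computed here from the distance transform of the
#' planning structure. The achieving voxel is the Hausdorff point HDP (ties
#' broken by lowest linear voxel index). HDD is 0 exactly when `ctv_i` is
#' contained in `ctv_plan`.
#'
#' @param ctv_plan,ctv_i nonempty `structure_mask`s on the same grid.
#' @return list with `hdd_mm`, `point` (world mm of the HDP), `index`
#'   (1-based linear voxel index).
#' @export
hausdorff_expansion <- function(ctv_plan, ctv_i) {
  stop_if_grid_mismatch(ctv_plan, ctv_i, c("ctv_plan", "ctv_i"))
  if (!any(ctv_plan) || !any(ctv_i)) stop("both masks must be nonempty")
  g <- grid_of(ctv_plan)
  dt <- distance_to_structure(ctv_plan)
  idx <- which(as.logical(ctv_i))
  d <- as.numeric(dt)[idx]
  best <- idx[which.max(d)]  # first maximum = lowest linear index
  list(hdd_mm = max(d),
       point = as.numeric(index_to_world(g, ijk_of_linear(g, best))),
       index = best)
}

#' Worst Hausdorff fraction over a series
#'
#' Given the per-fraction Hausdorff results, returns the fraction with the
#' largest HDD (earliest fraction on ties) and its Hausdorff point HDP_worst.
#'
#' @param hausdorff_list list of [hausdorff_expansion()] results, one per
#'   fraction in series order.
#' @return list with `fraction` (index) and `point` (world mm).
#' @export
hdp_worst <- function(hausdorff_list) {
  if (length(hausdorff_list) < 1) stop("need at least one fraction")
  hdds <- vapply(hausdorff_list, function(h) h$hdd_mm, numeric(1))
  w <- which.max(hdds)  # first maximum = earliest fraction
  list(fraction = w, point = hausdorff_list[[w]]$point, hdd_mm = hdds[w])
}

#' Map a fraction-geometry point back to planning geometry
#'
#' Inverts the displacement at a single point by fixed-point iteration
#' `p <- q - u(p)` starting at `p = q` (tolerance 0.01 mm, at most 50
#' iterations), where `u` maps planning to fraction geometry.
#'
#' @param q world point (mm) in fraction geometry.
#' @param field a `displacement_field` (planning to fraction).
#' @param tol_mm convergence tolerance.
#' @param maxit iteration cap.
#' @return world point (mm) in planning geometry.
#' @export
invert_point <- function(q, field, tol_mm = 0.01, maxit = 50) {
  p <- q
  for (it in seq_len(maxit)) {
    pn <- q - as.numeric(sample_at(field, p))
    if (sqrt(sum((pn - p)^2)) < tol_mm) return(pn)
    p <- pn
  }
  stop(sprintf(paste0("point inversion did not converge within %d iterations",
                      " (last step %.3f mm at point [%.1f, %.1f, %.1f])"),
               maxit, sqrt(sum((pn - p)^2)), q[1], q[2], q[3]))
}

#' Global minimum-dose point of a patient series
#'
#' Finds the fraction with the smallest minimum dose in its deformed CTV over
#' all fractions (ties broken by earliest fraction), and maps that fraction's
#' minimum-dose voxel back to planning geometry through the inverse
#' displacement, giving the global minimum-dose point PD_min_global on the
#' planning CTV.
#'
#' @param series a `patient_series` from [generate_cohort()], or any list
#'   with `plan_dose` and `fractions` (each with `field` and `ctv`).
#' @return list with `fraction` (index of the global-minimum fraction x),
#'   `d_min` (Gy), `point_fraction` (world mm, fraction geometry) and
#'   `point_plan` (world mm, planning geometry).
#' @export
pd_min_global <- function(series) {
  nf <- length(series$fractions)
  if (nf < 1) stop("series has no fractions")
  dmins <- lapply(series$fractions, function(fr) d_min(series$plan_dose, fr$ctv))
  vals <- vapply(dmins, function(d) d$dose, numeric(1))
  x <- which.min(vals)  # first minimum = earliest fraction
  q <- dmins[[x]]$point
  p <- invert_point(q, series$fractions[[x]]$field)
  list(fraction = x, d_min = vals[x], point_fraction = q, point_plan = p)
}

#' Propagate a planning point through a fraction's displacement field
#'
#' Returns the propagated point `p + u(p)` (trilinear field interpolation)
#' and the dose sampled there by trilinear interpolation of the dose grid.
#' Points leaving the dose grid are clamped to the boundary with a warning.
#'
#' @param p_plan world point (mm) in planning geometry.
#' @param field a `displacement_field`.
#' @param dose a `dose_grid`.
#' @return list with `point` (world mm) and `dose` (Gy).
#' @export
propagate_point <- function(p_plan, field, dose) {
  q <- as.numeric(p_plan) + as.numeric(sample_at(field, p_plan))
  g <- grid_of(dose)
  upper <- g$origin + (g$shape - 1) * g$spacing
  if (any(q < g$origin - 1e-9) || any(q > upper + 1e-9))
    warning("propagated point left the dose grid; dose sampled at the clamped boundary position")
  list(point = q, dose = as.numeric(sample_at(dose, q)))
}

#' Projection of a fraction's deformation onto the worst-fraction direction
#'
#' The signed length (mm) of the projection of the deformation vector at
#' `p_plan` in fraction i onto the unit deformation vector at the same point
#' in the global-minimum fraction x: `v_i . v_x / |v_x|`. A surrogate for the
#' deformation component along the steepest dose-gradient direction. If
#' `|v_x| = 0` the reference direction is degenerate and 0 is returned with a
#' warning.
#'
#' @param p_plan world point (mm), typically PD_min_global.
#' @param field_i fraction i's `displacement_field`.
#' @param field_x the global-minimum fraction's `displacement_field`.
#' @return scalar projection in mm.
#' @export
scalar_pdmin <- function(p_plan, field_i, field_x) {
  v_i <- as.numeric(sample_at(field_i, p_plan))
  v_x <- as.numeric(sample_at(field_x, p_plan))
  nx <- sqrt(sum(v_x^2))
  if (nx == 0) {
    warning("degenerate reference direction (|v_x| = 0); returning 0")
    return(0)
  }
  sum(v_i * v_x) / nx
}

#' Deformation length at the worst Hausdorff point
#'
#' Euclidean norm (mm) of fraction i's displacement vector evaluated at the
#' planning-geometry location of HDP_worst.
#'
#' @param hdp_worst_plan world point (mm) in planning geometry.
#' @param field_i a `displacement_field`.
#' @return length in mm.
#' @export
delta_l_hdp_worst <- function(hdp_worst_plan, field_i) {
  sqrt(sum(as.numeric(sample_at(field_i, hdp_worst_plan))^2))
}

#' Systematic and random deformation components per axis
#'
#' Decomposes per-fraction deformation-vector differences between two
#' anatomical points into a systematic and a random component per axis, in
#' the classic interfraction-error sense: the random SD is the pooled
#' within-patient SD of the per-fraction differences, and the systematic SD
#' is the SD over patients of the per-patient mean difference.
#'
#' @param diffs data.frame with columns `patient` and `dx`, `dy`, `dz`
#'   (mm), one row per fraction: the difference of the deformation vectors
#'   between the two points at that fraction.
#' @return list with `systematic_sd` and `random_sd`, each a named length-3
#'   vector (mm).
#' @export
deformation_variance_decomposition <- function(diffs) {
  stopifnot(all(c("patient", "dx", "dy", "dz") %in% names(diffs)))
  pats <- unique(diffs$patient)
  if (length(pats) < 2) stop("need at least two patients")
  per_axis <- function(col) {
    v <- diffs[[col]]
    means <- tapply(v, diffs$patient, mean)
    ns <- tapply(v, diffs$patient, length)
    if (any(ns < 2))
      stop("random SD undefined: some patient has a single fraction")
    ss <- tapply(v, diffs$patient, function(x) sum((x - mean(x))^2))
    random <- sqrt(sum(ss) / sum(ns - 1))   # pooled within-patient SD
    systematic <- sd(means)                 # SD of per-patient means
    c(systematic = systematic, random = random)
  }
  res <- vapply(c("dx", "dy", "dz"), per_axis, numeric(2))
  list(systematic_sd = res["systematic", ], random_sd = res["random", ])
}

#' Per-fraction dosimetric and geometric feature table for a patient series
#'
#' Computes, for every fraction of a series, the feature row used by the
#' prediction study: normalized minimum CTV dose (`d_min`), normalized gEUD
#' and survival-model EUD, Hausdorff distance `hdd_mm`, deformation length at
#' the worst Hausdorff point `dl_hdpworst_mm`, normalized dose at the
#' propagated global minimum-dose point `d_pdmin_global`, its projection
#' feature `scalar_pdmin_mm`, and near-minimum DVH percentiles (normalized
#' D99.9/D99/D98/D50) used for the surrogate analysis. Doses are normalized
#' to the prescription. The survival EUD is computed for a standardized
#' course of `n_fractions_sf` fractions at `d_ref = 2` Gy by repeatedly
#' applying the fraction's dose distribution.
#'
#' @param series a `patient_series`.
#' @param a gEUD exponent.
#' @param sf_params [sf_model_params()].
#' @param bin_rel DVH bin width as a fraction of prescription.
#' @return data.frame, one row per fraction.
#' @export
extract_fraction_features <- function(series, a = -20,
                                      sf_params = sf_model_params(),
                                      bin_rel = 0.001) {
  g <- series$grid
  P <- series$prescription
  bw <- bin_rel * P
  nf <- length(series$fractions)
  haus <- vector("list", nf)
  dmins <- vector("list", nf)
  geuds <- numeric(nf)
  eudsf <- numeric(nf)
  d999 <- d99 <- d98 <- d50 <- numeric(nf)
  dtp <- distance_to_structure(series$ctv_plan)
  for (i in seq_len(nf)) {
    fr <- series$fractions[[i]]
    dvh <- compute_dvh(series$plan_dose, fr$ctv, bw)
    geuds[i] <- geud(dvh, a) / P
    # per-fraction distribution at the standardized 2 Gy prescription scale
    dvh_fx <- scale_dvh(dvh, sf_params$d_ref / P)
    eudsf[i] <- eud_sf(dvh_fx, sf_params) /
      (sf_params$d_ref * sf_params$n_fractions)
    d999[i] <- dose_percentile(dvh, 99.9) / P
    d99[i] <- dose_percentile(dvh, 99) / P
    d98[i] <- dose_percentile(dvh, 98) / P
    d50[i] <- dose_percentile(dvh, 50) / P
    dmins[[i]] <- d_min(series$plan_dose, fr$ctv)
    idx <- which(as.logical(fr$ctv))
    dh <- as.numeric(dtp)[idx]
    best <- idx[which.max(dh)]
    haus[[i]] <- list(hdd_mm = max(dh),
                      point = as.numeric(index_to_world(g, ijk_of_linear(g, best))),
                      index = best)
  }
  hw <- hdp_worst(haus)
  hw_plan <- invert_point(hw$point, series$fractions[[hw$fraction]]$field)
  pg <- pd_min_global(series)
  field_x <- series$fractions[[pg$fraction]]$field

  rows <- lapply(seq_len(nf), function(i) {
    fr <- series$fractions[[i]]
    pp <- propagate_point(pg$point_plan, fr$field, series$plan_dose)
    data.frame(patient_id = series$patient_id, fraction = i,
               d_min = dmins[[i]]$dose / P,
               geud = geuds[i], eud_sf = eudsf[i],
               hdd_mm = haus[[i]]$hdd_mm,
               dl_hdpworst_mm = delta_l_hdp_worst(hw_plan, fr$field),
               d_pdmin_global = pp$dose / P,
               scalar_pdmin_mm = scalar_pdmin(pg$point_plan, fr$field, field_x),
               d999 = d999[i], d99 = d99[i], d98 = d98[i], d50 = d50[i],
               excursion = isTRUE(fr$excursion),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Feature tables for a whole cohort
#' @param cohort list of `patient_series`.
#' @param ... passed to [extract_fraction_features()].
#' @return data.frame, one row per fraction over all patients.
#' @export
extract_cohort_features <- function(cohort, ...) {
  do.call(rbind, lapply(cohort, extract_fraction_features, ...))
}

# rescale a DVH's dose axis by a factor (volumes unchanged)
scale_dvh <- function(dvh, factor) {
  dvh$bin_edges <- dvh$bin_edges * factor
  dvh$bin_dose <- dvh$bin_dose * factor
  dvh
}
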