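#' Configuration of a synthetic gated-radiotherapy cohort
#'
#' Defaults emulate the interfraction statistics of an exhale-gated lung
#' radiotherapy series: 10 patients with 11-40 imaged fractions each, CTV
#' volumes of 149-344 cm^3, a dose plateau covering CTV plus a 5 mm PTV
#' margin, anisotropic dose falloff (cranio-caudal gradients of 5-12.5 %/mm,
#' axial 1.5-6.25 %/mm), per-patient systematic displacement components of
#' 1.7/3.0/2.3 mm and random components of 3.0/3.3/3.9 mm in x/y/z, and a
#' small probability per fraction of a large localized surface excursion
#' (8-12 mm) that drives the occasional cold fraction.
#'
#' @param n_patients number of patients.
#' @param fractions_range integer range (min, max) of imaged fractions per
#'   patient, drawn uniformly.
#' @param ctv_volume_range CTV volume range in cm^3, drawn uniformly.
#' @param prescription_dose prescription in Gy.
#' @param ptv_margin PTV margin in mm.
#' @param plateau dose plateau inside the PTV as a fraction of prescription;
#'   clinical plans run slightly hot inside the target (ICRU-style
#'   homogeneity), hence the 1.02 default.
#' @param gradient_cc cranio-caudal dose falloff range in %/mm.
#' @param gradient_axial axial dose falloff range in %/mm.
#' @param systematic_sd per-axis SD (mm) of the per-patient systematic
#'   displacement offset.
#' @param random_sd per-axis SD (mm) of the per-fraction random component,
#'   defined — as measured in interfraction-motion analyses — as the SD of
#'   the difference of deformation vectors between two distant points of the
#'   CTV; the generated field's pointwise SD is `random_sd / sqrt(2)`, so
#'   that differences between points separated by more than the correlation
#'   length reproduce `random_sd`.
#' @param correlation_length_mm spatial correlation length of the random
#'   field in mm.
#' @param large_excursion_prob per-fraction probability of a localized large
#'   surface excursion.
#' @param excursion_amplitude_range amplitude range (mm) of the excursion.
#' @param excursion_sigma_mm Gaussian width (mm) of the excursion bump.
#' @param grid a [grid_spec()] shared by all volumes.
#' @param seed integer seed making the whole cohort reproducible.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10,
                          fractions_range = c(11, 40),
                          ctv_volume_range = c(149.3, 344.2),
                          prescription_dose = 60,
                          ptv_margin = 5,
                          plateau = 1.02,
                          gradient_cc = c(5, 12.5),
                          gradient_axial = c(1.5, 6.25),
                          systematic_sd = c(1.7, 3.0, 2.3),
                          random_sd = c(3.0, 3.3, 3.9),
                          correlation_length_mm = 20,
                          large_excursion_prob = 0.05,
                          excursion_amplitude_range = c(8, 12),
                          excursion_sigma_mm = 8,
                          grid = grid_spec(c(64, 64, 64), c(2, 2, 2)),
                          seed = 1L) {
  stopifnot(n_patients >= 1,
            length(fractions_range) == 2, fractions_range[1] >= 1,
            fractions_range[2] >= fractions_range[1],
            length(ctv_volume_range) == 2,
            ctv_volume_range[2] >= ctv_volume_range[1],
            prescription_dose > 0, ptv_margin >= 0, plateau > 0,
            all(systematic_sd >= 0), all(random_sd >= 0),
            correlation_length_mm > 0,
            large_excursion_prob >= 0, large_excursion_prob <= 1,
            excursion_amplitude_range[2] >= excursion_amplitude_range[1])
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a smooth connected CTV-like structure of a target volume
#'
#' Builds a union of a few perturbed, overlapping ellipsoids around the grid
#' center and rescales them by bisection until the voxelized volume matches
#' `volume_cm3` (within 0.5%, well inside the 5% contract). The lobes all
#' overlap the central ellipsoid, so the mask is connected by construction.
#'
#' @param grid a [grid_spec()].
#' @param volume_cm3 target volume in cm^3.
#' @param seed integer seed.
#' @param n_lobes number of perturbing lobes.
#' @return a `structure_mask`.
#' @export
generate_ctv <- function(grid, volume_cm3, seed = 1L, n_lobes = 4L) {
  vox <- voxel_volume_cm3(grid)
  capacity <- prod(grid$shape) * vox
  if (volume_cm3 > 0.9 * capacity)
    stop(sprintf("target volume %.1f cm^3 exceeds grid capacity (%.1f cm^3)",
                 volume_cm3, capacity))
  if (volume_cm3 <= vox) stop("target volume below one voxel")
  rng <- local_rng(seed)
  center <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  r0 <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)  # mm, sphere-equivalent
  ax0 <- r0 * c(1.15, 1.0, 0.9) * with_rng(rng, runif(3, 0.95, 1.05))
  lobes <- lapply(seq_len(n_lobes), function(i) {
    list(center = center + with_rng(rng, rnorm(3, 0, 0.35 * r0)),
         axes = r0 * with_rng(rng, runif(3, 0.45, 0.7)))
  })
  # world coordinates of all voxel centers, one axis vector each
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  inside_at_scale <- function(s) {
    acc <- ellipsoid_mask(xs, ys, zs, center, ax0 * s)
    for (lb in lobes) {
      lc <- center + (lb$center - center) * s
      acc <- acc | ellipsoid_mask(xs, ys, zs, lc, lb$axes * s)
    }
    acc
  }
  target_vox <- volume_cm3 / vox
  lo <- 0.5; hi <- 1.8
  m <- NULL
  for (it in 1:40) {
    s <- (lo + hi) / 2
    m <- inside_at_scale(s)
    nv <- sum(m)
    if (abs(nv - target_vox) / target_vox < 0.005) break
    if (nv < target_vox) lo <- s else hi <- s
  }
  nv <- sum(m)
  if (abs(nv - target_vox) / target_vox > 0.05)
    stop("could not voxelize the target volume within 5% (structure may be clipped by the grid)")
  structure_mask(m, grid)
}

ellipsoid_mask <- function(xs, ys, zs, center, axes) {
  ex <- ((xs - center[1]) / axes[1])^2
  ey <- ((ys - center[2]) / axes[2])^2
  ez <- ((zs - center[3]) / axes[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

#' Generate an anisotropic planning dose distribution around a CTV
#'
#' Dose is a flat plateau of `plateau * prescription` inside the PTV (the CTV
#' dilated by `margin_mm`) and falls off linearly with distance from the PTV
#' surface at anisotropic rates: `gradient_cc` %/mm along z (cranio-caudal)
#' and `gradient_axial` %/mm in the axial plane, realized with a single
#' distance transform under a direction-scaled metric, clipped at zero.
#'
#' @param ctv a `structure_mask`.
#' @param margin_mm PTV margin in mm.
#' @param prescription prescription dose in Gy.
#' @param gradient_cc cranio-caudal falloff in %/mm.
#' @param gradient_axial axial falloff in %/mm.
#' @param plateau plateau level as fraction of prescription (default 1:
#'   plateau exactly at prescription).
#' @return list with `dose` (a `dose_grid`) and `ptv` (a `structure_mask`).
#' @export
generate_plan_dose <- function(ctv, margin_mm = 5, prescription = 60,
                               gradient_cc = 8.34, gradient_axial = 3.12,
                               plateau = 1) {
  stopifnot(margin_mm >= 0, gradient_cc >= 0, gradient_axial >= 0)
  g <- grid_of(ctv)
  ptv <- dilate_mask(ctv, margin_mm)
  if (gradient_cc == 0 && gradient_axial == 0) {
    dose <- array(prescription * plateau, g$shape)
    return(list(dose = dose_grid(dose, g), ptv = ptv))
  }
  # metric trick: scale the z spacing by gradient_cc/gradient_axial so that
  # the axial-equivalent distance d_eff satisfies
  #   dose = plateau - gradient_axial * d_eff / 100  (fraction of Rx)
  # reducing to plateau - gradient_cc * dz / 100 for pure cranio-caudal
  # offsets and plateau - gradient_axial * dxy / 100 for axial offsets.
  gax <- max(gradient_axial, 1e-6)
  sp_eff <- c(g$spacing[1], g$spacing[2], g$spacing[3] * gradient_cc / gax)
  d_eff <- sqrt(cpp_edt3d_sq(as.logical(ptv), g$shape, sp_eff))
  frac <- pmax(0, plateau - gax * d_eff / 100)
  frac[as.logical(ptv)] <- plateau
  list(dose = dose_grid(array(prescription * frac, g$shape), g), ptv = ptv)
}

#' Generate one fraction's displacement field
#'
#' The field (mm, planning geometry to fraction geometry) is the sum of a
#' constant per-patient systematic offset, a smooth Gaussian random field
#' (white noise smoothed with a Gaussian kernel of the given correlation
#' length, then rescaled so each component's voxelwise SD equals
#' `random_sd`), and optionally a localized Gaussian excursion bump of given
#' amplitude, width and direction centered at a point (typically on the CTV
#' surface). Invertibility of `id + u` is checked by sampling the warp
#' Jacobian; if it is not everywhere positive, the non-systematic part is
#' damped by 20% steps (with a warning) until it is.
#'
#' @param grid a [grid_spec()].
#' @param systematic_offset length-3 constant offset in mm.
#' @param random_sd per-axis SD in mm of the random smooth component.
#' @param correlation_length_mm spatial correlation length in mm (> 0).
#' @param excursion `NULL`, or list with `center` (world mm), `amplitude`
#'   (mm), `sigma_mm`, `direction` (length-3, normalized internally).
#' @param seed integer seed.
#' @return a `displacement_field`.
#' @export
generate_fraction_field <- function(grid, systematic_offset = c(0, 0, 0),
                                    random_sd = c(3.0, 3.3, 3.9),
                                    correlation_length_mm = 20,
                                    excursion = NULL, seed = 1L) {
  stopifnot(correlation_length_mm > 0, all(random_sd >= 0))
  rng <- local_rng(seed)
  base <- array(0, c(grid$shape, 3))
  if (any(random_sd > 0)) {
    # white noise smoothed by a Gaussian of the correlation length; generated
    # on a coarse lattice (fine enough for the kernel) and trilinearly
    # upsampled, then rescaled so each component's voxelwise SD is exact
    cs <- max(max(grid$spacing), correlation_length_mm / 4)
    extent <- (grid$shape - 1) * grid$spacing
    cshape <- pmax(as.integer(ceiling(extent / cs)) + 3L, 4L)
    sigma_cvox <- rep(correlation_length_mm / cs, 3)
    fine_ijk <- as.matrix(expand.grid(
      (seq_len(grid$shape[1]) - 1) * grid$spacing[1] / cs + 1,
      (seq_len(grid$shape[2]) - 1) * grid$spacing[2] / cs + 1,
      (seq_len(grid$shape[3]) - 1) * grid$spacing[3] / cs + 1)) - 1  # 0-based
    for (c in 1:3) {
      if (random_sd[c] == 0) next
      w <- with_rng(rng, rnorm(prod(cshape)))
      sm <- cpp_smooth3d(w, cshape, sigma_cvox)
      up <- cpp_trilinear(sm, cshape, fine_ijk)
      s <- sd(up)
      if (s > 0) up <- up * (random_sd[c] / s)
      base[, , , c] <- up
    }
  }
  bump <- NULL
  if (!is.null(excursion)) {
    dir <- excursion$direction / sqrt(sum(excursion$direction^2))
    xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
    ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
    zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
    s2 <- 2 * excursion$sigma_mm^2
    gx <- exp(-(xs - excursion$center[1])^2 / s2)
    gy <- exp(-(ys - excursion$center[2])^2 / s2)
    gz <- exp(-(zs - excursion$center[3])^2 / s2)
    bump3 <- outer(outer(gx, gy), gz) * excursion$amplitude
    bump <- array(0, c(grid$shape, 3))
    for (c in 1:3) bump[, , , c] <- bump3 * dir[c]
  }
  damp <- 1
  for (try in 1:6) {
    u <- base * damp
    if (!is.null(bump)) u <- u + bump * damp
    for (c in 1:3) u[, , , c] <- u[, , , c] + systematic_offset[c]
    if (warp_jacobian_ok(u, grid)) {
      if (damp < 1)
        warning(sprintf("field amplitude damped by factor %.2f to keep the warp invertible", damp))
      return(displacement_field(u, grid))
    }
    damp <- damp * 0.8
  }
  stop("could not produce an invertible displacement field")
}

# positive-Jacobian check of id + u by forward differences on the lattice
warp_jacobian_ok <- function(u, grid, min_det = 0.05) {
  s <- grid$shape
  J11 <- 1 + diffax(u[, , , 1], 1) / grid$spacing[1]
  J22 <- 1 + diffax(u[, , , 2], 2) / grid$spacing[2]
  J33 <- 1 + diffax(u[, , , 3], 3) / grid$spacing[3]
  J12 <- diffax(u[, , , 1], 2) / grid$spacing[2]
  J13 <- diffax(u[, , , 1], 3) / grid$spacing[3]
  J21 <- diffax(u[, , , 2], 1) / grid$spacing[1]
  J23 <- diffax(u[, , , 2], 3) / grid$spacing[3]
  J31 <- diffax(u[, , , 3], 1) / grid$spacing[1]
  J32 <- diffax(u[, , , 3], 2) / grid$spacing[2]
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  min(det) > min_det
}

# central difference along one axis in voxel units (one-sided at the edges)
diffax <- function(a, axis) {
  s <- dim(a)
  if (s[axis] < 2) return(array(0, s))
  hi <- lapply(s, seq_len); lo <- hi
  hi[[axis]] <- pmin(hi[[axis]] + 1L, s[axis])
  lo[[axis]] <- pmax(lo[[axis]] - 1L, 1L)
  span <- array(rep(2, prod(s)), s)
  edge <- lapply(s, seq_len)
  for (e in c(1L, s[axis])) {
    ed <- edge; ed[[axis]] <- e
    span <- do.call(`[<-`, c(list(span), ed, list(1)))
  }
  (do.call(`[`, c(list(a), hi)) - do.call(`[`, c(list(a), lo))) / span
}

#' Generate a reproducible synthetic patient cohort
#'
#' For each patient: draws a CTV volume, dose gradients and a systematic
#' offset; builds the CTV and planning dose; then for each fraction draws a
#' random smooth displacement field (plus, with probability
#' `large_excursion_prob`, an outward surface excursion), inverts it, and
#' produces the deformed CTV by nearest-neighbour resampling of the planning
#' CTV through the inverse field. Identical config and seed give identical
#' cohorts.
#'
#' @param cfg a [cohort_config()].
#' @return list of `patient_series` objects; each has `patient_id`, `grid`,
#'   `ctv_plan`, `plan_dose` (Gy, total course), `ptv`, `prescription`,
#'   `gradients`, `systematic_offset` and `fractions` (list with `field`,
#'   `ctv` and `excursion` flag).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  rng <- local_rng(cfg$seed)
  lapply(seq_len(cfg$n_patients), function(p) {
    vol <- with_rng(rng, runif(1, cfg$ctv_volume_range[1], cfg$ctv_volume_range[2]))
    gcc <- with_rng(rng, runif(1, cfg$gradient_cc[1], cfg$gradient_cc[2]))
    gax <- with_rng(rng, runif(1, cfg$gradient_axial[1], cfg$gradient_axial[2]))
    # systematic interfraction component: a per-patient fixed smooth
    # deformation pattern. Like random_sd, systematic_sd is defined through
    # deformation-vector differences between distant points (a constant
    # translation would cancel there, and bulk translations are removed by
    # the online rigid match), so the pattern's pointwise SD is sd/sqrt(2).
    sys_seed <- with_rng(rng, sample.int(2^31 - 2, 1))
    sys_field <- generate_fraction_field(cfg$grid, c(0, 0, 0),
                                         cfg$systematic_sd / sqrt(2),
                                         cfg$correlation_length_mm,
                                         seed = sys_seed)
    frange <- seq(cfg$fractions_range[1], cfg$fractions_range[2])
    nfrac <- with_rng(rng, frange[sample.int(length(frange), 1)])
    ctv_seed <- with_rng(rng, sample.int(2^31 - 2, 1))
    ctv <- generate_ctv(cfg$grid, vol, seed = ctv_seed)
    plan <- generate_plan_dose(ctv, cfg$ptv_margin, cfg$prescription_dose,
                               gcc, gax, plateau = cfg$plateau)
    # candidate excursion anchor points: CTV surface voxels
    surf <- ctv_surface_points(ctv)
    centroid <- colMeans(index_to_world(cfg$grid, ijk_of_linear(cfg$grid, which(as.logical(ctv)))))
    fractions <- lapply(seq_len(nfrac), function(i) {
      exc_flag <- with_rng(rng, runif(1)) < cfg$large_excursion_prob
      exc <- NULL
      if (exc_flag) {
        pt <- surf[with_rng(rng, sample.int(nrow(surf), 1)), ]
        dirv <- pt - centroid
        exc <- list(center = pt,
                    amplitude = with_rng(rng, runif(1, cfg$excursion_amplitude_range[1],
                                                    cfg$excursion_amplitude_range[2])),
                    sigma_mm = cfg$excursion_sigma_mm,
                    direction = dirv)
      }
      fseed <- with_rng(rng, sample.int(2^31 - 2, 1))
      # per-fraction random component, same difference-SD convention
      rand_field <- generate_fraction_field(cfg$grid, c(0, 0, 0),
                                            cfg$random_sd / sqrt(2),
                                            cfg$correlation_length_mm, exc, fseed)
      field <- displacement_field(unclass(sys_field) + unclass(rand_field),
                                  cfg$grid)
      inv <- invert_field(field, quiet = TRUE)
      ctv_i <- structure_mask(
        array(cpp_warp_mask_nn(as.logical(ctv), as.numeric(inv$field),
                               cfg$grid$shape, cfg$grid$spacing), cfg$grid$shape),
        cfg$grid)
      if (!any(ctv_i)) stop("deformed CTV left the grid")
      list(field = field, ctv = ctv_i, excursion = exc_flag)
    })
    structure(list(patient_id = sprintf("P%02d", p), grid = cfg$grid,
                   ctv_plan = ctv, plan_dose = plan$dose, ptv = plan$ptv,
                   prescription = cfg$prescription_dose,
                   gradients = c(cc = gcc, axial = gax),
                   systematic_field = sys_field,
                   ctv_volume_cm3 = vol,
                   fractions = fractions),
              class = "patient_series")
  })
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series %s: %s, CTV %.1f cm^3, %d fractions, Rx %g Gy>\n",
              x$patient_id, format(x$grid), x$ctv_volume_cm3,
              length(x$fractions), x$prescription))
  invisible(x)
}

# world coordinates of CTV surface voxels (CTV voxels with a face-neighbour
# outside the CTV), used to anchor excursion bumps
ctv_surface_points <- function(ctv) {
  g <- grid_of(ctv)
  d_in <- distance_to_structure(structure_mask(!ctv, g))
  surf <- as.logical(ctv) & (as.numeric(d_in) <= min(g$spacing) + 1e-9)
  ijk <- ijk_of_linear(g, which(surf))
  index_to_world(g, ijk)
}

# --- seeded sub-streams -----------------------------------------------------
# The generators take explicit seeds but must not clobber the caller's RNG
# state: each gets a private stream advanced across with_rng() calls.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}
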