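#' Regular 3-D grid geometry
#'
#' A `grid_spec` describes the regular voxel grid every volume in a patient
#' series lives on: the number of voxels per axis, the voxel spacing in mm and
#' the world coordinate of the first voxel center (voxel-center convention:
#' the voxel with 1-based index `(i, j, k)` has world coordinate
#' `origin + (c(i, j, k) - 1) * spacing`). Axes are ordered
#' `(x = left-right, y = anterior-posterior, z = cranio-caudal)` and arrays
#' are stored with x fastest, i.e. `dim = shape`.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, world mm of voxel (1,1,1) center.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(64, 64, 64), spacing = c(2, 2, 2))
#' @export
grid_spec <- function(shape, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape must be >= 1 on every axis")
  if (any(spacing <= 0)) stop("grid spacing must be > 0 on every axis")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("<grid %dx%dx%d @ %.3gx%.3gx%.3g mm>",
          x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

#' @export
print.grid_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = c("first", "second")) {
  if (!same_grid(grid_of(a), grid_of(b)))
    stop(sprintf("grid mismatch between %s (%s) and %s (%s)",
                 what[1], format(grid_of(a)), what[2], format(grid_of(b))))
  invisible(TRUE)
}

#' Dose grids, structure masks and displacement fields
#'
#' Volumes are plain R arrays carrying a `grid_spec` attribute:
#' * `dose_grid`: numeric 3-D array, one dose value (Gy) per voxel;
#' * `structure_mask`: logical 3-D array, `TRUE` on the structure;
#' * `displacement_field`: numeric 4-D array `dim = c(shape, 3)` holding the
#'   per-voxel displacement vector in mm that maps a planning-geometry point
#'   to its position in the fraction geometry (`q = p + u(p)`).
#'
#' @param values array of matching dimension (3-D for dose/mask, 4-D with
#'   last extent 3 for fields).
#' @param grid a [grid_spec()].
#' @return The array, classed and carrying the grid as attribute `grid`.
#' @export
dose_grid <- function(values, grid) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("dose array dimensions do not match grid shape")
  structure(values, grid = grid, class = c("dose_grid", "array"))
}

#' @rdname dose_grid
#' @export
structure_mask <- function(values, grid) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("mask array dimensions do not match grid shape")
  storage.mode(values) <- "logical"
  structure(values, grid = grid, class = c("structure_mask", "array"))
}

#' @rdname dose_grid
#' @export
displacement_field <- function(values, grid) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 4L, dim(values)[4] == 3L)
  if (!identical(as.integer(dim(values)[1:3]), grid$shape))
    stop("field array dimensions do not match grid shape")
  structure(values, grid = grid, class = c("displacement_field", "array"))
}

#' Grid of a volume object
#' @param x a `dose_grid`, `structure_mask` or `displacement_field`.
#' @return the attached [grid_spec()].
#' @export
grid_of <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) stop("object carries no grid_spec")
  g
}

#' Convert between world coordinates (mm) and continuous voxel indices
#'
#' `world_to_index` returns 1-based continuous indices; `index_to_world`
#' the inverse. Both accept an n x 3 matrix or a length-3 vector.
#' @param grid a [grid_spec()].
#' @param p points, n x 3 matrix or length-3 vector.
#' @return n x 3 matrix.
#' @export
world_to_index <- function(grid, p) {
  p <- rbind_pts(p)
  sweep(sweep(p, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

#' @rdname world_to_index
#' @export
index_to_world <- function(grid, p) {
  p <- rbind_pts(p)
  sweep(sweep(p - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  stopifnot(ncol(p) == 3)
  p
}

#' Sample a dose grid or displacement field at world points
#'
#' Trilinear interpolation; points outside the grid are clamped to the
#' boundary value. For a field, each of the three components is interpolated
#' independently.
#'
#' @param x a `dose_grid` or `displacement_field`.
#' @param p world coordinates (mm), n x 3 matrix or length-3 vector.
#' @return numeric vector (dose) or n x 3 matrix (field vectors, mm).
#' @export
sample_at <- function(x, p) {
  g <- grid_of(x)
  ip <- world_to_index(g, p) - 1  # 0-based for the C++ kernel
  if (inherits(x, "displacement_field"))
    cpp_sample_field(as.numeric(x), g$shape, ip)
  else
    cpp_trilinear(as.numeric(x), g$shape, ip)
}

#' Euclidean distance map to a structure
#'
#' Distance (mm) from every voxel center to the nearest voxel center of the
#' structure, honouring anisotropic spacing. The complement's distance map
#' (`outside = TRUE`, the default) is the minimal isotropic expansion radius
#' at which the expanded structure first covers each voxel.
#'
#' @param mask a `structure_mask`.
#' @param spacing_override optional spacing used for the metric instead of
#'   the grid spacing (used for anisotropic dose-falloff construction).
#' @return numeric 3-D array of distances in mm (0 on the structure).
#' @export
distance_to_structure <- function(mask, spacing_override = NULL) {
  g <- grid_of(mask)
  if (!any(mask)) stop("distance map of an empty structure is undefined")
  sp <- if (is.null(spacing_override)) g$spacing else as.numeric(spacing_override)
  d2 <- cpp_edt3d_sq(as.logical(mask), g$shape, sp)
  array(sqrt(d2), dim = g$shape)
}

#' Dilate a structure by an isotropic margin in mm
#' @param mask a `structure_mask`.
#' @param margin_mm margin in mm (>= 0).
#' @return a `structure_mask`.
#' @export
dilate_mask <- function(mask, margin_mm) {
  stopifnot(margin_mm >= 0)
  g <- grid_of(mask)
  d <- distance_to_structure(mask)
  structure_mask(d <= margin_mm, g)
}

#' Voxel volume in cm^3
#' @param grid a [grid_spec()].
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

linear_index <- function(grid, ijk) {
  # 1-based linear index from 1-based integer (i,j,k)
  ijk <- rbind_pts(ijk)
  s <- grid$shape
  as.integer(ijk[, 1] + s[1] * (ijk[, 2] - 1) + s[1] * s[2] * (ijk[, 3] - 1))
}

ijk_of_linear <- function(grid, l) {
  s <- grid$shape
  l0 <- l - 1L
  i <- l0 %% s[1]
  j <- (l0 %/% s[1]) %% s[2]
  k <- l0 %/% (s[1] * s[2])
  cbind(i, j, k) + 1L
}
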