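#' Read and write grids as NIfTI
#'
#' Doses and masks are stored as 3-D NIfTI volumes, displacement fields as
#' 4-D volumes with three components (mm). Spacing is carried in `pixdim`
#' and the origin in the sform translation; round trips preserve shape,
#' spacing and origin, masks bit-exactly and doses/fields to single float
#' tolerance (NIfTI data are written as float32).
#'
#' @param x a `dose_grid`, `structure_mask` or `displacement_field`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_grid` returns `path` invisibly; `read_grid` returns the
#'   reconstructed object.
#' @export
write_grid <- function(x, path) {
  g <- grid_of(x)
  arr <- unclass(x)
  attr(arr, "grid") <- NULL
  if (inherits(x, "structure_mask")) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  xform <- diag(4)
  diag(xform)[1:3] <- g$spacing
  xform[1:3, 4] <- g$origin
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  RNifti::pixdim(img) <- c(g$spacing, if (length(dim(arr)) == 4) 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_grid
#' @param kind one of "dose", "mask", "field"; "auto" infers a field from a
#'   4-D volume and otherwise returns a dose (use `kind = "mask"` to get a
#'   `structure_mask`).
#' @export
read_grid <- function(path, kind = c("auto", "dose", "mask", "field")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (!nd %in% c(3L, 4L)) stop(sprintf("unsupported NIfTI dimensionality in %s", path))
  sf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- sf[1:3, 4]
  g <- grid_spec(dim(img)[1:3], spacing, origin)
  arr <- array(as.numeric(img), dim(img))
  if (kind == "auto") kind <- if (nd == 4L) "field" else "dose"
  switch(kind,
         dose = dose_grid(arr, g),
         mask = structure_mask(arr != 0, g),
         field = {
           if (nd != 4L || dim(arr)[4] != 3L)
             stop(sprintf("%s is not a 3-component field", path))
           displacement_field(arr, g)
         })
}

#' Write and read a DVH as a two-column CSV
#'
#' Columns `dose_gy` (bin edges) and `cum_volume`. Reading reconstructs a
#' `dvh` usable by [dose_percentile()]; the exact per-bin mean doses are not
#' stored, so [geud()] on a re-read DVH uses bin midpoints.
#'
#' @param dvh a [compute_dvh()] result.
#' @param path CSV path.
#' @export
write_dvh_csv <- function(dvh, path) {
  write.csv(data.frame(dose_gy = dvh$bin_edges, cum_volume = dvh$cum_volume),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @export
read_dvh_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("dose_gy", "cum_volume") %in% names(df)))
  edges <- df$dose_gy
  cum <- df$cum_volume
  nb <- length(edges) - 1L
  diffv <- cum[seq_len(nb)] - cum[seq_len(nb) + 1L]
  structure(list(bin_edges = edges, cum_volume = cum,
                 bin_dose = (edges[seq_len(nb)] + edges[seq_len(nb) + 1L]) / 2,
                 diff_volume = diffv, n_voxels = NA_integer_),
            class = "dvh")
}

#' Write a per-fraction feature table as CSV
#' @param features data.frame from [extract_cohort_features()].
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

# short stable checksum of a configuration for provenance sidecars
config_checksum <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
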