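#' Construct a 3D OCT volume object
#'
#' Container for a macular OCT scan: a 3D voxel grid of backscatter
#' intensity in arbitrary units (AU) on the 16-bit export scale, plus the
#' acquisition metadata needed downstream.  The coordinate convention is
#' `voxels[x, y, z]` with `x` the A-scan (column) within a B-scan, `y` the
#' B-scan index, and `z` depth, starting at the vitreous side and increasing
#' posteriorly.
#'
#' @param voxels numeric 3D array `(nx, ny, nz)`; all values in `[0, 65535]`.
#' @param spacing lateral spacing in mm per voxel, `c(x = , y = )`.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param imageQ device image-quality score (dimensionless).
#' @param axial_spacing_mm axial voxel pitch in mm (metadata only; no
#'   computation in this package uses it).
#' @param subject_id,operator optional identifier strings.
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(voxels, spacing, laterality = c("OD", "OS"),
                       imageQ = NA_real_, axial_spacing_mm = NA_real_,
                       subject_id = NULL, operator = NULL) {
  laterality <- match.arg(laterality)
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array (x, y, z)")
  d <- dim(voxels)
  if (d[1] < 8 || d[2] < 2 || d[3] < 16)
    stop(sprintf("volume too small: dims (%d, %d, %d); need at least (8, 2, 16)",
                 d[1], d[2], d[3]))
  rng <- range(voxels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 65535)
    stop("voxel intensities must be finite and within [0, 65535]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive values (mm/column, mm/B-scan)")
  structure(list(voxels = voxels,
                 spacing = c(x = spacing[1], y = spacing[2]),
                 axial_spacing_mm = axial_spacing_mm,
                 laterality = laterality,
                 imageQ = imageQ,
                 subject_id = subject_id,
                 operator = operator),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<oct_volume> %d x %d x %d voxels (%s), %.3f x %.3f mm lateral spacing, imageQ %.1f\n",
              d[1], d[2], d[3], x$laterality, x$spacing[1], x$spacing[2], x$imageQ))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$voxels)

# canonical layer naming, anterior to posterior
.layers <- c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "PR", "RPE")

# layer -> bounding surface indices, half-open bands [S_lo, S_hi)
.layer_surfaces <- list(RNFL = c(1L, 2L), GCL = c(2L, 3L), IPL = c(3L, 4L),
                        INL = c(4L, 5L), OPL = c(5L, 6L), ONL = c(6L, 7L),
                        PR = c(7L, 10L), RPE = c(10L, 11L))

#' Set of eleven ordered intraretinal surfaces
#'
#' Bundles 11 height maps (surface 1 = internal limiting membrane to
#' surface 11 = outer retinal pigment epithelium boundary) into a validated
#' `surface_set`.  Surfaces are `(nx x ny)` integer matrices of depth voxel
#' indices and must be ordered `S_i <= S_{i+1}` at every A-scan.  The eight
#' analysed layers are the half-open voxel bands RNFL = \[S1, S2), GCL =
#' \[S2, S3), IPL = \[S3, S4), INL = \[S4, S5), OPL = \[S5, S6), ONL =
#' \[S6, S7), photoreceptor = \[S7, S10) and RPE = \[S10, S11).
#'
#' @param surfaces list of 11 `(nx x ny)` matrices, anterior to posterior.
#' @param min_separation optional vector of 10 minimum separations (voxels)
#'   that consecutive pairs are asserted to respect; 0 to skip.
#' @return object of class `surface_set`.
#' @export
surface_set <- function(surfaces, min_separation = rep(0L, 10L)) {
  if (length(surfaces) != 11)
    stop("a surface_set needs exactly 11 surfaces")
  d <- dim(surfaces[[1]])
  for (i in seq_along(surfaces)) {
    if (!is.matrix(surfaces[[i]]) || !identical(dim(surfaces[[i]]), d))
      stop("all surfaces must be matrices with identical dimensions")
  }
  for (i in 1:10) {
    gap <- surfaces[[i + 1]] - surfaces[[i]]
    if (any(gap < min_separation[i]))
      stop(sprintf("surface ordering violated: S%d and S%d are separated by less than %d voxel(s)",
                   i, i + 1, min_separation[i]))
  }
  structure(list(z = surfaces, dims = d), class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> 11 surfaces over a %d x %d A-scan grid; mean depths: %s\n",
              x$dims[1], x$dims[2],
              paste(sprintf("%.0f", vapply(x$z, mean, 0)), collapse = " ")))
  invisible(x)
}
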