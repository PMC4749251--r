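# Fovea localisation and ETDRS sector grid.
#
# The fovea is taken as the deepest point of surface 1 (the internal
# limiting membrane): the foveal pit is the unique posterior-most location
# of the ILM in a normal macula.  The ETDRS chart is three concentric
# circles of 1, 3 and 6 mm diameter centred on the fovea, with the two
# rings split into superior / inferior / nasal / temporal quadrants at the
# +-45 degree diagonals.  All geometry is computed in millimetres so the
# strongly anisotropic A-scan/B-scan pixel spacing is handled correctly.
#
# En-face orientation convention: within a B-scan, x increases from
# temporal to nasal for OD volumes (and the mirror for OS); B-scan index y
# increases from inferior to superior.

.sectors <- c("Cen", "Sin", "Nin", "Iin", "Tin", "Sout", "Nout", "Iout", "Tout")

#' Locate the fovea as the deepest point of surface 1
#'
#' The ILM height map is median-presmoothed (separable running median) and
#' the location of maximal depth is returned; ties are resolved by the
#' centroid of the deepest set.  A surface so flat that the deepest set
#' covers more than a quarter of the grid is rejected as ambiguous.
#'
#' @param s1 surface 1 as an `(nx x ny)` matrix of depths, or a
#'   [surface_set] (its first surface is used).
#' @param presmooth median window `c(wx, wy)` in grid units (odd values);
#'   `c(1, 1)` disables smoothing.
#' @return centre as `c(x, y)` in (possibly fractional) grid indices.
#' @export
locate_fovea <- function(s1, presmooth = c(5L, 3L)) {
  if (inherits(s1, "surface_set")) s1 <- s1$z[[1]]
  stopifnot(is.matrix(s1))
  sm <- .median2d(s1, presmooth[1], presmooth[2])
  mx <- max(sm)
  hits <- which(sm == mx, arr.ind = TRUE)
  if (nrow(hits) > 0.25 * length(sm))
    stop("ambiguous fovea: surface 1 is too flat (deepest set covers >25% of the grid)")
  c(x = mean(hits[, 1]), y = mean(hits[, 2]))
}

# separable running median with replicate padding
.median2d <- function(m, wx, wy) {
  run_med <- function(mat, w, along) {
    if (w <= 1) return(mat)
    h <- (w - 1L) %/% 2L
    n <- if (along == 1) nrow(mat) else ncol(mat)
    idx <- lapply(-h:h, function(o) pmin(pmax(seq_len(n) + o, 1L), n))
    if (along == 1) {
      arr <- vapply(idx, function(i) mat[i, , drop = FALSE],
                    matrix(0, nrow(mat), ncol(mat)))
    } else {
      arr <- vapply(idx, function(i) mat[, i, drop = FALSE],
                    matrix(0, nrow(mat), ncol(mat)))
    }
    apply(arr, c(1, 2), median)
  }
  run_med(run_med(m, wx, 1), wy, 2)
}

#' Build the 9-sector ETDRS grid around a fovea centre
#'
#' Ring membership uses the Euclidean distance in mm from the centre:
#' central subfield up to 0.5 mm, inner ring 0.5 to 1.5 mm, outer ring
#' 1.5 to 3.0 mm.  Rings are split into quadrants at the diagonals, with
#' half-open angular intervals so every pixel belongs to exactly one
#' sector; the nasal direction is `+x` for OD and `-x` for OS.  If the 6-mm
#' disc extends beyond the scanned area the masks are clipped and a
#' warning reports the affected coverage.
#'
#' @param center fovea centre `c(x, y)` in grid indices (may be fractional).
#' @param laterality `"OD"` or `"OS"`.
#' @param dims grid size `c(nx, ny)`.
#' @param spacing pixel spacing `c(mm/column, mm/B-scan)`.
#' @param radii_mm the three ring radii, by default `c(0.5, 1.5, 3)`.
#' @return an `etdrs_grid`: factor label matrix (`NA` outside the chart),
#'   centre, radii, laterality, pixel area (mm^2) and a `clipped` flag.
#' @export
build_etdrs_masks <- function(center, laterality = c("OD", "OS"),
                              dims, spacing, radii_mm = c(0.5, 1.5, 3)) {
  laterality <- match.arg(laterality)
  nx <- dims[1]; ny <- dims[2]
  sx <- spacing[1]; sy <- spacing[2]
  stopifnot(sx > 0, sy > 0, length(radii_mm) == 3, all(diff(radii_mm) > 0))
  if (center[1] < 1 || center[1] > nx || center[2] < 1 || center[2] > ny)
    stop("fovea centre lies outside the grid")
  dxmm <- (seq_len(nx) - center[1]) * sx
  dymm <- (seq_len(ny) - center[2]) * sy
  r <- sqrt(outer(dxmm^2, dymm^2, `+`))
  ring <- matrix(NA_integer_, nx, ny)
  ring[r <= radii_mm[3]] <- 3L
  ring[r <= radii_mm[2]] <- 2L
  ring[r <= radii_mm[1]] <- 1L

  nasal_sign <- if (laterality == "OD") 1 else -1
  u <- matrix(nasal_sign * dxmm, nx, ny)          # mm toward nasal
  v <- matrix(rep(dymm, each = nx), nx, ny)       # mm toward superior
  ang <- atan2(v, u) * 180 / pi
  quad <- ifelse(ang >= -45 & ang < 45, "N",
                 ifelse(ang >= 45 & ang < 135, "S",
                        ifelse(ang >= -135 & ang < -45, "I", "T")))
  lab <- matrix(NA_character_, nx, ny)
  lab[ring == 1L & !is.na(ring)] <- "Cen"
  inner <- !is.na(ring) & ring == 2L
  outer_ <- !is.na(ring) & ring == 3L
  lab[inner] <- paste0(quad[inner], "in")
  lab[outer_] <- paste0(quad[outer_], "out")

  clipped <- (center[1] - 1) * sx < radii_mm[3] ||
    (nx - center[1]) * sx < radii_mm[3] ||
    (center[2] - 1) * sy < radii_mm[3] ||
    (ny - center[2]) * sy < radii_mm[3]
  if (clipped)
    warning("ETDRS chart extends beyond the scanned area; sector masks are clipped")

  label <- matrix(factor(lab, levels = .sectors), nx, ny)
  structure(list(label = label, center = center,
                 center_mm = c(x = (center[1] - 1) * sx, y = (center[2] - 1) * sy),
                 radii_mm = radii_mm, laterality = laterality,
                 pixel_area_mm2 = sx * sy, clipped = clipped),
            class = "etdrs_grid")
}

#' Sector areas of an ETDRS grid
#'
#' Rasterised area (pixel count times pixel area) per sector, for
#' comparison with the analytic ring/quadrant areas.
#'
#' @param grid an `etdrs_grid`.
#' @return named numeric vector of areas in mm^2.
#' @export
etdrs_sector_areas <- function(grid) {
  stopifnot(inherits(grid, "etdrs_grid"))
  counts <- table(factor(grid$label, levels = .sectors))
  as.numeric(counts) * grid$pixel_area_mm2 -> a
  names(a) <- .sectors
  a
}

#' Export the sector labels as a small integer-coded TIFF image
#'
#' Writes a single-page image with values 0 (outside) and 1..9 coding the
#' sectors in the order Cen, Sin, Nin, Iin, Tin, Sout, Nout, Iout, Tout,
#' for visual inspection.
#'
#' @param grid an `etdrs_grid`.
#' @param path output `.tif` path.
#' @export
write_etdrs_labels <- function(grid, path) {
  stopifnot(inherits(grid, "etdrs_grid"))
  code <- matrix(as.integer(grid$label), nrow(grid$label), ncol(grid$label))
  code[is.na(code)] <- 0L
  tiff::writeTIFF(t(code) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}
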