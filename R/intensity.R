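# Mean optical intensity per retinal layer and ETDRS sector.
#
# Optical intensity is the mean gray value (AU, 16-bit scale) of all raw
# voxels in the target region: a layer is the half-open depth band between
# its bounding surfaces, a region is an ETDRS sector mask, the whole chart
# (all nine sectors pooled) or the whole scan raster.  Statistics are
# always taken on the raw exported voxels, never on the denoised volume.

#' Layer-by-sector optical intensity table
#'
#' For every layer and ETDRS sector, computes the mean, SD and voxel count
#' of raw intensity over voxels whose A-scan lies in the sector mask and
#' whose depth lies in the layer's half-open surface band.  Per-layer
#' pooled rows are appended for the whole ETDRS chart (`sector =
#' "WholeETDRS"`) and the whole scan raster (`sector = "WholeScan"`).
#' Empty layer-sector combinations (possible when the chart is clipped)
#' get count 0 and an undefined (`NA`) mean, with a warning.
#'
#' @param vol raw [oct_volume].
#' @param surfaces a [surface_set] from the same volume.
#' @param grid an `etdrs_grid` from [build_etdrs_masks()].
#' @return data.frame with columns `layer`, `sector`, `mean_au`, `sd_au`,
#'   `n_voxels`.
#' @export
layer_sector_intensity <- function(vol, surfaces, grid) {
  stopifnot(inherits(vol, "oct_volume"), inherits(surfaces, "surface_set"),
            inherits(grid, "etdrs_grid"))
  d <- dim(vol$voxels)
  if (!identical(surfaces$dims, d[1:2]) ||
      !identical(dim(grid$label), d[1:2]))
    stop("surfaces / grid dimensions do not match the volume")
  nc <- d[1] * d[2]; nz <- d[3]

  m <- matrix(vol$voxels, nc, nz)
  cs <- m; cs2 <- m * m
  for (z in 2:nz) {
    cs[, z] <- cs[, z] + cs[, z - 1]
    cs2[, z] <- cs2[, z] + cs2[, z - 1]
  }
  band_sums <- function(lo, hi) {
    # per-A-scan sums over z in [lo, hi), empty when hi <= lo
    lo <- as.vector(lo); hi <- as.vector(hi)
    n <- pmax(hi - lo, 0L)
    hi_i <- pmin(pmax(hi - 1L, 1L), nz)
    lo_i <- lo - 1L
    s <- cs[cbind(seq_len(nc), hi_i)] -
      ifelse(lo_i >= 1L, cs[cbind(seq_len(nc), pmax(lo_i, 1L))], 0)
    s2 <- cs2[cbind(seq_len(nc), hi_i)] -
      ifelse(lo_i >= 1L, cs2[cbind(seq_len(nc), pmax(lo_i, 1L))], 0)
    s[n == 0L] <- 0; s2[n == 0L] <- 0
    list(n = n, s = s, s2 = s2)
  }

  sector <- as.character(as.vector(grid$label))   # NA outside the chart
  rows <- list()
  for (l in seq_along(.layers)) {
    b <- .layer_surfaces[[l]]
    bs <- band_sums(surfaces$z[[b[1]]], surfaces$z[[b[2]]])
    grp <- factor(sector, levels = .sectors)
    agg <- function(keep) {
      n <- sum(bs$n[keep]); s <- sum(bs$s[keep]); s2 <- sum(bs$s2[keep])
      mean_au <- if (n > 0) s / n else NA_real_
      sd_au <- if (n > 1) sqrt(max(0, (s2 - s^2 / n) / (n - 1))) else NA_real_
      c(mean_au = mean_au, sd_au = sd_au, n = n)
    }
    per_sector <- vapply(.sectors, function(sec)
      agg(!is.na(sector) & sector == sec), numeric(3))
    whole_chart <- agg(!is.na(sector))
    whole_scan <- agg(rep(TRUE, nc))
    rows[[l]] <- data.frame(
      layer = .layers[l],
      sector = c(.sectors, "WholeETDRS", "WholeScan"),
      mean_au = c(per_sector[1, ], whole_chart[1], whole_scan[1]),
      sd_au = c(per_sector[2, ], whole_chart[2], whole_scan[2]),
      n_voxels = as.integer(c(per_sector[3, ], whole_chart[3], whole_scan[3])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n_voxels == 0L))
    warning("some layer-sector combinations contain no voxels (clipped chart?)")
  out
}

#' Collect per-volume layer means into cohort intensity columns
#'
#' Extracts the per-layer whole-ETDRS (or whole-scan) means from a list of
#' intensity tables and binds them into one row per volume, ready to join
#' with per-subject covariates.
#'
#' @param tables named list of tables from [layer_sector_intensity()].
#' @param scope `"WholeETDRS"` or `"WholeScan"`.
#' @return data.frame with `subject_id` and one column per layer.
#' @export
cohort_intensity <- function(tables, scope = c("WholeETDRS", "WholeScan")) {
  scope <- match.arg(scope)
  rows <- lapply(names(tables), function(id) {
    t <- tables[[id]]
    sel <- t[t$sector == scope, ]
    vals <- as.list(setNames(sel$mean_au, sel$layer)[.layers])
    names(vals) <- .layers
    cbind(data.frame(subject_id = id, stringsAsFactors = FALSE),
          as.data.frame(vals, row.names = NULL))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
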