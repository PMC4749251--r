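# Volume, surface and table I/O in open containers.
#
# Proprietary vendor exports are out of scope: volumes travel as 16-bit
# multi-page TIFF (one page per B-scan, rows = depth, columns = A-scans) or
# NIfTI-1, with a JSON sidecar holding the acquisition metadata that the
# image container cannot carry (lateral spacing, laterality, image quality).
# All round trips are lossless on the 16-bit AU scale.

.sidecar_required <- c("spacing_x_mm", "spacing_y_mm", "laterality", "imageQ")

#' Write an OCT volume to an open container with a JSON sidecar
#'
#' @param vol an [oct_volume].
#' @param path output path ending in `.tif`/`.tiff` (multi-page 16-bit TIFF)
#'   or `.nii` (NIfTI-1, uint16).
#' @param sidecar path for the JSON metadata sidecar; defaults to `path`
#'   with a `.json` extension appended.
#' @return invisibly, the sidecar path.
#' @export
write_volume <- function(vol, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(vol, "oct_volume"))
  if (!is.character(path) || length(path) != 1 || !nzchar(path))
    stop("a non-empty output path is required")
  arr <- round(vol$voxels)
  d <- dim(arr)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(d[2]), function(y) t(arr[, y, ]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else if (grepl("\\.nii$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "uint16")
  } else {
    stop("unsupported container (use .tif/.tiff or .nii): ", path)
  }
  meta <- list(spacing_x_mm = unname(vol$spacing[1]),
               spacing_y_mm = unname(vol$spacing[2]),
               axial_spacing_mm = vol$axial_spacing_mm,
               laterality = vol$laterality,
               imageQ = vol$imageQ,
               subject_id = vol$subject_id,
               operator = vol$operator,
               dims = d)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}

#' Read an OCT volume from an open container plus JSON sidecar
#'
#' The container must hold 16-bit data and its dimensions must match the
#' sidecar's `dims` record; any missing required sidecar field is an error.
#'
#' @param path `.tif`/`.tiff` or `.nii` file written by [write_volume()]
#'   (or equivalent).
#' @param sidecar JSON sidecar path.
#' @return an [oct_volume]; round-trips with [write_volume()] bit-exactly.
#' @export
read_volume <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing_fields <- setdiff(.sidecar_required, names(meta))
  present <- intersect(.sidecar_required, names(meta))
  missing_fields <- c(missing_fields,
                      present[vapply(meta[present], is.null, TRUE)])
  if (length(missing_fields))
    stop("sidecar is missing required field(s): ",
         paste(unique(missing_fields), collapse = ", "))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(tiff::readTIFF(path, payload = FALSE), "bits.per.sample")
    if (!is.null(bits) && bits != 16)
      stop(sprintf("expected 16-bit TIFF data, found %d-bit", bits))
    if (max(vapply(pages, max, 0)) < 256 && is.null(bits))
      stop("TIFF does not appear to contain 16-bit data")
    d <- c(ncol(pages[[1]]), length(pages), nrow(pages[[1]]))
    arr <- array(0, d)
    for (y in seq_along(pages)) arr[, y, ] <- t(pages[[y]])
  } else if (grepl("\\.nii$", path, ignore.case = TRUE)) {
    hdr <- RNifti::niftiHeader(path)  # on-disk datatype; readNifti promotes in memory
    im <- RNifti::readNifti(path)
    if (hdr$bitpix != 16)
      stop(sprintf("expected 16-bit NIfTI data, found %d-bit", hdr$bitpix))
    arr <- array(as.numeric(im), dim(im))
    d <- dim(arr)
  } else {
    stop("unsupported container (use .tif/.tiff or .nii): ", path)
  }
  if (!is.null(meta$dims) && !identical(as.integer(meta$dims), as.integer(d)))
    stop(sprintf("dimension mismatch: container %s vs sidecar %s",
                 paste(d, collapse = "x"),
                 paste(meta$dims, collapse = "x")))
  oct_volume(arr,
             spacing = c(meta$spacing_x_mm, meta$spacing_y_mm),
             laterality = meta$laterality,
             imageQ = meta$imageQ,
             axial_spacing_mm = if (is.null(meta$axial_spacing_mm)) NA_real_ else meta$axial_spacing_mm,
             subject_id = meta$subject_id,
             operator = meta$operator)
}

#' Write a result table as CSV
#'
#' Fixed column order, header row, non-finite values (e.g. the undefined
#' mean of an empty sector) serialised as empty cells.  Numeric read-back
#' via [read_table_csv()] agrees to full double precision.
#'
#' @param table a data.frame.
#' @param path output CSV path.
#' @export
write_table_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (!is.character(path) || length(path) != 1 || !nzchar(path))
    stop("a non-empty output path is required")
  tab <- table
  for (j in seq_along(tab)) {
    if (is.numeric(tab[[j]])) {
      v <- sprintf("%.17g", tab[[j]])
      v[!is.finite(tab[[j]])] <- ""
      tab[[j]] <- v
    }
  }
  write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a CSV table written by [write_table_csv()]
#' @param path CSV path.
#' @return data.frame with empty numeric cells as `NA`.
#' @export
read_table_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(d)) {
    if (is.character(d[[j]])) {
      suppressWarnings(num <- as.numeric(d[[j]]))
      blank <- d[[j]] == "" | is.na(d[[j]])
      if (all(!is.na(num) | blank) && any(!blank)) {
        num[blank] <- NA_real_
        d[[j]] <- num
      }
    }
  }
  d
}

#' Write a surface set as CSV
#'
#' One row per A-scan `(x, y)` and one column per surface (`S1` .. `S11`),
#' depths in voxel units.
#'
#' @param surfaces a [surface_set].
#' @param path output CSV path.
#' @export
write_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_set"))
  d <- surfaces$dims
  out <- data.frame(x = rep(seq_len(d[1]), d[2]),
                    y = rep(seq_len(d[2]), each = d[1]))
  for (i in 1:11) out[[paste0("S", i)]] <- as.vector(surfaces$z[[i]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a surface set written by [write_surfaces()]
#' @param path CSV path.
#' @return a [surface_set].
#' @export
read_surfaces <- function(path) {
  d <- read.csv(path)
  nx <- max(d$x); ny <- max(d$y)
  ord <- order(d$y, d$x)
  surface_set(lapply(1:11, function(i)
    matrix(as.integer(d[[paste0("S", i)]][ord]), nx, ny)))
}
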