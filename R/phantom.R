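# Synthetic macular OCT phantoms with known ground truth.
#
# The phantom is a stack of plane-parallel tissue bands bounded by 11
# surfaces, deformed by a radially Gaussian foveal pit whose amplitude
# decays linearly across the inner surfaces and vanishes at the external
# limiting membrane.  Per-band reflectivity defaults reproduce the layer
# mean intensities and regional (central and nasal/temporal) patterns
# reported for normal eyes on the 16-bit AU scale.

.default_band_au <- c(RNFL = 31558.68, GCL = 26653.71, IPL = 26677.85,
                      INL = 23538.66, OPL = 24824.14, ONL = 21381.69,
                      IS = 33200, OS = 30100, IZ = 33500, RPE = 34677.2)
.band_layer <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 7L, 7L, 8L)

# central-subfield offset (Cen minus whole-ETDRS mean) per layer, AU
.default_central_au <- c(RNFL = -7456.16, GCL = -1600.48, IPL = -774.27,
                         INL = 513.39, OPL = -800.52, ONL = 104.96,
                         PR = -185.57, RPE = 1353.58)
# nasal-temporal half-difference (outer-ring nasal minus temporal over 2), AU
.default_nasal_au <- c(RNFL = 1385.22, GCL = 208.84, IPL = 5.44,
                       INL = -64.22, OPL = -35.72, ONL = -99.14,
                       PR = -356.19, RPE = -249.65)

#' Specification of a synthetic macular OCT phantom
#'
#' Describes the geometry, per-band reflectivity, regional modulation and
#' noise model of a layered retinal phantom.  The 11 surfaces are flat
#' parametric height maps (given as fractions of the depth range) deformed
#' by a radial-Gaussian foveal pit applied to surfaces 1-6 with amplitude
#' decaying linearly to zero at surface 7 (the external limiting membrane).
#'
#' Reflectivity of the 10 inter-surface bands defaults to normative layer
#' means in AU; regional modulation adds, per layer, a central Gaussian
#' term (negative = foveal depression of intensity, positive for the RPE)
#' and a linear nasal-temporal gradient signed by laterality.  Speckle is
#' multiplicative gamma noise with unit mean (shape `speckle_shape`), the
#' axial point-spread function is a Gaussian blur applied after speckle,
#' and `noise_floor` is a constant additive offset.
#'
#' @param dims integer c(nx, ny, nz): A-scans per B-scan, B-scans, depth.
#' @param extent_mm lateral scan extent c(x, y) in mm.
#' @param laterality "OD" or "OS".
#' @param surface_fracs 11 increasing depth fractions in (0, 1).
#' @param band_au 10 band reflectivities (AU), anterior to posterior:
#'   RNFL, GCL, IPL, INL, OPL, ONL, inner segments, outer segments,
#'   pre-RPE (interdigitation) band, RPE.
#' @param vitreous_au,choroid_au background reflectivity above S1 / below S11.
#' @param central_au,nasal_au per-layer modulation amplitudes (AU), length 8.
#' @param central_sigma_mm radial scale of the central modulation term.
#' @param pit_center_frac pit centre as fractions of the lateral extent.
#' @param pit_depth_frac pit amplitude at surface 1, fraction of depth.
#' @param pit_sigma_mm radial scale of the pit.
#' @param speckle_shape gamma shape of multiplicative speckle (unit mean);
#'   `Inf` disables speckle.
#' @param noise_floor additive constant offset (AU).
#' @param blur_sigma_voxels axial Gaussian PSF sigma; 0 disables blur.
#' @param imageQ image-quality score recorded in the volume metadata.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(128L, 32L, 256L),
                         extent_mm = c(6, 6),
                         laterality = c("OD", "OS"),
                         surface_fracs = c(55, 70, 88, 106, 120, 130,
                                           160, 166, 173, 175, 187) / 256,
                         band_au = .default_band_au,
                         vitreous_au = 6000, choroid_au = 16000,
                         central_au = .default_central_au,
                         nasal_au = .default_nasal_au,
                         central_sigma_mm = 0.5,
                         pit_center_frac = c(0.5, 0.5),
                         pit_depth_frac = 35 / 256,
                         pit_sigma_mm = 0.4,
                         speckle_shape = 20,
                         noise_floor = 0,
                         blur_sigma_voxels = 1,
                         imageQ = 58) {
  laterality <- match.arg(laterality)
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(is.na(dims)))
    stop("dims must be three integers (nx, ny, nz)")
  if (dims[1] < 8 || dims[2] < 2 || dims[3] < 16)
    stop(sprintf("phantom dims (%d, %d, %d) below the minimum (8, 2, 16)",
                 dims[1], dims[2], dims[3]))
  if (length(surface_fracs) != 11 || any(diff(surface_fracs) <= 0))
    stop("surface_fracs must be 11 strictly increasing depth fractions")
  if (any(surface_fracs <= 0) || any(surface_fracs >= 1))
    stop("surface_fracs must lie strictly inside (0, 1)")
  if (length(band_au) != 10)
    stop("band_au must give 10 band reflectivities")
  all_au <- c(band_au, vitreous_au, choroid_au)
  if (any(all_au < 0) || any(all_au > 65535))
    stop("reflectivities must be within [0, 65535]")
  if (length(central_au) != 8 || length(nasal_au) != 8)
    stop("central_au and nasal_au must have one amplitude per layer (8)")
  if (speckle_shape <= 0) stop("speckle_shape must be positive (or Inf)")
  spec <- list(dims = dims, extent_mm = as.numeric(extent_mm),
               laterality = laterality,
               surface_fracs = as.numeric(surface_fracs),
               band_au = as.numeric(band_au),
               vitreous_au = vitreous_au, choroid_au = choroid_au,
               central_au = as.numeric(central_au),
               nasal_au = as.numeric(nasal_au),
               central_sigma_mm = central_sigma_mm,
               pit_center_frac = as.numeric(pit_center_frac),
               pit_depth_frac = pit_depth_frac,
               pit_sigma_mm = pit_sigma_mm,
               speckle_shape = speckle_shape,
               noise_floor = noise_floor,
               blur_sigma_voxels = blur_sigma_voxels,
               imageQ = imageQ)
  class(spec) <- "phantom_spec"
  # fail early if the discretised surfaces would touch or cross
  .phantom_truth(spec)
  spec
}

# continuous surface height maps (voxel units), then discretised truth
.phantom_truth <- function(spec, center_shift = c(0, 0)) {
  nx <- spec$dims[1]; ny <- spec$dims[2]; nz <- spec$dims[3]
  sx <- spec$extent_mm[1] / nx; sy <- spec$extent_mm[2] / ny
  cx <- spec$pit_center_frac[1] * (nx + 1) + center_shift[1]
  cy <- spec$pit_center_frac[2] * (ny + 1) + center_shift[2]
  xmm <- (seq_len(nx) - cx) * sx
  ymm <- (seq_len(ny) - cy) * sy
  r2 <- outer(xmm^2, ymm^2, `+`)
  pit <- spec$pit_depth_frac * nz * exp(-r2 / (2 * spec$pit_sigma_mm^2))
  surfaces <- vector("list", 11)
  for (i in 1:11) {
    amp <- if (i <= 7) (1 - (i - 1) / 6) else 0
    surfaces[[i]] <- round(spec$surface_fracs[i] * nz + amp * pit)
  }
  for (i in 1:10) {
    bad <- surfaces[[i + 1]] - surfaces[[i]] < 1
    if (any(bad))
      stop(sprintf("phantom surfaces S%d and S%d touch or cross after discretisation",
                   i, i + 1))
  }
  if (surfaces[[11]][1, 1] > nz || surfaces[[1]][1, 1] < 1)
    stop("phantom surfaces extend outside the depth range")
  surface_set(lapply(surfaces, function(m) { storage.mode(m) <- "integer"; m }))
}

# PSF pre-compensation of band reflectivities.  The configured band values
# are the *measured* mean intensities the bands should exhibit after the
# axial point-spread function has mixed neighbouring bands (normative
# tables report means measured on real, PSF-limited data).  Rendering the
# nominal values and blurring again would double-count the PSF -- e.g. the
# bright RNFL would bleed into the GCL and overturn the small GCL/IPL
# contrast.  The underlying tissue reflectivities are obtained by solving
# the linear band-mixing system implied by the blur kernel and the flat
# base geometry.
.compensate_bands <- function(spec) {
  targets <- c(spec$vitreous_au, spec$band_au, spec$choroid_au)
  if (spec$blur_sigma_voxels <= 0) return(targets)
  nz <- spec$dims[3]
  S <- round(spec$surface_fracs * nz)
  reg <- findInterval(seq_len(nz), S) + 1L       # 1 = vitreous .. 12 = choroid
  M <- matrix(0, 12, 12)
  for (b in 1:12) {
    ind <- matrix(as.numeric(reg == b), 1)
    bl <- .blur_axial(ind, spec$blur_sigma_voxels)[1, ]
    for (b2 in 1:12) M[b2, b] <- mean(bl[reg == b2])
  }
  vals <- tryCatch(solve(M, targets), error = function(e) targets)
  pmin(pmax(vals, 0), 65535)
}

# deterministic (noise-free, pre-blur) voxel matrix (NC x nz)
.phantom_render <- function(spec, truth, center_shift = c(0, 0)) {
  nx <- spec$dims[1]; ny <- spec$dims[2]; nz <- spec$dims[3]
  nc <- nx * ny
  sx <- spec$extent_mm[1] / nx; sy <- spec$extent_mm[2] / ny
  cx <- spec$pit_center_frac[1] * (nx + 1) + center_shift[1]
  cy <- spec$pit_center_frac[2] * (ny + 1) + center_shift[2]
  xmm <- (seq_len(nx) - cx) * sx
  ymm <- (seq_len(ny) - cy) * sy
  r2 <- outer(xmm^2, ymm^2, `+`)
  central <- exp(-r2 / (2 * spec$central_sigma_mm^2))      # nx x ny
  nasal_sign <- if (spec$laterality == "OD") 1 else -1
  u <- matrix(nasal_sign * xmm / (spec$extent_mm[1] / 2), nx, ny)

  # per-band value maps (nc x 10): PSF-compensated base + layer modulation
  base <- .compensate_bands(spec)
  vals <- matrix(0, nc, 12)
  vals[, 1] <- base[1]
  vals[, 12] <- base[12]
  for (b in 1:10) {
    l <- .band_layer[b]
    vals[, b + 1] <- base[b + 1] +
      spec$central_au[l] * as.vector(central) +
      spec$nasal_au[l] * as.vector(u)
  }
  vals <- pmin(pmax(vals, 0), 65535)

  # band label per voxel: number of surfaces at or above each depth
  smat <- vapply(truth$z, as.vector, numeric(nc))          # nc x 11
  lab <- matrix(0L, nc, nz)
  zrow <- matrix(seq_len(nz), nc, nz, byrow = TRUE)
  for (k in 1:11) lab <- lab + (zrow >= smat[, k])
  out <- matrix(vals[cbind(rep(seq_len(nc), nz), as.vector(lab) + 1L)], nc, nz)
  out
}

# axial Gaussian blur on an (nc x nz) matrix, replicate padding
.blur_axial <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  nz <- ncol(m)
  pad <- cbind(m[, rep(1L, half), drop = FALSE], m,
               m[, rep(nz, half), drop = FALSE])
  out <- matrix(0, nrow(m), nz)
  for (j in seq_along(kern))
    out <- out + kern[j] * pad[, j:(j + nz - 1L), drop = FALSE]
  out
}

.run_seeded <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  force(expr)
}

.phantom_noise <- function(spec, det) {
  # multiplicative unit-mean gamma speckle applied to the structural image,
  # then the axial PSF; the expected voxel value is the blurred structure
  if (is.finite(spec$speckle_shape)) {
    sp <- matrix(rgamma(length(det), shape = spec$speckle_shape,
                        rate = spec$speckle_shape),
                 nrow(det), ncol(det))
    noisy <- det * sp
  } else {
    noisy <- det
  }
  noisy <- .blur_axial(noisy, spec$blur_sigma_voxels) + spec$noise_floor
  pmin(pmax(noisy, 0), 65535)
}

#' Generate a synthetic OCT volume with ground-truth surfaces
#'
#' Renders the phantom described by `spec` and returns both the simulated
#' volume and the exact discretised surfaces used to build it.  Identical
#' `spec` and `seed` give bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed (mandatory; generation is deterministic).
#' @return list with elements `volume` (an [oct_volume]) and
#'   `truth` (a [surface_set]).
#' @export
generate_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (missing(seed)) stop("a seed is required for phantom generation")
  truth <- .phantom_truth(spec)
  det <- .phantom_render(spec, truth)
  noisy <- .run_seeded(seed, .phantom_noise(spec, det))
  vol <- oct_volume(array(noisy, spec$dims),
                    spacing = spec$extent_mm / spec$dims[1:2],
                    laterality = spec$laterality, imageQ = spec$imageQ)
  list(volume = vol, truth = truth)
}

#' Expected (noise-free) phantom volume
#'
#' The deterministic part of the phantom: rendered bands convolved with the
#' axial PSF plus the noise floor.  This is the voxel-wise expectation of
#' [generate_phantom()] output (up to 16-bit clamping in the far tails),
#' which makes the mean-preservation of the speckle model testable.
#'
#' @inheritParams generate_phantom
#' @return an [oct_volume] with the expected intensities.
#' @export
phantom_expectation <- function(spec) {
  truth <- .phantom_truth(spec)
  det <- .blur_axial(.phantom_render(spec, truth), spec$blur_sigma_voxels) +
    spec$noise_floor
  oct_volume(array(pmin(pmax(det, 0), 65535), spec$dims),
             spacing = spec$extent_mm / spec$dims[1:2],
             laterality = spec$laterality, imageQ = spec$imageQ)
}

#' Rescan variability model
#'
#' Parameters of the operator-rescan model used by
#' [generate_rescan_pair()]: a between-scan multiplicative intensity gain
#' drawn once per scan from `Normal(1, gain_sd)`, a lateral re-centering
#' shift (whole columns / B-scans), and fresh speckle.
#'
#' @param gain_sd standard deviation of the per-scan gain.
#' @param shift_cols,shift_bscans lateral shift of the second acquisition.
#' @export
rescan_jitter <- function(gain_sd = 0.03, shift_cols = 0L, shift_bscans = 0L) {
  stopifnot(gain_sd >= 0)
  list(gain_sd = gain_sd, shift_cols = as.integer(shift_cols),
       shift_bscans = as.integer(shift_bscans))
}

#' Generate an operator re-scan pair of the same anatomy
#'
#' Two volumes of the same phantom anatomy differing only by the rescan
#' model: independent speckle realisations, per-scan intensity gains and a
#' lateral re-centering shift of the second scan.  With zero jitter the two
#' scans differ only in their speckle realisation.
#'
#' @param spec a [phantom_spec()].
#' @param jitter a [rescan_jitter()] list.
#' @param seed integer RNG seed.
#' @return list `a`, `b` (both [oct_volume]) and `truth_a`, `truth_b`
#'   (ground-truth [surface_set]s; `truth_b` reflects the lateral shift).
#' @export
generate_rescan_pair <- function(spec, jitter = rescan_jitter(), seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (missing(seed)) stop("a seed is required")
  shift <- c(jitter$shift_cols, jitter$shift_bscans)
  truth_a <- .phantom_truth(spec)
  truth_b <- .phantom_truth(spec, center_shift = shift)
  det_a <- .phantom_render(spec, truth_a)
  det_b <- .phantom_render(spec, truth_b, center_shift = shift)
  res <- .run_seeded(seed, {
    ga <- if (jitter$gain_sd > 0) rnorm(1, 1, jitter$gain_sd) else 1
    gb <- if (jitter$gain_sd > 0) rnorm(1, 1, jitter$gain_sd) else 1
    na <- .phantom_noise(spec, det_a * ga)
    nb <- .phantom_noise(spec, det_b * gb)
    list(na = na, nb = nb)
  })
  sp <- spec$extent_mm / spec$dims[1:2]
  list(a = oct_volume(array(res$na, spec$dims), sp, spec$laterality,
                      imageQ = spec$imageQ, operator = "A"),
       b = oct_volume(array(res$nb, spec$dims), sp, spec$laterality,
                      imageQ = spec$imageQ, operator = "B"),
       truth_a = truth_a, truth_b = truth_b)
}
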