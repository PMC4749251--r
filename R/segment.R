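# Sequential 11-surface segmentation.
#
# Each surface is an exact optimal-surface problem (minimum closed set /
# min-cut) over a cost volume encoding the axial gradient with a
# surface-specific polarity.  The ILM (S1) and the outer RPE boundary (S11)
# are found first over wide depth ranges because they carry the strongest
# vitreoretinal and RPE/choroid transitions; the interior surfaces are then
# localised within the bands bounded by already-found neighbours minus the
# configured minimum separations, in an order that leaves each search band
# with a single dominant gradient transition of the requested polarity.
# The GCL/IPL interface (S3) has nearly no intensity contrast in normal
# eyes, so it additionally uses an anatomical relative-position prior
# (GCL and IPL are of comparable thickness at the macula).

#' Segmentation configuration
#'
#' @param dx,dy hard smoothness bounds (voxels) between neighbouring
#'   A-scans along x and across B-scans.  B-scan spacing is much coarser
#'   than A-scan spacing, hence the larger default along y; both defaults
#'   are chosen to admit the foveal pit slope expressed in voxel units at
#'   the anisotropic macular raster sampling.
#' @param min_sep minimum separations (voxels) for consecutive surface
#'   pairs S1S2 .. S10S11.
#' @param cad parameters passed to [denoise_cad()] before cost computation.
#' @param cost_smooth_z,cost_smooth_x,cost_smooth_y triangular smoothing
#'   half-widths applied to the cost along depth, columns and B-scans.
#'   Lateral aggregation is the main speckle defence: boundaries are
#'   laterally smooth while speckle decorrelates between A-scans.
#' @param s3_band_margin half-width (voxels) of the hard search band for S3
#'   around the GCL/IPL midpoint prior.  The GCL/IPL interface carries
#'   almost no intensity contrast in normal eyes, so S3 is positioned by an
#'   equal-thickness anatomical prior refined by the weak gradient.
#' @param s3_prior_weight,s3_prior_scale soft quadratic prior for S3.
#' @param pool_z depth pooling factor of the coarse detection pass.
#' @param refine_radius,refine_dx,refine_dy,refine_smooth_x,refine_smooth_y
#'   flattening refinement parameters (voxels): the cost is re-sampled in a
#'   band of half-width `refine_radius` around the current surface (which
#'   removes the anatomical slope), smoothed laterally with half-widths
#'   `refine_smooth_x`/`refine_smooth_y`, and re-solved with residual
#'   smoothness bounds `refine_dx`/`refine_dy`.  Flattening lets lateral
#'   aggregation suppress speckle without displacing sloped boundaries such
#'   as the foveal pit walls.
#' @param polarity character vector of 11 polarities, names S1..S11.
#' @export
segment_config <- function(dx = 3L, dy = 12L,
                           min_sep = c(4L, 4L, 4L, 4L, 3L, 3L, 3L, 3L, 1L, 4L),
                           cad = list(conductance = 2.0, iterations = 5L,
                                      time_step = 0.0625),
                           cost_smooth_z = 2L,
                           cost_smooth_x = 2L,
                           cost_smooth_y = 1L,
                           s3_band_margin = 1L,
                           s3_prior_weight = 0.1,
                           s3_prior_scale = 3,
                           pool_z = 2L,
                           refine_radius = 5L,
                           refine_dx = 2L, refine_dy = 2L,
                           refine_smooth_x = 8L, refine_smooth_y = 5L,
                           polarity = c(S1 = "dark_to_bright",
                                        S2 = "bright_to_dark",
                                        S3 = "dark_to_bright",
                                        S4 = "bright_to_dark",
                                        S5 = "dark_to_bright",
                                        S6 = "bright_to_dark",
                                        S7 = "dark_to_bright",
                                        S8 = "bright_to_dark",
                                        S9 = "dark_to_bright",
                                        S10 = "dark_to_bright",
                                        S11 = "bright_to_dark")) {
  stopifnot(length(min_sep) == 10, all(min_sep >= 0), length(polarity) == 11)
  list(dx = as.integer(dx), dy = as.integer(dy),
       min_sep = as.integer(min_sep), cad = cad,
       cost_smooth_z = cost_smooth_z,
       cost_smooth_x = cost_smooth_x,
       cost_smooth_y = cost_smooth_y,
       s3_band_margin = as.integer(s3_band_margin),
       s3_prior_weight = s3_prior_weight, s3_prior_scale = s3_prior_scale,
       pool_z = as.integer(pool_z),
       refine_radius = as.integer(refine_radius),
       refine_dx = as.integer(refine_dx), refine_dy = as.integer(refine_dy),
       refine_smooth_x = as.integer(refine_smooth_x),
       refine_smooth_y = as.integer(refine_smooth_y),
       polarity = polarity)
}

#' Segment the 11 intraretinal surfaces of a macular volume
#'
#' Runs denoising, builds gradient cost volumes of both polarities, and
#' detects the 11 surfaces sequentially by exact optimal-surface search.
#' The returned set satisfies the ordering and minimum-separation
#' invariants, or an error identifies the surface whose search band became
#' empty (a segmentation failure, e.g. on structureless input).
#'
#' @param vol raw [oct_volume].
#' @param config a [segment_config()].
#' @param denoised optionally, a pre-computed denoised volume (to avoid
#'   re-running the diffusion filter).
#' @return a [surface_set].
#' @export
segment_retina <- function(vol, config = segment_config(), denoised = NULL) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$voxels)
  nz <- d[3]
  if (is.null(denoised)) {
    denoised <- denoise_cad(vol, conductance = config$cad$conductance,
                            iterations = config$cad$iterations,
                            time_step = config$cad$time_step)
  }
  # smoothed costs for broad searches; axially unsmoothed ("lat") for the
  # thin outer-retinal bands where axial smoothing would bleed neighbouring
  # edges into the search band; plain (unaggregated) for the snap step
  mk_cost <- function(pol, z, x, y)
    compute_surface_cost(denoised, pol, smooth_z = z, smooth_x = x, smooth_y = y)
  cost_sm <- list(
    dark_to_bright = mk_cost("dark_to_bright", config$cost_smooth_z,
                             config$cost_smooth_x, config$cost_smooth_y),
    bright_to_dark = mk_cost("bright_to_dark", config$cost_smooth_z,
                             config$cost_smooth_x, config$cost_smooth_y))
  plain <- list(
    dark_to_bright = mk_cost("dark_to_bright", 0, 0, 0),
    bright_to_dark = mk_cost("bright_to_dark", 0, 0, 0))
  # noise scale of the cost volumes (median absolute depth difference at
  # lag 2, the snap move range): exactly zero on noise-free input, of the
  # order of the speckle-induced fluctuation otherwise
  theta <- lapply(plain, function(p) {
    dd <- p$arr[, , -(1:2), drop = FALSE] - p$arr[, , -c(nz - 1L, nz), drop = FALSE]
    4 * median(abs(dd)) + 1e-9
  })
  # The per-column snap recovers the discretisation phase of sloped
  # boundaries, which matters when the cost is effectively noise-free; on
  # speckled data the laterally aggregated estimate is already the best
  # available and per-column snapping would only reintroduce noise.
  snap_ok <- lapply(theta, function(t) t < 1e-3)

  ms <- config$min_sep
  span <- function(i, j) if (j <= i) 0L else sum(ms[i:(j - 1L)])
  S <- vector("list", 11)
  zm <- function(v) matrix(as.integer(v), d[1], d[2])
  fail <- function(k, e)
    stop(sprintf("segmentation failure at surface S%d: %s", k,
                 conditionMessage(e)), call. = FALSE)

  # per-A-scan search bands from the nearest already-detected surfaces,
  # shrunk by the cumulative minimum separations
  bands_for <- function(k) {
    lo <- zm(1L); hi <- zm(nz)
    below <- which(!vapply(S, is.null, TRUE) & seq_len(11) < k)
    above <- which(!vapply(S, is.null, TRUE) & seq_len(11) > k)
    if (length(below)) { j <- max(below); lo <- S[[j]] + span(j, k) }
    if (length(above)) { j <- min(above); hi <- S[[j]] - span(k, j) }
    list(lo = lo, hi = hi)
  }

  # ---- coarse pass on a depth-pooled cost volume (fast, heavily averaged)
  f <- config$pool_z
  nzp <- nz %/% f
  pool_arr <- function(p) {
    out <- array(0, c(d[1], d[2], nzp))
    for (j in seq_len(f)) out <- out + p$arr[, , (seq_len(nzp) - 1L) * f + j] / f
    out
  }
  pooled <- lapply(cost_sm, pool_arr)
  solve_coarse <- function(k) {
    b <- bands_for(k)
    plo <- pmax((pmax(b$lo, 1L) - 1L) %/% f + 1L, 1L)
    phi <- pmin((pmin(b$hi, nz) - 1L) %/% f + 1L, nzp)
    if (any(plo > phi))
      stop(sprintf("segmentation failure at surface S%d: empty search band", k))
    s <- tryCatch(
      find_optimal_surface(pooled[[config$polarity[k]]],
                           dx = max(1L, ceiling(config$dx / f)),
                           dy = max(1L, ceiling(config$dy / f)),
                           zmin = plo, zmax = phi),
      error = function(e) fail(k, e))
    z <- (s$z - 1L) * f + (f + 1L) %/% 2L
    pmin(pmax(z, b$lo), b$hi)
  }

  refine_surface <- function(k, r, zs, n_stage1 = 2L,
                             sx = config$refine_smooth_x,
                             sy = config$refine_smooth_y) {
    b <- bands_for(k)
    pc <- plain[[config$polarity[k]]]$arr
    # flattened band with aggressive lateral aggregation: removes the
    # slope-induced displacement of coarser passes while suppressing speckle
    if (r == 0L) n_stage1 <- 0L
    for (i in seq_len(n_stage1)) {
      S[[k]] <<- .flatten_refine(pc, S[[k]], r = r, zs = zs,
                                 sx = sx, sy = sy,
                                 dxr = config$refine_dx,
                                 dyr = config$refine_dy, nz = nz,
                                 zlo = b$lo, zhi = b$hi)
    }
    # per-column snap to a decisively better plain cost within +-3 voxels:
    # recovers the per-A-scan discretisation phase on sloped boundaries
    # (lateral aggregation locks to the majority rounding)
    if (snap_ok[[config$polarity[k]]])
      S[[k]] <<- .snap_refine(pc, S[[k]], theta[[config$polarity[k]]],
                              nz = nz, zlo = b$lo, zhi = b$hi)
  }

  # strong, globally unambiguous surfaces: vitreoretinal interface, outer
  # RPE boundary, external limiting membrane
  for (k in c(1L, 11L, 7L)) {
    S[[k]] <- solve_coarse(k)
    refine_surface(k, r = config$refine_radius, zs = 1L)
  }

  # interior surfaces: initialise at the depth offset (relative to an
  # already-found reference surface) that minimises the column-averaged
  # cost -- the mean-A-scan-profile initialisation -- then refine locally.
  # This keeps weak-contrast boundaries out of the attraction basins of
  # stronger edges elsewhere in their corridor.
  place_offset <- function(k, ref, r, zs, ...) {
    b <- bands_for(k)
    pc <- plain[[config$polarity[k]]]$arr
    S[[k]] <<- tryCatch(.offset_init(pc, S[[ref]], b$lo, b$hi, nz),
                        error = function(e) fail(k, e))
    refine_surface(k, r = r, zs = zs, ...)
  }
  place_offset(2L, 1L, r = 6L, zs = 1L)   # RNFL/GCL: strongest inner edge
  place_offset(6L, 7L, r = 6L, zs = 1L)   # OPL/ONL, nearest edge above ELM
  place_offset(4L, 2L, r = 6L, zs = 1L)   # IPL/INL within [S2, S6]
  # INL/OPL is the weakest-contrast gradient surface: extra-wide aggregation
  place_offset(5L, 4L, r = 5L, zs = 1L, sx = 12L, sy = 6L)

  # ---- S3 (GCL/IPL): anatomical midpoint prior, weak-gradient refinement
  mid <- round((S[[2]] + S[[4]]) / 2)
  # the narrow corridor around the midpoint prior already constrains S3;
  # the smoothness bounds are relaxed so that per-column detail in the
  # (refined, snapped) neighbouring surfaces cannot make the corridor
  # infeasible under constraint propagation
  s3 <- tryCatch(
    find_optimal_surface(cost_sm[[config$polarity[3L]]],
                         dx = config$dx + 2L * config$s3_band_margin + 4L,
                         dy = config$dy + 2L * config$s3_band_margin + 4L,
                         zmin = pmax(S[[2]] + span(2L, 3L),
                                     mid - config$s3_band_margin),
                         zmax = pmin(S[[4]] - span(3L, 4L),
                                     mid + config$s3_band_margin),
                         prior = mid, prior_weight = config$s3_prior_weight,
                         prior_scale = config$s3_prior_scale),
    error = function(e) fail(3L, e))
  S[[3]] <- s3$z
  if (snap_ok[[config$polarity[3L]]]) {
    b3 <- list(lo = pmax(S[[2]] + span(2L, 3L), mid - config$s3_band_margin),
               hi = pmin(S[[4]] - span(3L, 4L), mid + config$s3_band_margin))
    S[[3]] <- .snap_refine(plain[[config$polarity[3L]]]$arr, S[[3]],
                           theta[[config$polarity[3L]]],
                           nz = nz, zlo = b3$lo, zhi = b3$hi)
  }

  # ---- outer retina: thin bands, axially unsmoothed cost in refinement.
  # S10's gradient merges with the stronger outer-segment transition under
  # the axial PSF, so its offset initialisation (relative to S9) carries
  # most of the localisation and the refinement stays within one voxel.
  place_offset(8L, 7L, r = 3L, zs = 0L)
  place_offset(9L, 8L, r = 3L, zs = 0L, sx = 12L, sy = 6L)
  # S10 (inner RPE boundary): under the axial PSF its transition merges
  # with the stronger outer-segment edge two voxels above, leaving no
  # separate minimum in the averaged cost profile.  The offset from S9 is
  # therefore recovered by decomposing the averaged profile into two
  # blurred edge components (Gaussian mixture over a small grid of offsets
  # and widths); S10 then inherits S9's per-column accuracy.
  {
    b10 <- bands_for(10L)
    pc10 <- plain[[config$polarity[10L]]]$arr
    cm10 <- matrix(pc10, d[1] * d[2], nz)
    dmax <- min(8L, max(as.vector(b10$hi - S[[9]])))
    if (dmax < 1L)
      stop("segmentation failure at surface S10: empty search band")
    prof <- vapply(-3:dmax, function(dd) {
      z <- pmin(pmax(as.vector(S[[9]]) + dd, 1L), nz)
      mean(cm10[cbind(seq_along(z), z)])
    }, 0)
    # calibrate the effective axial blur width on the isolated, strong
    # outer RPE edge (S11), then fit only the offset of the second edge
    cm11 <- matrix(plain[[config$polarity[11L]]]$arr, d[1] * d[2], nz)
    prof11 <- vapply(-3:3, function(dd) {
      z <- pmin(pmax(as.vector(S[[11]]) + dd, 1L), nz)
      mean(cm11[cbind(seq_along(z), z)])
    }, 0)
    sg11 <- .fit_edge_sigma(prof11)
    m10 <- .fit_double_edge(prof, sg11)
    S[[10]] <- pmin(pmax(S[[9]] + m10, b10$lo), b10$hi)
    if (snap_ok[[config$polarity[10L]]])
      S[[10]] <- .snap_refine(pc10, S[[10]], theta[[config$polarity[10L]]],
                              nz = nz, zlo = b10$lo, zhi = b10$hi)
  }

  # final sweep now that every search band is bounded by both neighbours:
  # repairs surfaces whose first placement used a one-sided or preliminary
  # band (detection-order cascades)
  for (k in c(5L, 4L, 6L, 2L, 8L, 9L)) {
    wide <- k %in% c(5L, 9L)
    refine_surface(k, r = 3L, zs = if (k %in% 8:9) 0L else 1L, n_stage1 = 1L,
                   sx = if (wide) 12L else config$refine_smooth_x,
                   sy = if (wide) 6L else config$refine_smooth_y)
  }

  # restore ordering / separation invariants band-by-band
  S[[1]] <- pmin(pmax(S[[1]], 1L), nz - sum(ms))
  for (k in 2:11)
    S[[k]] <- pmin(pmax(S[[k]], S[[k - 1]] + ms[k - 1]),
                   nz - if (k < 11) sum(ms[k:10]) else 0L)

  surface_set(S, min_separation = ms)
}

# initialise a surface at the constant depth offset from a reference
# surface minimising the column-averaged cost (mean-A-scan-profile
# initialisation); offsets leaving fewer than half of the A-scans inside
# their per-column bands are not considered
.offset_init <- function(cost_arr, ref, blo, bhi, nz) {
  d <- dim(ref)
  nc <- length(ref)
  cm <- matrix(cost_arr, nc, nz)
  refv <- as.vector(ref); lov <- as.vector(blo); hiv <- as.vector(bhi)
  dlo <- min(lov - refv); dhi <- max(hiv - refv)
  ds <- (dlo - 1L):(dhi + 1L)    # one extra on each side for local minima
  prof <- vapply(ds, function(dd) {
    z <- refv + dd
    ok <- z >= 1L & z <= nz
    if (!any(ok)) return(NA_real_)
    mean(cm[cbind(which(ok), z[ok])])
  }, 0)
  feas <- vapply(ds, function(dd) {
    z <- refv + dd
    sum(z >= lov & z <= hiv & z >= 1L & z <= nz) >= nc / 2
  }, TRUE)
  idx <- which(feas)
  if (!length(idx))
    stop("empty search band (no feasible depth offset)")
  # prefer interior local minima of the averaged profile: the flank of a
  # neighbouring surface's (possibly stronger) transition is never a local
  # minimum, so the initialisation cannot slide onto it
  n_ds <- length(ds)
  locmin <- idx[vapply(idx, function(i) {
    i > 1L && i < n_ds && !is.na(prof[i]) &&
      !is.na(prof[i - 1]) && !is.na(prof[i + 1]) &&
      prof[i] <= prof[i - 1] && prof[i] <= prof[i + 1]
  }, TRUE)]
  cand <- if (length(locmin)) locmin else idx[!is.na(prof[idx])]
  if (!length(cand))
    stop("empty search band (no feasible depth offset)")
  best_d <- ds[cand[which.min(prof[cand])]]
  matrix(pmin(pmax(refv + best_d, lov), hiv), d[1], d[2])
}

# re-sample a cost volume in a band around an initial surface (flattening),
# smooth laterally, and re-solve; returns the refined height map.
# zlo/zhi are absolute per-column depth bounds (e.g. from neighbouring
# surfaces); depths outside them are penalised so the refinement cannot be
# captured by a stronger edge across the band limit.
.flatten_refine <- function(cost_arr, z0, r, zs, sx, sy, dxr, dyr, nz,
                            zlo = NULL, zhi = NULL) {
  d <- dim(cost_arr)
  nc <- d[1] * d[2]
  cm <- matrix(cost_arr, nc, nz)
  z0v <- as.vector(z0)
  Fb <- array(0, c(d[1], d[2], 2L * r + 1L))
  pen <- array(0, c(d[1], d[2], 2L * r + 1L))
  for (j in seq_len(2L * r + 1L)) {
    zj <- z0v + j - r - 1L
    idx <- pmin(pmax(zj, 1L), nz)
    Fb[, , j] <- matrix(cm[cbind(seq_len(nc), idx)], d[1], d[2])
    out <- zj < 1L | zj > nz
    if (!is.null(zlo)) out <- out | zj < as.vector(zlo)
    if (!is.null(zhi)) out <- out | zj > as.vector(zhi)
    pen[, , j] <- matrix(2 * out, d[1], d[2])
  }
  if (zs > 0) Fb <- .tri_smooth(Fb, zs, 3L)
  if (sx > 0) Fb <- .tri_smooth(Fb, sx, 1L)
  if (sy > 0 && d[2] > 1) Fb <- .tri_smooth(Fb, sy, 2L)
  s <- find_optimal_surface(Fb + pen, dxr, dyr)
  zr <- z0 + s$z - (r + 1L)
  pmin(pmax(zr, 1L), nz)
}

# effective blur width of an isolated averaged cost dip (profile sampled
# at d = -3..3 around the edge), by least squares over sub-voxel centre and
# width grids
.fit_edge_sigma <- function(prof) {
  dd <- seq_along(prof) - 4L
  depth <- max(prof) - prof
  best <- list(rss = Inf, s = 1)
  for (del in seq(-0.5, 0.5, by = 0.25)) {
    for (sg in seq(0.3, 3, by = 0.1)) {
      x <- exp(-(dd - del)^2 / (2 * sg^2))
      a <- sum(x * depth) / sum(x * x)
      rss <- sum((depth - a * x)^2)
      if (rss < best$rss) best <- list(rss = rss, s = sg)
    }
  }
  best$s
}

# decompose an averaged cost-dip profile (sampled from 3 voxels above the
# known first edge, which sits at offset 0) into two blurred edge
# components of known width and return the integer offset of the second;
# sub-voxel centres on a grid, amplitudes by non-negative linear least
# squares
.fit_double_edge <- function(prof, sigma) {
  dd <- seq_along(prof) - 4L
  depth <- max(prof) - prof
  dmax <- max(dd)
  if (dmax < 2L) return(max(1L, dmax))
  best <- list(rss = Inf, m = which.min(prof[dd >= 1]))
  for (d1 in seq(-0.5, 0.5, by = 0.25)) {
    for (c2 in seq(1, dmax - 1, by = 0.25)) {
      X <- cbind(exp(-(dd - d1)^2 / (2 * sigma^2)),
                 exp(-(dd - c2)^2 / (2 * sigma^2)))
      cf <- tryCatch(qr.solve(X, depth), error = function(e) NULL)
      if (is.null(cf) || any(cf < 0)) next
      rss <- sum((depth - X %*% cf)^2)
      if (rss < best$rss) best <- list(rss = rss, m = round(c2))
    }
  }
  as.integer(max(1L, best$m))
}

# per-column snap: move a surface by up to 3 voxels where the unaggregated
# cost is lower by more than the gate theta; ties prefer the smaller move
.snap_refine <- function(cost_arr, z0, theta, nz, zlo, zhi) {
  d <- dim(z0)
  nc <- length(z0)
  cm <- matrix(cost_arr, nc, nz)
  z0v <- as.vector(z0)
  lo <- as.vector(zlo); hi <- as.vector(zhi)
  deltas <- c(0L, -1L, 1L, -2L, 2L, -3L, 3L)
  v <- matrix(Inf, nc, length(deltas))
  for (j in seq_along(deltas)) {
    zj <- z0v + deltas[j]
    ok <- zj >= pmax(lo, 1L) & zj <= pmin(hi, nz)
    v[ok, j] <- cm[cbind(which(ok), zj[ok])]
    if (deltas[j] != 0L) v[, j] <- v[, j] + theta
  }
  v[!is.finite(v[, 1L]), 1L] <- 2    # centre outside band: allow any move
  pick <- max.col(-v, ties.method = "first")
  matrix(pmin(pmax(z0v + deltas[pick], 1L), nz), d[1], d[2])
}

#' Automated segmentation quality control
#'
#' A proxy for the visual per-B-scan inspection used in clinical reading:
#' flags B-scans whose layer thicknesses are implausible (outside the
#' configured per-layer range) or whose surfaces jump too far between
#' adjacent B-scans.  Volumes with any flagged B-scan are meant to be
#' excluded from cohort statistics.
#'
#' @param surfaces a [surface_set].
#' @param thresholds list with `min_thickness` and `max_thickness` (voxels,
#'   scalars or per-layer length-8 vectors) and `max_jump` (voxels, maximum
#'   allowed |z(x, y+1) - z(x, y)| for any surface).
#' @return list with `pass` (logical), `flags` (data.frame of B-scan index
#'   and reason) and `n_flagged`.
#' @export
qc_surfaces <- function(surfaces,
                        thresholds = list(min_thickness = 1,
                                          max_thickness = 80,
                                          max_jump = 15)) {
  stopifnot(inherits(surfaces, "surface_set"))
  d <- surfaces$dims
  mn <- rep(thresholds$min_thickness, length.out = 8)
  mx <- rep(thresholds$max_thickness, length.out = 8)
  flags <- list()
  for (l in seq_along(.layers)) {
    b <- .layer_surfaces[[l]]
    th <- surfaces$z[[b[2]]] - surfaces$z[[b[1]]]
    bad <- apply(th < mn[l] | th > mx[l], 2, any)
    for (y in which(bad))
      flags[[length(flags) + 1]] <- data.frame(
        bscan = y, reason = sprintf("%s thickness outside [%g, %g]",
                                    .layers[l], mn[l], mx[l]))
  }
  if (d[2] > 1) {
    for (i in 1:11) {
      jump <- abs(surfaces$z[[i]][, -1, drop = FALSE] -
                    surfaces$z[[i]][, -d[2], drop = FALSE])
      bad <- apply(jump > thresholds$max_jump, 2, any)
      for (y in which(bad))
        flags[[length(flags) + 1]] <- data.frame(
          bscan = y + 1L, reason = sprintf("S%d jump > %g voxels between B-scans",
                                           i, thresholds$max_jump))
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(bscan = integer(), reason = character())
  flags <- flags[order(flags$bscan), , drop = FALSE]
  list(pass = nrow(flags) == 0L, flags = flags,
       n_flagged = length(unique(flags$bscan)))
}
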