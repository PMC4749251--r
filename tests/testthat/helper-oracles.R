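# Independent oracles used across the suite.

# exhaustive minimum-cost surface search by recursive enumeration with
# branch-and-bound pruning; cm is (n_columns x n_depths) in raster order
# (x fastest), bounds dx within a B-scan and dy across B-scans
brute_force_surface <- function(cm, nx, ny, dx, dy) {
  nz <- ncol(cm)
  nc <- nx * ny
  best <- Inf
  zcur <- integer(nc)
  rec <- function(ci, acc) {
    if (acc >= best) return(invisible())
    if (ci > nc) { best <<- acc; return(invisible()) }
    x <- (ci - 1L) %% nx + 1L
    y <- (ci - 1L) %/% nx + 1L
    for (z in seq_len(nz)) {
      if (x > 1L && abs(z - zcur[ci - 1L]) > dx) next
      if (y > 1L && abs(z - zcur[ci - nx]) > dy) next
      zcur[ci] <<- z
      rec(ci + 1L, acc + cm[ci, z])
    }
  }
  rec(1L, 0)
  best
}

# naive triple-loop layer/sector statistics, the reference for
# layer_sector_intensity
naive_intensity <- function(vol, surfaces, grid) {
  d <- dim(vol$voxels)
  layers <- list(RNFL = c(1, 2), GCL = c(2, 3), IPL = c(3, 4), INL = c(4, 5),
                 OPL = c(5, 6), ONL = c(6, 7), PR = c(7, 10), RPE = c(10, 11))
  out <- NULL
  sectors <- c("Cen", "Sin", "Nin", "Iin", "Tin", "Sout", "Nout", "Iout",
               "Tout", "WholeETDRS", "WholeScan")
  for (ln in names(layers)) {
    lo_s <- layers[[ln]][1]; hi_s <- layers[[ln]][2]
    for (sec in sectors) {
      vals <- c()
      for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
        lab <- as.character(grid$label[x, y])
        keep <- switch(sec,
                       WholeScan = TRUE,
                       WholeETDRS = !is.na(lab),
                       !is.na(lab) && lab == sec)
        if (!keep) next
        zlo <- surfaces$z[[lo_s]][x, y]
        zhi <- surfaces$z[[hi_s]][x, y]
        if (zhi > zlo) vals <- c(vals, vol$voxels[x, y, zlo:(zhi - 1)])
      }
      out <- rbind(out, data.frame(
        layer = ln, sector = sec,
        mean_au = if (length(vals)) mean(vals) else NA_real_,
        n_voxels = length(vals), stringsAsFactors = FALSE))
    }
  }
  out
}

# two-way ANOVA mean squares ICC, written independently of the package
oracle_icc <- function(a, b) {
  n <- length(a); k <- 2
  x <- cbind(a, b)
  rm_ <- rowMeans(x); cm_ <- colMeans(x); g <- mean(x)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm_ - g)^2) / (k - 1)
  mse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g)^2) /
    ((n - 1) * (k - 1))
  list(icc2 = (msr - mse) / (msr + mse + k * (msc - mse) / n),
       icc3 = (msr - mse) / (msr + mse))
}

# small phantom used in segmentation tests: same geometry as the default,
# scaled to keep the foveal pit slope within the solver's default bounds
small_spec <- function(...) {
  phantom_spec(dims = c(96L, 32L, 224L), central_au = rep(0, 8),
               nasal_au = rep(0, 8), ...)
}

layer_means_of <- function(tab, sector = "WholeETDRS") {
  sel <- tab[tab$sector == sector, ]
  setNames(sel$mean_au, sel$layer)
}
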