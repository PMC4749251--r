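flat_setup <- function() {
  spec <- phantom_spec(dims = c(32L, 8L, 64L),
                       surface_fracs = c(20, 25, 28, 31, 34, 36, 44, 46, 49, 50, 54) / 64,
                       pit_depth_frac = 0, speckle_shape = Inf,
                       blur_sigma_voxels = 0,
                       central_au = rep(0, 8), nasal_au = rep(0, 8))
  ph <- generate_phantom(spec, seed = 1)
  g <- suppressWarnings(build_etdrs_masks(c(16.5, 4.5), spec$laterality,
                                          c(32, 8), c(6 / 32, 6 / 8)))
  list(spec = spec, ph = ph, g = g)
}

test_that("constant layers give exact sector means", {
  s <- flat_setup()
  tab <- suppressWarnings(layer_sector_intensity(s$ph$volume, s$ph$truth, s$g))
  bands <- s$spec$band_au
  expected <- c(bands[1:6],
                weighted.mean(bands[7:9], diff(round(s$spec$surface_fracs * 64))[7:9]),
                bands[10])
  names(expected) <- c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "PR", "RPE")
  for (l in c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "RPE")) {
    rows <- tab[tab$layer == l & tab$n_voxels > 0, ]
    expect_equal(rows$mean_au, rep(unname(expected[l]), nrow(rows)),
                 tolerance = 1e-12)
    # constant band: SD is zero up to sums-of-squares cancellation at AU scale
    expect_true(all(rows$sd_au[rows$n_voxels > 1] < 0.01))
  }
})

test_that("a two-layer toy volume matches direct summation", {
  arr <- array(100, c(16, 4, 32))
  arr[, , 17:32] <- 200
  v <- oct_volume(arr, spacing = c(6 / 16, 6 / 4), laterality = "OD")
  base <- matrix(2L, 16, 4)
  ss <- surface_set(list(base, base + 4L, base + 6L, base + 8L, base + 10L,
                         base + 12L, base + 15L, base + 20L, base + 24L,
                         base + 26L, base + 29L))
  g <- suppressWarnings(build_etdrs_masks(c(8.5, 2.5), "OD",
                                          c(16, 4), c(6 / 16, 6 / 4)))
  tab <- suppressWarnings(layer_sector_intensity(v, ss, g))
  oracle <- naive_intensity(v, ss, g)
  merged <- merge(tab, oracle, by = c("layer", "sector"),
                  suffixes = c("", "_oracle"))
  expect_equal(merged$n_voxels, merged$n_voxels_oracle)
  ok <- merged$n_voxels > 0
  expect_equal(merged$mean_au[ok], merged$mean_au_oracle[ok], tolerance = 1e-12)
})

test_that("sector statistics agree with the naive triple-loop oracle", {
  set.seed(21)
  arr <- array(sample(0:65535, 24 * 6 * 40, TRUE), c(24, 6, 40))
  v <- oct_volume(arr, spacing = c(6 / 24, 6 / 6), laterality = "OS")
  zb <- matrix(3L, 24, 6)
  ss <- surface_set(lapply(c(0L, 3L, 6L, 9L, 12L, 15L, 18L, 22L, 26L, 28L, 32L),
                           function(o) zb + o))
  g <- suppressWarnings(build_etdrs_masks(c(12.5, 3.5), "OS",
                                          c(24, 6), c(6 / 24, 6 / 6)))
  tab <- suppressWarnings(layer_sector_intensity(v, ss, g))
  oracle <- naive_intensity(v, ss, g)
  merged <- merge(tab, oracle, by = c("layer", "sector"),
                  suffixes = c("", "_oracle"))
  expect_equal(merged$n_voxels, merged$n_voxels_oracle)
  ok <- merged$n_voxels > 0
  expect_equal(merged$mean_au[ok], merged$mean_au_oracle[ok], tolerance = 1e-12)
})

test_that("sector counts and means pool exactly to the whole-chart rows", {
  ph <- generate_phantom(phantom_spec(dims = c(64L, 16L, 128L),
                                      surface_fracs = c(40, 50, 56, 62, 68, 72, 88, 92, 98, 100, 108) / 128),
                         seed = 4)
  g <- suppressWarnings(build_etdrs_masks(c(32.5, 8.5), "OD",
                                          c(64, 16), c(6 / 64, 6 / 16)))
  tab <- suppressWarnings(layer_sector_intensity(ph$volume, ph$truth, g))
  sec9 <- c("Cen", "Sin", "Nin", "Iin", "Tin", "Sout", "Nout", "Iout", "Tout")
  for (l in unique(tab$layer)) {
    s9 <- tab[tab$layer == l & tab$sector %in% sec9, ]
    wc <- tab[tab$layer == l & tab$sector == "WholeETDRS", ]
    expect_equal(sum(s9$n_voxels), wc$n_voxels)
    expect_lt(abs(sum(s9$mean_au * s9$n_voxels) / sum(s9$n_voxels) - wc$mean_au) /
                wc$mean_au, 1e-6)
  }
})

test_that("whole-scan rows do not depend on the chart centre", {
  ph <- generate_phantom(phantom_spec(dims = c(64L, 16L, 128L),
                                      surface_fracs = c(40, 50, 56, 62, 68, 72, 88, 92, 98, 100, 108) / 128),
                         seed = 4)
  g1 <- suppressWarnings(build_etdrs_masks(c(32.5, 8.5), "OD",
                                           c(64, 16), c(6 / 64, 6 / 16)))
  g2 <- suppressWarnings(build_etdrs_masks(c(20, 5), "OD",
                                           c(64, 16), c(6 / 64, 6 / 16)))
  t1 <- suppressWarnings(layer_sector_intensity(ph$volume, ph$truth, g1))
  t2 <- suppressWarnings(layer_sector_intensity(ph$volume, ph$truth, g2))
  w1 <- t1[t1$sector == "WholeScan", c("layer", "mean_au", "n_voxels")]
  w2 <- t2[t2$sector == "WholeScan", c("layer", "mean_au", "n_voxels")]
  expect_equal(w1, w2)
})

test_that("empty layer-sector combinations get zero counts and NA means", {
  s <- flat_setup()
  # chart centred near the border: whole quadrants fall outside
  g <- suppressWarnings(build_etdrs_masks(c(3, 4.5), "OD",
                                          c(32, 8), c(6 / 32, 6 / 8)))
  expect_warning(tab <- layer_sector_intensity(s$ph$volume, s$ph$truth, g),
                 "no voxels")
  empty <- tab[tab$n_voxels == 0, ]
  expect_gt(nrow(empty), 0)
  expect_true(all(is.na(empty$mean_au)))
})

test_that("per-volume layer means collect into cohort intensity rows", {
  s <- flat_setup()
  tab <- suppressWarnings(layer_sector_intensity(s$ph$volume, s$ph$truth, s$g))
  ci <- cohort_intensity(list(A = tab, B = tab))
  expect_equal(nrow(ci), 2)
  expect_identical(ci$subject_id, c("A", "B"))
  expect_equal(ci$RNFL[1], tab$mean_au[tab$layer == "RNFL" & tab$sector == "WholeETDRS"])
})
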