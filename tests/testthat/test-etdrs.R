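test_that("the fovea is found at the deepest point of the ILM", {
  # centred pit, noise-free ground truth
  spec <- phantom_spec(speckle_shape = Inf, blur_sigma_voxels = 0)
  tr <- generate_phantom(spec, seed = 1)$truth
  ctr <- locate_fovea(tr$z[[1]])
  expect_equal(unname(ctr), c(64.5, 16.5), tolerance = 1e-9)
  # offset pit recovered exactly
  spec2 <- phantom_spec(speckle_shape = Inf, blur_sigma_voxels = 0,
                        pit_center_frac = c(0.5 + 10 / 129, 0.5 + 3 / 33))
  tr2 <- generate_phantom(spec2, seed = 1)$truth
  ctr2 <- locate_fovea(tr2$z[[1]])
  expect_equal(unname(ctr2 - ctr), c(10, 3), tolerance = 0.51)
})

test_that("a flat ILM is rejected as ambiguous", {
  expect_error(locate_fovea(matrix(40L, 64, 16)), "ambiguous")
})

test_that("fovea localisation stays within tolerance under speckle", {
  # S1 alone suffices for the fovea; detect it directly on each phantom
  errs <- t(vapply(1:5, function(s) {
    ph <- generate_phantom(small_spec(), seed = 400 + s)
    den <- denoise_cad(ph$volume)
    cd <- compute_surface_cost(den, "dark_to_bright", smooth_z = 2,
                               smooth_x = 2, smooth_y = 1)
    s1 <- find_optimal_surface(cd, 3, 12)$z
    truth_ctr <- locate_fovea(ph$truth$z[[1]])
    est_ctr <- locate_fovea(s1)
    abs(est_ctr - truth_ctr)
  }, c(x = 0, y = 0)))
  expect_lte(median(errs[, "x"]), 3)
  expect_lte(median(errs[, "y"]), 1)
})

test_that("ETDRS sector areas approach the analytic ring/quadrant areas", {
  g <- suppressWarnings(
    build_etdrs_masks(c(256.5, 64.5), "OD", c(512, 128), c(6 / 512, 6 / 128)))
  a <- etdrs_sector_areas(g)
  expect_lt(abs(a["Cen"] - pi * 0.25) / (pi * 0.25), 0.02)
  for (q in c("Sout", "Nout", "Iout", "Tout"))
    expect_lt(abs(a[q] - 5.3014) / 5.3014, 0.02)
  for (q in c("Sin", "Nin", "Iin", "Tin"))
    expect_lt(abs(a[q] - pi * 2 / 4) / (pi * 2 / 4), 0.02)
})

test_that("sector masks are disjoint and cover exactly the 6-mm disc", {
  g <- suppressWarnings(
    build_etdrs_masks(c(64.5, 16.5), "OD", c(128, 32), c(6 / 128, 6 / 32)))
  lab <- g$label
  r <- sqrt(outer(((1:128) - 64.5) * 6 / 128, rep(1, 32))^2 +
              outer(rep(1, 128), ((1:32) - 16.5) * 6 / 32)^2)
  expect_true(all(!is.na(lab[r <= 3])))
  expect_true(all(is.na(lab[r > 3])))
  # every in-disc pixel belongs to exactly one sector by construction
  expect_equal(sum(table(lab)), sum(r <= 3))
})

test_that("switching laterality swaps the nasal and temporal masks", {
  ctr <- c(64.5, 16.5); dims <- c(128, 32); sp <- c(6 / 128, 6 / 32)
  god <- suppressWarnings(build_etdrs_masks(ctr, "OD", dims, sp))
  gos <- suppressWarnings(build_etdrs_masks(ctr, "OS", dims, sp))
  swap <- c(Cen = "Cen", Sin = "Sin", Nin = "Tin", Iin = "Iin", Tin = "Nin",
            Sout = "Sout", Nout = "Tout", Iout = "Iout", Tout = "Nout")
  od <- as.character(god$label); os <- as.character(gos$label)
  expect_identical(unname(swap[od]), os)
})

test_that("charts clipped by the scan border warn and flag", {
  expect_warning(
    g <- build_etdrs_masks(c(10, 16.5), "OD", c(128, 32), c(6 / 128, 6 / 32)),
    "clipped")
  expect_true(g$clipped)
  expect_error(build_etdrs_masks(c(200, 5), "OD", c(128, 32), c(6 / 128, 6 / 32)),
               "outside")
})
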