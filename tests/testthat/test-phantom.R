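test_that("phantom generation is bit-reproducible under a fixed seed", {
  spec <- phantom_spec(dims = c(32L, 4L, 64L),
                       surface_fracs = c(20, 25, 28, 31, 34, 36, 44, 46, 49, 50, 54) / 64)
  a <- generate_phantom(spec, seed = 7)
  b <- generate_phantom(spec, seed = 7)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$z, b$truth$z)
  c <- generate_phantom(spec, seed = 8)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("a noiseless flat phantom renders exact band constants", {
  spec <- phantom_spec(speckle_shape = Inf, blur_sigma_voxels = 0,
                       pit_depth_frac = 0,
                       central_au = rep(0, 8), nasal_au = rep(0, 8))
  ph <- generate_phantom(spec, seed = 1)
  v <- ph$volume$voxels
  tr <- ph$truth$z
  # layers bounded by consecutive surfaces carry their configured value
  bands <- spec$band_au
  for (b in c(1, 6, 10)) {   # RNFL, ONL, RPE
    zlo <- tr[[b]][1, 1]; zhi <- tr[[b + 1]][1, 1]
    expect_equal(unique(as.vector(v[, , zlo:(zhi - 1)])), unname(bands[b]),
                 tolerance = 1e-12)
  }
  # background above S1 and below S11
  expect_equal(unique(as.vector(v[, , 1:(tr[[1]][1, 1] - 1)])),
               spec$vitreous_au)
})

test_that("speckle is mean-preserving per layer at the 1% level", {
  spec <- phantom_spec(blur_sigma_voxels = 0, central_au = rep(0, 8),
                       nasal_au = rep(0, 8))
  ph <- generate_phantom(spec, seed = 42)
  tr <- ph$truth$z
  d <- dim(ph$volume$voxels)
  for (b in c(1, 6, 10)) {
    # per-column band extraction: surfaces are not planes (foveal pit)
    vox <- unlist(lapply(seq_len(d[2]), function(y) {
      unlist(lapply(seq_len(d[1]), function(x) {
        ph$volume$voxels[x, y, seq.int(tr[[b]][x, y], tr[[b + 1]][x, y] - 1L)]
      }))
    }))
    expect_gt(length(vox), 4e4)
    expect_lt(abs(mean(vox) - spec$band_au[b]) / spec$band_au[b], 0.01)
  }
})

test_that("the voxel-wise expectation matches the blurred structure", {
  spec <- phantom_spec(dims = c(64L, 4L, 128L),
                       surface_fracs = c(40, 50, 56, 62, 68, 72, 88, 92, 98, 100, 108) / 128,
                       central_au = rep(0, 8), nasal_au = rep(0, 8))
  det <- phantom_expectation(spec)
  # Monte-Carlo over independent speckle realisations
  acc <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) acc <- acc + generate_phantom(spec, seed = s)$volume$voxels
  rel <- abs(acc / n_rep - det$voxels) / pmax(det$voxels, 1)
  # layer interiors: MC error ~ CoV/sqrt(40) ~ 3.5% per voxel; check the bulk
  expect_lt(median(rel), 0.05)
  expect_lt(abs(mean(acc / n_rep) - mean(det$voxels)) / mean(det$voxels), 0.005)
})

test_that("ground-truth surfaces are strictly ordered and inside the depth range", {
  for (pit in c(0.1, 0.137, 0.05)) {
    spec <- phantom_spec(dims = c(48L, 8L, 256L), pit_depth_frac = pit,
                         speckle_shape = Inf)
    tr <- generate_phantom(spec, seed = 1)$truth
    for (i in 1:10) expect_true(all(tr$z[[i + 1]] > tr$z[[i]]))
    expect_true(all(tr$z[[1]] >= 1))
    expect_true(all(tr$z[[11]] <= spec$dims[3]))
  }
})

test_that("crossing or touching surfaces are rejected with the offending pair named", {
  expect_error(
    phantom_spec(surface_fracs = c(55, 70, 88, 106, 120, 130, 160, 160.4, 173, 175, 187) / 256),
    "S7 and S8")
  expect_error(phantom_spec(dims = c(4L, 4L, 64L)), "dims")
  expect_error(phantom_spec(surface_fracs = seq(0.9, 1.4, length.out = 11)),
               "inside")
})

test_that("zero-jitter rescan pairs share anatomy and differ only by speckle", {
  spec <- phantom_spec(dims = c(32L, 4L, 64L),
                       surface_fracs = c(20, 25, 28, 31, 34, 36, 44, 46, 49, 50, 54) / 64,
                       speckle_shape = Inf)
  pr <- generate_rescan_pair(spec, rescan_jitter(gain_sd = 0, shift_cols = 0L),
                             seed = 3)
  expect_identical(pr$a$voxels, pr$b$voxels)  # no speckle, no jitter
  spec2 <- phantom_spec(dims = c(32L, 4L, 64L),
                        surface_fracs = c(20, 25, 28, 31, 34, 36, 44, 46, 49, 50, 54) / 64)
  pr2 <- generate_rescan_pair(spec2, rescan_jitter(gain_sd = 0), seed = 3)
  expect_identical(pr2$truth_a$z, pr2$truth_b$z)
  expect_false(identical(pr2$a$voxels, pr2$b$voxels))
})

test_that("a lateral rescan shift moves the ground-truth pit by that shift", {
  spec <- phantom_spec(speckle_shape = Inf, blur_sigma_voxels = 0)
  pr <- generate_rescan_pair(spec, rescan_jitter(shift_cols = 2L, shift_bscans = 1L),
                             seed = 1)
  ca <- locate_fovea(pr$truth_a$z[[1]])
  cb <- locate_fovea(pr$truth_b$z[[1]])
  expect_equal(unname(cb - ca), c(2, 1), tolerance = 1e-9)
})

test_that("cohort generation honours the model and refuses tiny cohorts", {
  expect_error(generate_cohort(cohort_model(), 5, seed = 1), "fewer than 10")
  # degenerate model: zero coefficients, vanishing residual scatter
  m0 <- cohort_model(beta_age = rep(0, 8), beta_q = rep(0, 8),
                     layer_sd = rep(1e-6, 8))
  d0 <- generate_cohort(m0, 20, seed = 2)
  expect_lt(max(abs(d0$RNFL - m0$layer_mean[1])), 1e-3)
  # age moments at the default cohort size
  d <- generate_cohort(cohort_model(), 231, seed = 5)
  expect_equal(nrow(d), 231)
  expect_lt(abs(mean(d$age) - 46.90), 3 * 16.87 / sqrt(231) + 1.5)
  expect_true(all(d$age >= 18 & d$age <= 90))
  expect_false(any(duplicated(d$subject_id)))
})

test_that("the generating model reproduces the negative age-RNFL correlation", {
  neg <- vapply(1:20, function(s) {
    d <- generate_cohort(cohort_model(), 231, seed = 100 + s)
    cor(d$age, d$RNFL) < 0
  }, TRUE)
  expect_true(all(neg))
})
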