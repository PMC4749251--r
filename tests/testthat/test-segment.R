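# Segmentation accuracy at full scale is exercised by the acceptance suite;
# unit tests use a reduced raster with the same relative geometry.

test_that("all 11 surfaces are recovered exactly on a noiseless phantom", {
  ph <- generate_phantom(small_spec(speckle_shape = Inf, blur_sigma_voxels = 0),
                         seed = 1)
  ss <- segment_retina(ph$volume)
  for (i in 1:11) {
    expect_equal(max(abs(ss$z[[i]] - ph$truth$z[[i]])), 0,
                 label = sprintf("surface S%d max error", i))
  }
})

test_that("default-speckle recovery stays within one voxel MAE per surface", {
  ph <- generate_phantom(small_spec(), seed = 2)
  ss <- segment_retina(ph$volume)
  mae <- vapply(1:11, function(i) mean(abs(ss$z[[i]] - ph$truth$z[[i]])), 0)
  expect_true(all(mae <= 1.0), label = paste("MAEs:", paste(round(mae, 2), collapse = " ")))
})

test_that("structureless input never yields a silently crossing surface set", {
  set.seed(8)
  v <- oct_volume(array(runif(32 * 4 * 80, 0, 65535), c(32, 4, 80)),
                  spacing = c(6 / 32, 6 / 4), laterality = "OD")
  res <- tryCatch(segment_retina(v), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "segmentation failure")
  } else {
    expect_s3_class(res, "surface_set")   # constructor enforces ordering
    for (i in 1:10) expect_true(all(res$z[[i + 1]] >= res$z[[i]]))
  }
})

test_that("ground-truth surface sets pass quality control", {
  ph <- generate_phantom(small_spec(speckle_shape = Inf), seed = 1)
  qc <- qc_surfaces(ph$truth)
  expect_true(qc$pass)
  expect_equal(nrow(qc$flags), 0L)
})

test_that("gross boundary errors are flagged by quality control", {
  ph <- generate_phantom(small_spec(speckle_shape = Inf), seed = 1)
  # a layer collapsed to zero thickness over one whole B-scan
  bad1 <- ph$truth$z
  bad1[[2]][, 3] <- bad1[[3]][, 3]
  qc1 <- qc_surfaces(surface_set(bad1))
  expect_false(qc1$pass)
  expect_true(any(qc1$flags$bscan == 3 & grepl("GCL", qc1$flags$reason)))
  # a gross jump between adjacent B-scans
  bad2 <- ph$truth$z
  bad2[[7]][, 5] <- bad2[[7]][, 5] + 25L
  bad2[[8]][, 5] <- pmax(bad2[[8]][, 5], bad2[[7]][, 5] + 1L)
  bad2[[9]][, 5] <- pmax(bad2[[9]][, 5], bad2[[8]][, 5] + 1L)
  bad2[[10]][, 5] <- pmax(bad2[[10]][, 5], bad2[[9]][, 5] + 1L)
  bad2[[11]][, 5] <- pmax(bad2[[11]][, 5], bad2[[10]][, 5] + 1L)
  qc2 <- qc_surfaces(surface_set(bad2))
  expect_false(qc2$pass)
  expect_true(any(grepl("jump", qc2$flags$reason)))
})

test_that("injected gross errors are detected at a high rate", {
  ph <- generate_phantom(small_spec(speckle_shape = Inf), seed = 1)
  set.seed(99)
  detected <- vapply(1:20, function(i) {
    bad <- ph$truth$z
    k <- sample(1:7, 1)
    y <- sample(seq_len(ncol(bad[[1]])), 1)
    shift <- sample(c(-30L, 30L), 1)
    bad[[k]][, y] <- bad[[k]][, y] + shift
    # a displaced boundary drags its neighbours along: repair ordering
    # outward from the shifted surface so the gross error persists
    if (k < 11) for (j in k:10) {
      bad[[j + 1]] <- pmax(bad[[j + 1]], bad[[j]] + 1L)
    }
    if (k > 1) for (j in k:2) {
      bad[[j - 1]] <- pmin(bad[[j - 1]], bad[[j]] - 1L)
    }
    bad <- lapply(bad, function(m) pmin(pmax(m, 1L), dim(ph$volume$voxels)[3]))
    !qc_surfaces(surface_set(bad))$pass
  }, TRUE)
  expect_gte(mean(detected), 0.9)
})
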