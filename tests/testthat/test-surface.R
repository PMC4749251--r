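test_that("the cost minimum sits on the step voxel with matching polarity", {
  nz <- 16
  col <- c(rep(0, 9), rep(100, 7))          # step: first bright voxel at z = 10
  arr <- array(rep(col, each = 8 * 2), c(8, 2, nz))
  for (x in 1:8) for (y in 1:2) arr[x, y, ] <- col
  cd <- compute_surface_cost(arr, "dark_to_bright")
  expect_equal(unname(which.min(cd$arr[1, 1, ])), 10)
  expect_equal(sum(cd$arr[1, 1, ] == min(cd$arr[1, 1, ])), 1)  # unique
  cb <- compute_surface_cost(arr, "bright_to_dark")
  expect_gte(cb$arr[1, 1, 10], 0.5)         # no minimum at the step
  # constant column: flat mid-range cost
  flat <- array(500, c(8, 2, nz))
  cf <- compute_surface_cost(flat, "dark_to_bright")
  expect_true(all(cf$arr == 0.5))
  expect_error(compute_surface_cost(array(1, c(8, 2, 2))), "depth")
})

test_that("a single-column search returns the in-range cost argmin", {
  set.seed(3)
  arr <- array(runif(12), c(1, 1, 12))
  s <- find_optimal_surface(arr, 1, 1)
  expect_equal(s$z[1, 1], which.min(arr[1, 1, ]))
  s2 <- find_optimal_surface(arr, 1, 1, zmin = 4, zmax = 9)
  expect_equal(s2$z[1, 1], 3 + which.min(arr[1, 1, 4:9]))
})

test_that("the min-cut solver matches brute-force enumeration on small instances", {
  set.seed(11)
  for (i in 1:15) {
    arr <- array(sample(0:9, 4 * 2 * 6, TRUE) + runif(48) * 1e-6, c(4, 2, 6))
    for (dd in list(c(1, 1), c(0, 0), c(2, 1))) {
      s <- find_optimal_surface(arr, dd[1], dd[2])
      b <- brute_force_surface(matrix(arr, 8, 6), 4, 2, dd[1], dd[2])
      expect_equal(s$total_cost, b, tolerance = 1e-8)
    }
  }
})

test_that("with zero smoothness bounds the optimum is the best flat surface", {
  set.seed(5)
  arr <- array(runif(6 * 3 * 10), c(6, 3, 10))
  s <- find_optimal_surface(arr, 0, 0)
  expect_equal(length(unique(as.vector(s$z))), 1L)
  cm <- matrix(arr, 18, 10)
  expect_equal(s$total_cost, min(colSums(cm)), tolerance = 1e-10)
  expect_equal(s$z[1, 1], unname(which.min(colSums(cm))))
})

test_that("relaxing the smoothness bound never increases the optimal cost", {
  set.seed(9)
  for (i in 1:6) {
    arr <- array(runif(5 * 3 * 8), c(5, 3, 8))
    costs <- vapply(0:4, function(dd)
      find_optimal_surface(arr, dd, dd)$total_cost, 0)
    expect_true(all(diff(costs) <= 1e-10))
  }
})

test_that("surfaces satisfy their smoothness bounds and stay in range", {
  set.seed(13)
  for (i in 1:5) {
    arr <- array(runif(10 * 4 * 12), c(10, 4, 12))
    dx <- sample(0:2, 1); dy <- sample(0:3, 1)
    s <- find_optimal_surface(arr, dx, dy)
    z <- s$z
    expect_true(all(abs(z[-1, ] - z[-10, ]) <= dx))
    expect_true(all(abs(z[, -1] - z[, -4]) <= dy))
    expect_true(all(z >= 1 & z <= 12))
  }
})

test_that("infeasible constraint sets raise an error rather than a fallback", {
  arr <- array(runif(4 * 1 * 10), c(4, 1, 10))
  zlo <- matrix(c(1L, 1L, 1L, 9L), 4, 1)
  zhi <- matrix(c(2L, 2L, 2L, 10L), 4, 1)
  expect_error(find_optimal_surface(arr, 0, 0, zmin = zlo, zmax = zhi),
               "infeasible")
  expect_error(find_optimal_surface(arr, 1, 1, zmin = 5, zmax = 4), "empty")
  arr[1] <- NA
  expect_error(find_optimal_surface(arr, 1, 1), "finite")
})

test_that("a quadratic depth prior pulls a flat-cost surface to the prior", {
  arr <- array(0.5, c(6, 2, 20))
  pri <- matrix(12L, 6, 2)
  s <- find_optimal_surface(arr, 2, 2, prior = pri, prior_weight = 0.1)
  expect_true(all(s$z == 12))
})
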