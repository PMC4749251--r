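test_that("identical operator columns give ICC of exactly 1", {
  ic <- icc_two_operator(c(3, 7, 2, 9, 4, 6), c(3, 7, 2, 9, 4, 6))
  expect_equal(ic$icc2, 1)
  expect_equal(ic$icc3, 1)
  expect_false(ic$degenerate)
})

test_that("a pure rater offset separates ICC(2,1) from ICC(3,1)", {
  a <- 1:6; b <- 1:6 + 10
  ic <- icc_two_operator(a, b)
  # hand-computable mean squares: MSR = 7, MSC = 300, MSE = 0
  expect_equal(ic$icc3, 1)
  expect_equal(ic$icc2, 7 / 107, tolerance = 1e-12)
  expect_lt(ic$icc2, ic$icc3)
})

test_that("the ICC agrees with the independent mean-squares oracle", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    a <- rnorm(n, 50, 10)
    b <- a + rnorm(n, 2, 3)
    ic <- icc_two_operator(a, b)
    or <- oracle_icc(a, b)
    expect_equal(ic$icc2, or$icc2, tolerance = 1e-10)
    expect_equal(ic$icc3, or$icc3, tolerance = 1e-10)
  }
})

test_that("zero between-subject variance is reported as degenerate", {
  ic <- icc_two_operator(rep(5, 6), rep(8, 6))
  expect_true(ic$degenerate)
  expect_true(is.na(ic$icc2))
  expect_error(icc_two_operator(1:3, 1:3), "at least 5")
  expect_error(icc_two_operator(1:6, 1:5), "equal length")
})

test_that("ICC recovery on simulated rescan pairs matches the variance components", {
  # subjects with true ICC = var_s / (var_s + var_e) = 0.9
  est <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    subj <- rnorm(44, 0, sqrt(0.9))
    icc_two_operator(subj + rnorm(44, 0, sqrt(0.1)),
                     subj + rnorm(44, 0, sqrt(0.1)))$icc2
  }, 0)
  expect_lt(abs(median(est) - 0.9), 0.05)
})

test_that("correlation screens reproduce exact and rank relationships", {
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 1, z = exp(seq(0.1, 2, length.out = 20)))
  sc <- correlation_screen(d, covariates = "x", responses = c("y", "z"))
  expect_equal(unname(sc$r["x", "y"]), 1, tolerance = 1e-12)
  expect_lt(sc$r["x", "z"], 1)
  scs <- correlation_screen(d, covariates = "x", responses = c("y", "z"),
                            method = "spearman")
  expect_equal(unname(scs$r["x", "z"]), 1, tolerance = 1e-12)
  # zero-variance columns are flagged, not crashed on
  d$c0 <- 5
  sc0 <- correlation_screen(d, covariates = "c0", responses = "y")
  expect_true(is.na(sc0$r["c0", "y"]))
  expect_match(attr(sc0, "undefined"), "c0")
})

test_that("group comparisons handle identical and degenerate inputs", {
  g <- rep(c("a", "b"), each = 10)
  x <- rep(1:10, 2)
  ct <- compare_groups(x, g)
  expect_equal(ct$t, 0)
  expect_equal(ct$p, 1)
  # paired, constant non-zero difference: flagged degenerate
  cp <- compare_groups(5:14 + 2, 5:14, mode = "paired")
  expect_true(cp$degenerate)
  expect_true(is.infinite(cp$t))
  cz <- compare_groups(5:14, 5:14, mode = "paired")
  expect_equal(cz$t, 0)
  expect_equal(cz$p, 1)
  expect_error(compare_groups(x, rep("a", 20)), "two groups")
})

test_that("shifted groups are detected with the expected power", {
  hits <- vapply(1:30, function(s) {
    set.seed(500 + s)
    compare_groups(c(rnorm(30), rnorm(30, 1)),
                   rep(c("a", "b"), each = 30))$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("a perfect predictor is selected with unit standardized coefficient", {
  d <- data.frame(y = 3 * (1:30) - 4, x = 1:30,
                  w = rnorm(30, sd = 1e4))
  fit <- stepwise_ols(d, "y", c("x", "w"))
  expect_identical(fit$selected, "x")
  expect_equal(unname(fit$beta["x"]), 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("with both thresholds at 1 stepwise reduces to full OLS", {
  set.seed(77)
  d <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  d$y <- d$a - 2 * d$b + rnorm(60)
  fit <- stepwise_ols(d, "y", c("a", "b", "c"), alpha_in = 1, alpha_out = 1,
                      prefilter = FALSE)
  expect_setequal(fit$selected, c("a", "b", "c"))
  zfull <- lm(y ~ a + b + c, data = as.data.frame(scale(d)))
  expect_equal(fit$beta[c("a", "b", "c")],
               coef(zfull)[c("a", "b", "c")], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("standardized coefficients are invariant to affine predictor rescaling", {
  set.seed(78)
  d <- data.frame(a = rnorm(80), b = rnorm(80))
  d$y <- 2 * d$a + d$b + rnorm(80)
  f1 <- stepwise_ols(d, "y", c("a", "b"))
  d2 <- transform(d, a = 1000 * a + 5)
  f2 <- stepwise_ols(d2, "y", c("a", "b"))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  # negating a predictor negates its coefficient and keeps its p-value
  d3 <- transform(d, a = -a)
  f3 <- stepwise_ols(d3, "y", c("a", "b"))
  expect_equal(unname(f3$beta["a"]), -unname(f1$beta["a"]), tolerance = 1e-9)
  expect_equal(f3$p, f1$p, tolerance = 1e-9)
})

test_that("collinear candidate sets are rejected with the columns named", {
  set.seed(79)
  d <- data.frame(a = rnorm(40))
  d$b <- 2 * d$a
  d$y <- d$a + rnorm(40)
  expect_error(stepwise_ols(d, "y", c("a", "b")), "collinear")
  expect_error(stepwise_ols(d[1:12, ], "y", c("a", "b")), "n >")
})

test_that("age-decade summaries bin, pool and trend correctly", {
  d <- data.frame(age = rep(25, 30))
  for (l in c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "PR", "RPE"))
    d[[l]] <- rnorm(30, 25000, 100)
  ag <- age_group_summary(d)
  tab <- ag$table
  expect_true(all(tab$n[tab$age_group == "20-29"] == 30))
  expect_true(all(tab$n[tab$age_group != "20-29"] == 0))
  # deterministic decline: Spearman rho of exactly -1
  d2 <- data.frame(age = seq(50, 80, length.out = 40))
  for (l in c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "PR"))
    d2[[l]] <- 40000 - 100 * d2$age
  d2$RPE <- 30000 + 50 * d2$age
  ag2 <- age_group_summary(d2)
  expect_equal(ag2$trend$rho[ag2$trend$layer == "RNFL"], -1)
  expect_equal(ag2$trend$rho[ag2$trend$layer == "RPE"], 1)
  # under-20 subjects pool into the first decade and are counted
  d3 <- d
  d3$age[1:3] <- 19
  ag3 <- age_group_summary(d3)
  expect_equal(ag3$underage_pooled, 3)
  expect_true(all(ag3$table$n[ag3$table$age_group == "20-29"] == 30))
})

test_that("p-values live in the unit interval across the battery", {
  d <- generate_cohort(cohort_model(), 60, seed = 9)
  sc <- correlation_screen(d)
  expect_true(all(sc$p >= 0 & sc$p <= 1, na.rm = TRUE))
  ct <- compare_groups(d$RNFL, d$sex)
  expect_true(ct$p >= 0 && ct$p <= 1)
})
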