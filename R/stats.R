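# Cohort statistics for normative optical-intensity analysis:
# two-operator reproducibility (ICC), univariate correlation screens,
# group comparisons, stepwise multiple regression with standardized
# coefficients, and age-decade summaries.

#' Two-operator intraclass correlation coefficient
#'
#' Computes the single-measure ICC from the two-way ANOVA mean squares of a
#' subjects-by-operators table.  The primary estimate is ICC(2,1) (two-way
#' random effects, absolute agreement): operators are treated as a random
#' sample of interchangeable raters.  ICC(3,1) (two-way mixed, consistency)
#' is reported alongside.  The F test of between-subject variance
#' (`MS_rows / MS_error`) accompanies the estimate.
#'
#' @param a,b paired measurements by operators A and B (same subjects, same
#'   order), at least 5 complete pairs.
#' @return list with `icc2`, `icc3`, `F`, `df1`, `df2`, `p`, the mean
#'   squares, and `degenerate` (TRUE when between-subject variance is zero
#'   and the ICC is undefined).
#' @export
icc_two_operator <- function(a, b) {
  if (length(a) != length(b)) stop("operator vectors must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 5) stop("need at least 5 complete subject pairs")
  k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- isTRUE(all.equal(ssr, 0)) || msr <= 0
  icc2 <- if (degenerate) NA_real_ else
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc3 <- if (degenerate) NA_real_ else (msr - mse) / (msr + (k - 1) * mse)
  Fv <- if (mse > 0) msr / mse else Inf
  p <- pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc2 = icc2, icc3 = icc3, F = Fv, df1 = n - 1, df2 = (n - 1) * (k - 1),
       p = p, msr = msr, msc = msc, mse = mse, n = n, degenerate = degenerate)
}

#' Correlation screen of covariates against layer intensities
#'
#' Pairwise Pearson or Spearman correlations with two-sided p-values over
#' complete cases per pair.  Zero-variance pairs are reported as `NA` and
#' listed in the `undefined` attribute.
#'
#' @param cohort data.frame (e.g. from [generate_cohort()]).
#' @param covariates,responses column names; defaults: the standard
#'   covariate set against the eight layers.
#' @param method `"pearson"` or `"spearman"`.
#' @return list of matrices `r` and `p` (covariates x responses).
#' @export
correlation_screen <- function(cohort,
                               covariates = c("age", "height_cm", "weight_kg",
                                              "se_d", "axial_length_mm",
                                              "imageQ", "disc_area_mm2",
                                              "rd_area_ratio"),
                               responses = .layers,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(cohort) < 10) stop("need at least 10 subjects")
  r <- p <- matrix(NA_real_, length(covariates), length(responses),
                   dimnames = list(covariates, responses))
  undefined <- character()
  for (i in seq_along(covariates)) for (j in seq_along(responses)) {
    x <- cohort[[covariates[i]]]; y <- cohort[[responses[j]]]
    cc <- complete.cases(x, y)
    if (sd(x[cc]) == 0 || sd(y[cc]) == 0) {
      undefined <- c(undefined, paste0(covariates[i], ":", responses[j]))
      next
    }
    ct <- suppressWarnings(cor.test(x[cc], y[cc], method = method))
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  structure(list(r = r, p = p, method = method, n = nrow(cohort)),
            undefined = undefined)
}

#' Group comparisons by t test
#'
#' Independent two-sample t tests (classic, equal variance) for grouped
#' comparisons such as men vs women, and paired t tests for within-subject
#' contrasts such as nasal vs temporal sector means.  A paired contrast
#' with a constant nonzero difference is degenerate (infinite t) and is
#' flagged rather than silently reported.
#'
#' @param x numeric outcome; for `mode = "paired"`, the first member of
#'   each pair.
#' @param y grouping factor with two levels (independent mode) or the
#'   second member of each pair (paired mode).
#' @param mode `"independent"` or `"paired"`.
#' @return list with `t`, `df`, `p`, `estimate`, `mode`, `degenerate`.
#' @export
compare_groups <- function(x, y, mode = c("independent", "paired")) {
  mode <- match.arg(mode)
  if (mode == "independent") {
    g <- factor(y)
    if (nlevels(g) != 2) stop("independent mode needs exactly two groups")
    if (any(table(g) < 2)) stop("each group needs at least 2 observations")
    tt <- t.test(x ~ g, var.equal = TRUE)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, estimate = unname(diff(rev(tt$estimate))),
                mode = mode, degenerate = FALSE))
  }
  if (length(x) != length(y)) stop("paired mode needs matched vectors")
  dif <- x - y
  if (length(dif) < 2) stop("need at least 2 pairs")
  if (sd(dif) == 0) {
    d0 <- mean(dif) == 0
    return(list(t = if (d0) 0 else Inf * sign(mean(dif)),
                df = length(dif) - 1, p = if (d0) 1 else 0,
                estimate = mean(dif), mode = mode, degenerate = !d0))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       estimate = unname(tt$estimate), mode = mode, degenerate = FALSE)
}

# partial-F p-value for adding/keeping one term, robust to perfect fits
.partial_f_p <- function(rss0, rss1, df_resid1) {
  if (df_resid1 <= 0) return(NA_real_)
  if (rss1 <= 0) return(if (rss0 <= 0) 1 else 0)
  f <- (rss0 - rss1) / (rss1 / df_resid1)
  pf(max(f, 0), 1, df_resid1, lower.tail = FALSE)
}

#' Stepwise multiple regression with standardized coefficients
#'
#' Classic forward selection with backward removal on partial-F p-values:
#' at each step the candidate with the smallest entry p-value joins the
#' model if below `alpha_in`, then any included predictor whose p-value
#' exceeds `alpha_out` is dropped; iterate to a fixed point.  When
#' `prefilter = TRUE`, candidates are first screened univariately and only
#' those with p < `alpha_in` enter the candidate pool (the usual screen
#' before multivariate analysis).  Coefficients are reported standardized
#' (response and predictors z-scored), making them unit-free effect sizes.
#'
#' @param cohort data.frame.
#' @param response response column name.
#' @param candidates candidate predictor column names.
#' @param alpha_in,alpha_out entry and removal thresholds.
#' @param prefilter univariately screen candidates at `alpha_in` first.
#' @return list of class `stepwise_fit`: `selected`, `beta` (standardized),
#'   `p`, `r_squared`, `trace` (entry/removal order), `n`.
#' @export
stepwise_ols <- function(cohort, response, candidates,
                         alpha_in = 0.05, alpha_out = 0.10,
                         prefilter = TRUE) {
  stopifnot(response %in% names(cohort), all(candidates %in% names(cohort)))
  d <- cohort[complete.cases(cohort[c(response, candidates)]),
              c(response, candidates)]
  n <- nrow(d)
  if (n <= length(candidates) + 10)
    stop("need n > number of candidates + 10")
  X <- as.matrix(d[candidates])
  if (length(candidates) > 1) {
    sdev <- apply(X, 2, sd)
    if (any(sdev == 0))
      stop("zero-variance candidate(s): ",
           paste(candidates[sdev == 0], collapse = ", "))
    kap <- kappa(scale(X), exact = TRUE)
    if (kap > 1e8) {
      cm <- abs(cor(X)); diag(cm) <- 0
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop(sprintf("collinear candidates (condition number %.3g): %s and %s",
                   kap, candidates[worst[1]], candidates[worst[2]]))
    }
  }
  y <- d[[response]]

  if (prefilter) {
    keep <- vapply(candidates, function(v) {
      ct <- suppressWarnings(cor.test(d[[v]], y))
      is.finite(ct$p.value) && ct$p.value < alpha_in
    }, TRUE)
    pool <- candidates[keep]
  } else pool <- candidates

  rss_of <- function(vars) {
    if (!length(vars)) return(sum((y - mean(y))^2))
    fit <- lm(y ~ ., data = d[, vars, drop = FALSE])
    sum(fit$residuals^2)
  }
  included <- character()
  trace <- character()
  repeat {
    changed <- FALSE
    # entry
    out_pool <- setdiff(pool, included)
    if (length(out_pool)) {
      rss0 <- rss_of(included)
      ps <- vapply(out_pool, function(v) {
        .partial_f_p(rss0, rss_of(c(included, v)),
                     n - length(included) - 2)
      }, 0)
      if (any(is.finite(ps)) && min(ps, na.rm = TRUE) < alpha_in) {
        add <- out_pool[which.min(ps)]
        included <- c(included, add)
        trace <- c(trace, paste0("+", add))
        changed <- TRUE
      }
    }
    # removal
    repeat {
      if (length(included) < 1) break
      rss1 <- rss_of(included)
      ps <- vapply(included, function(v) {
        .partial_f_p(rss_of(setdiff(included, v)), rss1,
                     n - length(included) - 1)
      }, 0)
      if (max(ps, na.rm = TRUE) > alpha_out) {
        drop_ <- included[which.max(ps)]
        included <- setdiff(included, drop_)
        trace <- c(trace, paste0("-", drop_))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  beta <- p <- setNames(numeric(0), character(0))
  r2 <- 0
  if (length(included)) {
    zd <- as.data.frame(scale(d[, c(response, included), drop = FALSE]))
    fit <- lm(stats::reformulate(included, response = response), data = zd)
    sm <- suppressWarnings(summary(fit))
    cf <- sm$coefficients
    beta <- setNames(cf[included, 1], included)
    rss1 <- rss_of(included)
    p <- vapply(included, function(v)
      .partial_f_p(rss_of(setdiff(included, v)), rss1,
                   n - length(included) - 1), 0)
    r2 <- sm$r.squared
  }
  structure(list(response = response, selected = included, beta = beta,
                 p = p, r_squared = r2, trace = trace, n = n,
                 alpha_in = alpha_in, alpha_out = alpha_out,
                 candidates = candidates, pool = pool),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> %s ~ %s  (n = %d, R^2 = %.3f)\n",
              x$response,
              if (length(x$selected)) paste(x$selected, collapse = " + ") else "1",
              x$n, x$r_squared))
  if (length(x$beta)) {
    for (v in x$selected)
      cat(sprintf("  beta[%s] = %+.3f  (p = %.3g)\n", v, x$beta[v], x$p[v]))
  }
  cat("  trace:", if (length(x$trace)) paste(x$trace, collapse = " ") else "(none)", "\n")
  invisible(x)
}

#' Age-decade summaries and age trends of layer intensity
#'
#' Bins subjects into decades (20-29 ... 60-69, 70+; subjects under 20 are
#' pooled into the first bin and flagged) and reports per-bin mean and SD
#' of each layer intensity.  Two Spearman age trends accompany the table:
#' for layers whose intensity declines late in life the trend is evaluated
#' on subjects aged `decline_from` and older, while the RPE trend uses all
#' ages.
#'
#' @param cohort data.frame with `age` and layer columns.
#' @param layers layer column names.
#' @param decline_from age cutoff for the declining-layer trend (years).
#' @return list with `table` (per-bin, per-layer mean, SD, n), `trend`
#'   (per-layer Spearman rho and p plus the subset used), and
#'   `underage_pooled` (how many under-20 subjects were pooled).
#' @export
age_group_summary <- function(cohort, layers = .layers, decline_from = 50) {
  stopifnot("age" %in% names(cohort))
  edges <- c(-Inf, 30, 40, 50, 60, 70, Inf)
  labels <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70+")
  bin <- cut(cohort$age, edges, labels = labels, right = FALSE)
  underage <- sum(cohort$age < 20)
  rows <- list()
  for (g in labels) {
    i <- bin == g
    for (l in layers) {
      rows[[length(rows) + 1]] <- data.frame(
        age_group = g, layer = l, n = sum(i),
        mean_au = if (any(i)) mean(cohort[[l]][i]) else NA_real_,
        sd_au = if (sum(i) > 1) sd(cohort[[l]][i]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  trend <- do.call(rbind, lapply(layers, function(l) {
    use_all <- identical(l, "RPE")
    i <- if (use_all) rep(TRUE, nrow(cohort)) else cohort$age >= decline_from
    if (sum(i) >= 5 && sd(cohort[[l]][i]) > 0) {
      ct <- suppressWarnings(cor.test(cohort$age[i], cohort[[l]][i],
                                      method = "spearman"))
      data.frame(layer = l, subset = if (use_all) "all ages" else
        paste0("age >= ", decline_from),
        rho = unname(ct$estimate), p = ct$p.value, n = sum(i),
        stringsAsFactors = FALSE)
    } else {
      data.frame(layer = l, subset = NA_character_, rho = NA_real_,
                 p = NA_real_, n = sum(i), stringsAsFactors = FALSE)
    }
  }))
  list(table = tab, trend = trend, underage_pooled = underage)
}
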