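# Simulated normative cohorts: demographic covariates plus per-layer mean
# optical intensity generated from a linear age + image-quality model.
#
# Default parameters encode the structure reported for 231 normal eyes:
# covariate means/SDs, per-layer intensity means/SDs, standardized age and
# image-quality effects, and a negative age/image-quality correlation that
# reproduces the univariate correlation pattern (including the apparent
# univariate age effect in layers whose adjusted age coefficient is zero).

.default_layer_mean <- c(RNFL = 31558.68, GCL = 26653.71, IPL = 26677.85,
                         INL = 23538.66, OPL = 24824.14, ONL = 21381.69,
                         PR = 31759.63, RPE = 34677.2)
.default_layer_sd <- c(RNFL = 1097.91, GCL = 896.17, IPL = 903.37,
                       INL = 875.85, OPL = 933.38, ONL = 794.03,
                       PR = 1444.96, RPE = 695.81)
.default_beta_age <- c(RNFL = -0.362, GCL = -0.191, IPL = -0.222,
                       INL = -0.179, OPL = -0.204, ONL = 0,
                       PR = 0, RPE = 0.456)
.default_beta_q <- c(RNFL = 0.576, GCL = 0.702, IPL = 0.732,
                     INL = 0.783, OPL = 0.779, ONL = 0.851,
                     PR = 0.553, RPE = 0.626)

#' Cohort generating model for per-subject layer intensities
#'
#' Covariates are drawn independently except height and weight, which
#' depend on sex; age and image quality are drawn from a bivariate normal
#' with correlation `cor_age_q` (older subjects tend to have poorer image
#' quality, e.g. through media opacity), then truncated to their ranges.
#' Each layer's mean optical intensity follows
#' `mean + b_age (age - mu_age) + b_q (imageQ - mu_q) + noise`, where the
#' raw slopes are derived from the standardized coefficients `beta_age`,
#' `beta_q` and the layer SD, and the residual SD is chosen so the model's
#' implied R^2 equals `beta' Sigma beta` for the correlated predictors.
#'
#' @param age_mean,age_sd,age_range age distribution (years), truncated.
#' @param p_female probability of female sex.
#' @param height_by_sex,weight_by_sex list(M = c(mean, sd), F = c(mean, sd)).
#' @param se_mean,se_sd spherical equivalent (D).
#' @param axial_mean,axial_sd axial length (mm).
#' @param q_mean,q_sd,q_range device image-quality score.
#' @param disc_area_mean,disc_area_sd optic disc area (mm^2).
#' @param rd_ratio_mean,rd_ratio_sd rim/disc area ratio.
#' @param cor_age_q correlation between age and image quality.
#' @param layer_mean,layer_sd per-layer intensity mean and SD (AU), length 8.
#' @param beta_age,beta_q standardized coefficients per layer, length 8.
#' @param p_right probability the study eye is the right eye.
#' @return object of class `cohort_model`.
#' @export
cohort_model <- function(age_mean = 46.90, age_sd = 16.87,
                         age_range = c(18, 90),
                         p_female = 129 / 231,
                         height_by_sex = list(M = c(168.99, 5.40),
                                              F = c(156.98, 4.88)),
                         weight_by_sex = list(M = c(66.36, 9.20),
                                              F = c(54.84, 9.31)),
                         se_mean = -0.67, se_sd = 1.91,
                         axial_mean = 23.65, axial_sd = 1.22,
                         q_mean = 58.19, q_sd = 4.39, q_range = c(45, 80),
                         disc_area_mean = 2.27, disc_area_sd = 0.41,
                         rd_ratio_mean = 0.66, rd_ratio_sd = 0.21,
                         cor_age_q = -0.29,
                         layer_mean = .default_layer_mean,
                         layer_sd = .default_layer_sd,
                         beta_age = .default_beta_age,
                         beta_q = .default_beta_q,
                         p_right = 113 / 231) {
  stopifnot(length(layer_mean) == 8, length(layer_sd) == 8,
            length(beta_age) == 8, length(beta_q) == 8,
            all(layer_sd > 0), abs(cor_age_q) < 1)
  r2 <- beta_age^2 + beta_q^2 + 2 * beta_age * beta_q * cor_age_q
  if (any(r2 >= 1))
    stop("standardized coefficients imply a model R^2 of 1 or more; residual SD would not be positive")
  m <- as.list(environment())
  m$resid_sd <- layer_sd * sqrt(1 - r2)
  class(m) <- "cohort_model"
  m
}

#' Simulate a cohort of subjects with per-layer intensities
#'
#' @param model a [cohort_model()].
#' @param n number of subjects (at least 10; below that the downstream
#'   stepwise regression is not defined).
#' @param seed integer RNG seed.
#' @return data.frame with one row per subject: identifiers, covariates and
#'   the eight per-layer mean intensities (AU).
#' @export
generate_cohort <- function(model, n, seed) {
  stopifnot(inherits(model, "cohort_model"))
  if (n < 10) stop("refusing to generate a cohort with fewer than 10 subjects")
  if (missing(seed)) stop("a seed is required")
  .run_seeded(seed, {
    sex <- ifelse(runif(n) < model$p_female, "F", "M")
    draw_trunc2 <- function(n) {
      # bivariate (age, imageQ), truncated by joint resampling
      age <- numeric(n); q <- numeric(n)
      need <- seq_len(n)
      while (length(need)) {
        z1 <- rnorm(length(need)); z2 <- rnorm(length(need))
        a <- model$age_mean + model$age_sd * z1
        qq <- model$q_mean + model$q_sd *
          (model$cor_age_q * z1 + sqrt(1 - model$cor_age_q^2) * z2)
        ok <- a >= model$age_range[1] & a <= model$age_range[2] &
          qq >= model$q_range[1] & qq <= model$q_range[2]
        age[need[ok]] <- a[ok]; q[need[ok]] <- qq[ok]
        need <- need[!ok]
      }
      list(age = age, q = q)
    }
    aq <- draw_trunc2(n)
    hw <- function(tab) {
      out <- numeric(n)
      for (s in c("M", "F")) {
        i <- sex == s
        out[i] <- rnorm(sum(i), tab[[s]][1], tab[[s]][2])
      }
      out
    }
    d <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      sex = sex,
      age = aq$age,
      height_cm = hw(model$height_by_sex),
      weight_kg = hw(model$weight_by_sex),
      se_d = pmin(pmax(rnorm(n, model$se_mean, model$se_sd), -6), 6),
      axial_length_mm = rnorm(n, model$axial_mean, model$axial_sd),
      imageQ = aq$q,
      disc_area_mm2 = pmax(rnorm(n, model$disc_area_mean, model$disc_area_sd), 0.5),
      rd_area_ratio = pmin(pmax(rnorm(n, model$rd_ratio_mean, model$rd_ratio_sd), 0), 1),
      laterality = ifelse(runif(n) < model$p_right, "OD", "OS"),
      stringsAsFactors = FALSE)
    for (l in seq_along(.layers)) {
      b_age <- model$beta_age[l] * model$layer_sd[l] / model$age_sd
      b_q <- model$beta_q[l] * model$layer_sd[l] / model$q_sd
      y <- model$layer_mean[l] +
        b_age * (d$age - model$age_mean) +
        b_q * (d$imageQ - model$q_mean) +
        rnorm(n, 0, model$resid_sd[l])
      d[[.layers[l]]] <- pmin(pmax(y, 0), 65535)
    }
    d
  })
}
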