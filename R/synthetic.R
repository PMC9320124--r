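#' Reference nine-band compositions
#'
#' Sex-specific geometric-mean time-use compositions (min/day over the
#' 960-min waking day) used as generator targets and substitution
#' baselines: roughly 75% of the day below 50 mg, monotonically less time
#' at higher accelerations, with about 11 min (boys) and 6.3 min (girls)
#' at or above 700 mg.
#'
#' @param sex "all", "boy" or "girl".
#' @param total Closure constant.
#' @return Named closed composition.
#' @export
reference_composition <- function(sex = c("all", "boy", "girl"),
                                  total = 960) {
  sex <- match.arg(sex)
  raw <- switch(sex,
    all  = c(722.9, 105.7, 51.1, 27.8, 15.4, 9.1, 5.8, 14.3, 8.0),
    boy  = c(719.9, 102.6, 49.6, 27.8, 16.1, 9.8, 6.4, 16.7, 11.1),
    girl = c(724.0, 108.0, 52.0, 28.0, 15.0, 9.0, 5.0, 13.0, 6.3))
  close_composition(stats::setNames(raw, band_scheme()$labels),
                    total = total)
}

default_effect_clr <- function() {
  # band-vs-remaining pattern of realistic magnitude: strongest inverse
  # association for the top band, positive 50-100, inverse 100-150;
  # mapped from the beta_ilr1 scale by 1/sqrt(D/(D-1)) and centred to sum 0
  b <- c(0.03, 1.39, -2.55, 1.87, -1.64, 1.04, -0.09, 0.39, -0.71)
  a <- (b - mean(b)) / sqrt(9 / 8)
  stats::setNames(a, band_scheme()$labels)
}

#' Synthetic cohort generator configuration
#'
#' Bundles the study-design constants the generator emulates: cohort size
#' and sex split, school structure, sex-specific target geometric-mean
#' compositions, clr-space spread, the true clr effect vector linking the
#' composition to the outcome, covariate effects, the marginal outcome SD
#' target, and the exclusion-cascade missingness counts.
#'
#' The outcome noise SD is derived at generation time so that the marginal
#' outcome SD matches \code{outcome_sd} given the configured effects.
#'
#' @param n Roster size before exclusions.
#' @param prop_girls Proportion of girls.
#' @param n_schools Number of schools.
#' @param prop_primary Proportion of schools that are primary schools.
#' @param target_boy,target_girl Sex-specific target geometric-mean
#'   compositions (closed to \code{total}).
#' @param clr_sd Per-band log-scale spread of compositions (length D);
#'   draws are projected onto the clr plane.
#' @param effect_clr True clr-space effect vector a (must sum to 0); the
#'   implied band-vs-remaining coefficient is \code{sqrt(D/(D-1)) * a_j}.
#' @param beta_sex_boy,beta_age,beta_eimd Covariate effects on the outcome.
#' @param outcome_mean,outcome_sd Marginal outcome mean and SD targets.
#' @param missing_outcome,missing_wear,missing_ses Exact record counts that
#'   lose, respectively, the outcome, wear validity, and the SES decile
#'   (applied in cascade order).
#' @param total Day length in minutes.
#' @return List of class \code{cohort_config}; validated on construction.
#' @export
cohort_config <- function(n = 1803,
                          prop_girls = 0.575,
                          n_schools = 63,
                          prop_primary = 2 / 3,
                          target_boy = reference_composition("boy"),
                          target_girl = reference_composition("girl"),
                          clr_sd = c(0.05, 0.10, 0.12, 0.14, 0.16,
                                     0.18, 0.20, 0.20, 0.30),
                          effect_clr = default_effect_clr(),
                          beta_sex_boy = 0.30,
                          beta_age = 0.02,
                          beta_eimd = -0.02,
                          outcome_mean = 0.51,
                          outcome_sd = 1.24,
                          missing_outcome = 67,
                          missing_wear = 233,
                          missing_ses = 50,
                          total = 960) {
  cfg <- list(n = n, prop_girls = prop_girls, n_schools = n_schools,
              prop_primary = prop_primary,
              target_boy = close_composition(target_boy, total),
              target_girl = close_composition(target_girl, total),
              clr_sd = clr_sd, effect_clr = effect_clr,
              beta_sex_boy = beta_sex_boy, beta_age = beta_age,
              beta_eimd = beta_eimd,
              outcome_mean = outcome_mean, outcome_sd = outcome_sd,
              missing_outcome = missing_outcome,
              missing_wear = missing_wear, missing_ses = missing_ses,
              total = total,
              band_labels = names(effect_clr) %||%
                band_scheme()$labels[seq_along(effect_clr)])
  problems <- character(0)
  D <- length(cfg$effect_clr)
  if (D < 3) problems <- c(problems, "effect_clr needs >= 3 parts")
  if (abs(sum(cfg$effect_clr)) > 1e-8) {
    problems <- c(problems, "effect_clr must sum to 0")
  }
  if (length(cfg$clr_sd) != D || any(cfg$clr_sd <= 0)) {
    problems <- c(problems, "clr_sd must be positive, one entry per band")
  }
  if (length(cfg$target_boy) != D || length(cfg$target_girl) != D) {
    problems <- c(problems, "target compositions must match effect_clr length")
  }
  if (prop_girls < 0 || prop_girls > 1 || prop_primary < 0 ||
      prop_primary > 1) {
    problems <- c(problems, "proportions must be in [0, 1]")
  }
  if (n < 1 || n_schools < 2) {
    problems <- c(problems, "need n >= 1 and n_schools >= 2")
  }
  miss <- missing_outcome + missing_wear + missing_ses
  if (any(c(missing_outcome, missing_wear, missing_ses) < 0) || miss > n) {
    problems <- c(problems, "missingness counts must be >= 0 and sum <= n")
  }
  if (outcome_sd <= 0) problems <- c(problems, "outcome_sd must be positive")
  if (length(problems)) {
    stop("invalid generator config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config: n =", x$n, ", girls =",
      round(100 * x$prop_girls, 1), "%, schools =", x$n_schools, "\n")
  cat("Missingness (outcome/wear/SES):", x$missing_outcome, "/",
      x$missing_wear, "/", x$missing_ses, "\n")
  invisible(x)
}

#' Noise SD implied by the configured marginal outcome SD
#'
#' The signal variance is \code{sum(a_j^2 s_j^2)} (the clr projection leaves
#' a zero-sum effect vector untouched) plus the covariate contributions;
#' the residual noise SD makes the marginal SD hit the configured target.
#' @noRd
derive_noise_sd <- function(cfg, var_age_c = 2.4, var_eimd = 7.6) {
  var_comp <- sum(cfg$effect_clr^2 * cfg$clr_sd^2)
  p_boy <- 1 - cfg$prop_girls
  var_cov <- cfg$beta_sex_boy^2 * p_boy * (1 - p_boy) +
    cfg$beta_age^2 * var_age_c + cfg$beta_eimd^2 * var_eimd
  v <- cfg$outcome_sd^2 - var_comp - var_cov
  if (v <= 0.01) {
    stop("configured effects already exceed the marginal outcome variance")
  }
  sqrt(v)
}

#' Generate a synthetic youth activity cohort
#'
#' Draws a seeded cohort whose structure matches the analysis assumptions:
#' nine-part compositions additive-logistic-normal around the sex-specific
#' target geometric means, covariates with realistic youth-cohort
#' distributions, an outcome linear in the clr coordinates plus covariates
#' with Gaussian noise, and (optionally) exact missingness counts applied
#' in exclusion-cascade order.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @param missingness Apply [inject_missingness()] with the configured
#'   counts (default TRUE).
#' @return Data frame of cohort records (one per participant) with
#'   covariates, wear metadata, the nine band columns and \code{bmi_z}.
#'   Attributes: \code{config}, \code{true_beta_ilr1} (the implied
#'   band-vs-remaining coefficients \code{sqrt(D/(D-1)) * a}),
#'   \code{noise_sd}.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            missingness = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n
  D <- length(config$effect_clr)
  labels <- config$band_labels

  sex <- ifelse(stats::runif(n) < config$prop_girls, "girl", "boy")

  n_primary <- max(1L, round(config$prop_primary * config$n_schools))
  school_type_of <- rep(c("primary", "secondary"),
                        c(n_primary, config$n_schools - n_primary))
  # two-thirds of pupils attend primary schools; allocate within type
  is_primary <- stats::runif(n) < config$prop_primary
  school_id <- integer(n)
  school_id[is_primary] <- sample.int(n_primary, sum(is_primary),
                                      replace = TRUE)
  school_id[!is_primary] <- n_primary +
    sample.int(config$n_schools - n_primary, sum(!is_primary),
               replace = TRUE)
  school_type <- school_type_of[school_id]
  age <- ifelse(school_type == "primary",
                pmin(pmax(stats::rnorm(n, 8.6, 1.7), 5), 11),
                pmin(pmax(stats::rnorm(n, 13.4, 1.5), 11), 16))

  eimd <- sample(1:10, n, replace = TRUE,
                 prob = c(rep(0.1348, 5), rep(0.0652, 5)))
  accel_model <- sample(c("GT9X", "GENEActiv", "AX3"), n, replace = TRUE,
                        prob = c(0.7, 0.2, 0.1))
  samp_freq <- sample(c(100, 30), n, replace = TRUE, prob = c(0.8, 0.2))

  clr_boy <- clr(config$target_boy)
  clr_girl <- clr(config$target_girl)
  centre <- matrix(0, n, D)
  centre[sex == "boy", ] <- matrix(clr_boy, sum(sex == "boy"), D,
                                   byrow = TRUE)
  centre[sex == "girl", ] <- matrix(clr_girl, sum(sex == "girl"), D,
                                    byrow = TRUE)
  U <- matrix(stats::rnorm(n * D), n, D) %*% diag(config$clr_sd)
  U <- U - rowMeans(U)  # project onto the clr plane
  comp <- clr_inverse(centre + U, total = config$total)
  colnames(comp) <- labels

  records <- data.frame(id = seq_len(n), sex = sex, age = age,
                        school_id = school_id, school_type = school_type,
                        eimd_decile = eimd, accel_model = accel_model,
                        samp_freq = samp_freq,
                        stringsAsFactors = FALSE)
  records <- center_age_by_group(records)

  noise_sd <- derive_noise_sd(config)
  lp_comp <- drop((centre + U) %*% config$effect_clr)
  p_boy <- 1 - config$prop_girls
  mean_lp <- sum(config$effect_clr *
                   (p_boy * clr_boy + config$prop_girls * clr_girl)) +
    config$beta_sex_boy * p_boy
  intercept <- config$outcome_mean - mean_lp
  records$bmi_z <- intercept + lp_comp +
    config$beta_sex_boy * (sex == "boy") +
    config$beta_age * records$age_c +
    config$beta_eimd * (eimd - mean(1:10)) +
    stats::rnorm(n, 0, noise_sd)

  records$valid_days <- sample(3:7, n, replace = TRUE,
                               prob = c(0.06, 0.12, 0.30, 0.32, 0.20))
  records$calib_error_mg <- round(abs(stats::rnorm(n, 3, 2)), 2)
  records$wear_ok <- TRUE
  records <- cbind(records, as.data.frame(comp))

  if (missingness) records <- inject_missingness(records, config)

  attr(records, "config") <- config
  attr(records, "true_beta_ilr1") <-
    stats::setNames(sqrt(D / (D - 1)) * config$effect_clr, labels)
  attr(records, "noise_sd") <- noise_sd
  records
}

#' Inject exact missingness counts in cascade order
#'
#' Removes the outcome from \code{missing_outcome} records; among the
#' remainder, marks \code{missing_wear} records as failing wear screening;
#' among the remainder of those, blanks the SES decile of
#' \code{missing_ses} records. Applied this way, the downstream
#' [exclusion_cascade()] stage counts equal the configured counts exactly.
#'
#' @param records Complete cohort records.
#' @param config A [cohort_config()] (its missing_* counts are used).
#' @return Records with missingness applied.
#' @export
inject_missingness <- function(records, config) {
  n <- nrow(records)
  need <- config$missing_outcome + config$missing_wear + config$missing_ses
  if (need > n) stop("missingness counts exceed the number of records")
  idx <- sample.int(n, need)
  i1 <- idx[seq_len(config$missing_outcome)]
  i2 <- idx[config$missing_outcome + seq_len(config$missing_wear)]
  i3 <- idx[config$missing_outcome + config$missing_wear +
              seq_len(config$missing_ses)]
  if (length(i1)) records$bmi_z[i1] <- NA_real_
  if (length(i2)) records$wear_ok[i2] <- FALSE
  if (length(i3)) records$eimd_decile[i3] <- NA_integer_
  records
}

#' Generate an epoch-level ENMO stream realising a composition
#'
#' Emits one standardised 960-min day of epochs whose band memberships
#' reproduce the given composition up to whole-epoch rounding
#' (largest-remainder apportionment keeps the epoch count exact, so
#' [band_minutes()] inverts the stream to within one epoch per band).
#'
#' @param comp Closed composition (min/day).
#' @param scheme A [band_scheme()].
#' @param seed Integer seed.
#' @param epoch_s Epoch length in seconds.
#' @return Data frame: \code{epoch_index}, \code{enmo_mg}, \code{worn}.
#' @export
generate_epoch_stream <- function(comp, scheme = band_scheme(), seed = 1,
                                  epoch_s = 1) {
  set.seed(seed)
  total <- sum(comp)
  n_epochs <- round(total * 60 / epoch_s)
  target <- comp * 60 / epoch_s
  counts <- floor(target)
  short <- n_epochs - sum(counts)
  if (short > 0) {
    rem <- target - counts
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  lo <- scheme$edges
  hi <- ifelse(is.finite(scheme$upper), scheme$upper, 1500)
  vals <- unlist(lapply(seq_along(counts), function(j) {
    stats::runif(counts[j], lo[j], hi[j])
  }))
  data.frame(epoch_index = seq_len(n_epochs),
             enmo_mg = sample(vals),
             worn = 1L)
}
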