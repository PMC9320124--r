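test_that("coda_lm interpolates a noiseless linear outcome exactly", {
  coh <- small_cohort(n = 120, seed = 14)
  Z <- pivot_ilr(close_composition(as.matrix(coh[, bands9]), 960),
                 pivot_basis(9, lead = 9))
  coh$bmi_z <- 2 * Z[, 1] - 0.5 * Z[, 3] + 1
  fit <- coda_lm(bmi_z ~ 1, coh, parts = bands9, lead = "700+")
  expect_equal(coef(fit)[["ilr1"]], 2, tolerance = 1e-10)
  expect_equal(coef(fit)[["ilr3"]], -0.5, tolerance = 1e-10)
  expect_equal(coef(fit)[["(Intercept)"]], 1, tolerance = 1e-10)
  expect_lt(sum(residuals(fit)^2), 1e-16)
})

test_that("coda_lm equals a normal-equations oracle on a 40-row fixture", {
  coh <- small_cohort(n = 40, seed = 15)
  fit <- coda_lm(bmi_z ~ age_c + eimd_decile, coh, parts = bands9,
                 lead = "50-100")
  # independent linear-algebra route: build the design by hand
  Z <- pivot_ilr(close_composition(as.matrix(coh[, bands9]), 960),
                 pivot_basis(9, lead = 2))
  X <- cbind(1, Z, coh$age_c, coh$eimd_decile)
  beta <- solve(t(X) %*% X, t(X) %*% coh$bmi_z)
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-10)
  # covariance = s2 * (X'X)^-1
  s2 <- sum((coh$bmi_z - X %*% beta)^2) / (40 - ncol(X))
  expect_equal(unname(vcov(fit)), s2 * solve(t(X) %*% X),
               tolerance = 1e-8)
  expect_equal(fit$fit$df.residual, 40 - ncol(X))
})

test_that("coda_lm rejects rank-deficient designs by name", {
  coh <- small_cohort(n = 80, seed = 16)
  coh$dup <- coh$age_c
  expect_error(coda_lm(bmi_z ~ age_c + dup, coh, parts = bands9), "dup")
})

test_that("predict on new data uses the composition columns", {
  coh <- small_cohort(n = 150, seed = 17)
  fit <- coda_lm(bmi_z ~ age_c, coh, parts = bands9, lead = "700+")
  pred <- predict(fit, newdata = coh)
  expect_equal(pred, fitted(fit), ignore_attr = TRUE)
})

test_that("omnibus F matches stats::anova and flags degenerate reduction", {
  coh <- small_cohort(n = 200, seed = 18)
  fit <- coda_lm(bmi_z ~ sex + age_c, coh, parts = bands9)
  om <- omnibus_test(fit)
  expect_equal(om$df1, 8)
  expect_equal(om$df2, fit$fit$df.residual)
  # independent route through stats::anova on the two lm fits
  mf <- model.frame(fit$fit)
  red <- lm(bmi_z ~ sex + age_c, data = mf)
  a <- anova(red, fit$fit)
  expect_equal(om$F, a$F[2], tolerance = 1e-10)
  expect_equal(om$p, a$`Pr(>F)`[2], tolerance = 1e-10)
  # reduced model identical to the full one is rejected
  broken <- fit
  broken$znames <- character(0)
  expect_error(omnibus_test(broken), "df1 = 0")
})

test_that("a strong compositional effect is always detected", {
  for (s in 1:5) {
    coh <- small_cohort(n = 400, seed = 100 + s)
    fit <- coda_lm(bmi_z ~ sex + age_c, coh, parts = bands9)
    expect_lt(omnibus_test(fit)$p, 1e-3)
  }
})

test_that("the nine rotations share fitted values, F, and a zero-sum", {
  coh <- small_cohort(n = 300, seed = 19)
  scan <- pivot_scan(bmi_z ~ sex + age_c + eimd_decile, coh, bands9)
  fits <- attr(scan, "fits")
  base_fitted <- fitted(fits[[1]])
  for (f in fits[-1]) {
    expect_lt(max(abs(fitted(f) - base_fitted)), 1e-8)
  }
  expect_lt(abs(sum(scan$estimate)), 1e-8)
  Fs <- vapply(fits, function(f) omnibus_test(f)$F, numeric(1))
  expect_lt(diff(range(Fs)), 1e-8)
})

test_that("pivot scan recovers the generator's implied coefficients", {
  cfg <- cohort_config(n = 2000, missing_outcome = 0, missing_wear = 0,
                       missing_ses = 0)
  coh <- generate_cohort(cfg, seed = 20)
  truth <- attr(coh, "true_beta_ilr1")
  scan <- pivot_scan(bmi_z ~ sex + age_c + eimd_decile, coh, bands9)
  expect_lt(max(abs(scan$estimate - truth) / scan$se), 4)
})

test_that("null compositional effects stay near zero", {
  cfg <- cohort_config(n = 800, effect_clr = rep(0, 9),
                       missing_outcome = 0, missing_wear = 0,
                       missing_ses = 0)
  hits <- 0
  for (s in 1:10) {
    coh <- generate_cohort(cfg, seed = 200 + s)
    scan <- pivot_scan(bmi_z ~ sex, coh, bands9)
    hits <- hits + sum(scan$ci_lo > 0 | scan$ci_hi < 0)
  }
  # 90 intervals at the 5% level: expect ~4.5 false exclusions
  expect_lt(hits, 15)
})

test_that("sex stratification triggers on a sex effect and recovers it", {
  cfg <- cohort_config(n = 1200, beta_sex_boy = 0.8,
                       missing_outcome = 0, missing_wear = 0,
                       missing_ses = 0)
  coh <- generate_cohort(cfg, seed = 21)
  truth <- attr(coh, "true_beta_ilr1")
  an <- stratify_by_sex(bmi_z ~ sex + age_c, coh, bands9)
  expect_lt(an$sex_p, 0.05)
  expect_named(an$stratified, c("boy", "girl"))
  for (s in names(an$stratified)) {
    sc <- an$stratified[[s]]
    # both strata share the generator's compositional effect
    expect_lt(max(abs(sc$estimate - truth) / sc$se), 4)
    # stratified fits carry no sex term
    expect_false("sexgirl" %in% names(coef(attr(sc, "fits")[[1]])))
  }
})

test_that("stratification is rarely triggered without a sex effect", {
  cfg <- cohort_config(n = 300, beta_sex_boy = 0,
                       missing_outcome = 0, missing_wear = 0,
                       missing_ses = 0)
  trig <- 0
  for (s in 1:20) {
    coh <- generate_cohort(cfg, seed = 300 + s)
    an <- stratify_by_sex(bmi_z ~ sex + age_c, coh, bands9)
    trig <- trig + !is.null(an$stratified)
  }
  expect_lte(trig, 4)  # nominal 5% trigger rate
})

test_that("single-sex input fits the pooled model without a sex term", {
  coh <- small_cohort(n = 200, seed = 22)
  girls <- coh[coh$sex == "girl", ]
  an <- stratify_by_sex(bmi_z ~ sex + age_c, girls, bands9)
  expect_null(an$stratified)
  expect_true(is.na(an$sex_p))
  expect_false("sexgirl" %in%
                 names(coef(attr(an$pooled, "fits")[[1]])))
})

test_that("VIF matches the closed form and flags collinearity", {
  set.seed(23)
  x1 <- rnorm(500)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(500)
  X <- cbind(a = x1, b = x2)
  r <- cor(x1, x2)
  v <- vif(X)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  # centred orthogonal predictors: VIF exactly 1
  q <- unclass(poly(1:100, 3))
  expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-10)
  # duplicated column is infinite
  expect_equal(unname(vif(cbind(x1, x1))), c(Inf, Inf))
  # coda_lm method: no multicollinearity among ilr coords + covariates
  coh <- small_cohort(n = 300, seed = 24)
  fit <- coda_lm(bmi_z ~ sex + age_c, coh, parts = bands9)
  expect_true(all(is.finite(vif(fit))))
})

test_that("one-way ICC recovers known variance shares", {
  # known ICC = 0.3: between-sd sqrt(0.3), within-sd sqrt(0.7)
  est <- vapply(1:10, function(s) {
    set.seed(400 + s)
    g <- rep(1:50, each = 20)
    y <- rnorm(50, 0, sqrt(0.3))[g] + rnorm(1000, 0, sqrt(0.7))
    icc_oneway(y, g)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.03)
  expect_lt(max(abs(est - 0.3)), 0.15)
  # permuted labels: no group structure
  set.seed(25)
  y <- rnorm(600)
  expect_lt(icc_oneway(y, sample(rep(1:30, 20))), 0.02)
  # huge separation, tiny noise
  g <- rep(1:10, each = 10)
  y2 <- g * 100 + rnorm(100, 0, 0.01)
  expect_gt(icc_oneway(y2, g), 0.999)
  expect_error(icc_oneway(rnorm(5), c(1, 1, 1, 1, 1)), "groups")
})
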