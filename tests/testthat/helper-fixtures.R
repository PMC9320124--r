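# Shared fixtures built in code at test time.

bands9 <- band_scheme()$labels

# small complete cohort for regression tests (no missingness)
small_cohort <- function(n = 300, seed = 42, ...) {
  cfg <- cohort_config(n = n, missing_outcome = 0, missing_wear = 0,
                       missing_ses = 0, ...)
  generate_cohort(cfg, seed = seed)
}

# random strictly positive compositions closed to `total`
random_compositions <- function(n, D = 9, total = 960, seed = 1) {
  set.seed(seed)
  m <- matrix(exp(stats::rnorm(n * D, sd = 0.7)), n, D)
  close_composition(m, total = total)
}

expect_composition_equal <- function(x, y, tol = 1e-9) {
  expect_equal(unname(as.vector(x)), unname(as.vector(y)),
               tolerance = tol)
}
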