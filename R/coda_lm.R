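#' Compositional regression on pivot ILR coordinates
#'
#' Fits an ordinary least-squares regression of an outcome on the D-1 pivot
#' ILR coordinates of a time-use composition plus covariates. The first
#' coordinate contrasts the lead band against the geometric mean of all
#' remaining bands, so its coefficient is the band-vs-remaining association
#' the pivot scan extracts.
#'
#' @param formula Model formula of the form \code{outcome ~ covariates};
#'   composition coordinates are added internally. Use \code{outcome ~ 1}
#'   for an unadjusted fit.
#' @param data Data frame containing the outcome, covariates and the
#'   composition columns named in \code{parts}.
#' @param parts Character vector of composition column names (band labels).
#' @param lead Band (name or index into \code{parts}) isolated by the first
#'   pivot coordinate. Default: the first part.
#' @param total Closure constant in minutes.
#' @param pseudo Pseudo-duration for zero bands (see [zero_replace()]).
#' @return An object of class \code{coda_lm}: the underlying \code{lm} fit
#'   plus the pivot basis, part names and coordinate bookkeeping. Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov}, \code{confint},
#'   \code{predict}, \code{residuals}, \code{fitted}, \code{nobs}.
#' @examples
#' cfg <- cohort_config(n = 400, missing_outcome = 0, missing_wear = 0,
#'                      missing_ses = 0)
#' coh <- generate_cohort(cfg, seed = 1)
#' fit <- coda_lm(bmi_z ~ sex + age_c, coh, parts = cfg$band_labels,
#'                lead = "700+")
#' coef(fit)[["ilr1"]]
#' @export
coda_lm <- function(formula, data, parts, lead = parts[[1L]], total = 960,
                    pseudo = 1 / 120) {
  if (!all(parts %in% names(data))) {
    stop("composition columns missing from data: ",
         paste(setdiff(parts, names(data)), collapse = ", "))
  }
  D <- length(parts)
  lead_idx <- if (is.character(lead)) match(lead, parts) else as.integer(lead)
  if (is.na(lead_idx) || lead_idx < 1L || lead_idx > D) {
    stop("lead band not found among parts: ", lead)
  }
  X <- as.matrix(data[, parts, drop = FALSE])
  storage.mode(X) <- "double"
  X <- close_composition(zero_replace(X, pseudo), total = total)
  basis <- pivot_basis(D, lead = lead_idx)
  Z <- pivot_ilr(X, basis)
  znames <- paste0("ilr", seq_len(D - 1L))
  colnames(Z) <- znames
  df2 <- cbind(data, as.data.frame(Z))
  covars <- attr(stats::terms(formula, data = data), "term.labels")
  response <- all.vars(formula)[1L]
  f2 <- stats::reformulate(c(znames, covars), response = response)
  environment(f2) <- environment()
  fit <- stats::lm(f2, data = df2)
  b <- stats::coef(fit)
  if (anyNA(b)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(b)[is.na(b)], collapse = ", "))
  }
  structure(list(fit = fit, basis = basis, parts = parts,
                 lead = parts[[lead_idx]], znames = znames, total = total,
                 pseudo = pseudo, formula = formula,
                 call = match.call()),
            class = "coda_lm")
}

#' @export
print.coda_lm <- function(x, ...) {
  cat("Compositional regression (pivot ILR), lead band:", x$lead, "\n")
  cat("n =", stats::nobs(x$fit), ", residual df =", x$fit$df.residual, "\n")
  cat("\nCoefficients:\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @export
summary.coda_lm <- function(object, ...) {
  s <- summary(object$fit, ...)
  s$lead <- object$lead
  s
}

#' @export
coef.coda_lm <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.coda_lm <- function(object, ...) stats::vcov(object$fit)

#' @export
residuals.coda_lm <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.coda_lm <- function(object, ...) stats::fitted(object$fit)

#' @export
nobs.coda_lm <- function(object, ...) stats::nobs(object$fit)

#' @export
confint.coda_lm <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$fit, parm = parm, level = level, ...)
}

#' @export
predict.coda_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, ...))
  X <- as.matrix(newdata[, object$parts, drop = FALSE])
  storage.mode(X) <- "double"
  X <- close_composition(zero_replace(X, object$pseudo),
                         total = object$total)
  Z <- pivot_ilr(X, object$basis)
  colnames(Z) <- object$znames
  stats::predict(object$fit, newdata = cbind(newdata, as.data.frame(Z)), ...)
}

#' @export
plot.coda_lm <- function(x, ...) {
  graphics::plot(fitted(x), residuals(x),
                 xlab = "Fitted values", ylab = "Residuals",
                 main = paste("coda_lm residuals, lead", x$lead), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Omnibus F-test for the compositional coordinates
#'
#' Tests whether the set of D-1 pivot ILR coordinates jointly improves on
#' the covariates-only model:
#' \code{F = ((RSS_r - RSS_f)/df1) / (RSS_f/df2)} with df1 the number of
#' coordinates and df2 the full model's residual df. The statistic is
#' invariant to which rotation's coordinates are used, since all rotations
#' span the same column space.
#'
#' @param object A [coda_lm()] fit.
#' @return List of class \code{coda_anova}: \code{F}, \code{df1},
#'   \code{df2}, \code{p}, plus both residual sums of squares.
#' @export
omnibus_test <- function(object) {
  stopifnot(inherits(object, "coda_lm"))
  mf <- stats::model.frame(object$fit)
  response <- names(mf)[1L]
  keep <- setdiff(names(mf), c(response, object$znames))
  f_red <- stats::reformulate(if (length(keep)) keep else "1",
                              response = response)
  fit_r <- stats::lm(f_red, data = mf)
  rss_f <- sum(stats::residuals(object$fit)^2)
  rss_r <- sum(stats::residuals(fit_r)^2)
  df1 <- fit_r$df.residual - object$fit$df.residual
  if (df1 <= 0) stop("reduced model is not a strict submodel (df1 = 0)")
  df2 <- object$fit$df.residual
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  structure(list(F = Fstat, df1 = df1, df2 = df2,
                 p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 rss_full = rss_f, rss_reduced = rss_r),
            class = "coda_anova")
}

#' @export
print.coda_anova <- function(x, ...) {
  cat(sprintf("Omnibus ILR test: F(%d, %d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Nine-rotation pivot scan
#'
#' Refits the compositional regression once per band, each time with that
#' band as the lead of the pivot basis, and extracts the first-coordinate
#' coefficient with its t-based 95\% confidence interval and p-value. All
#' rotations span one column space, so fitted values and the omnibus F are
#' identical across rotations, and the extracted coefficients sum to zero.
#'
#' @inheritParams coda_lm
#' @param level Confidence level for the per-band intervals.
#' @return Data frame of class \code{pivot_scan}: one row per band with
#'   \code{band}, \code{estimate}, \code{se}, \code{ci_lo}, \code{ci_hi},
#'   \code{p}. Attributes: \code{fits} (the D \code{coda_lm} objects),
#'   \code{omnibus} (shared F-test).
#' @export
pivot_scan <- function(formula, data, parts, total = 960, pseudo = 1 / 120,
                       level = 0.95) {
  fits <- lapply(parts, function(b) {
    coda_lm(formula, data, parts, lead = b, total = total, pseudo = pseudo)
  })
  names(fits) <- parts
  tcrit <- stats::qt(1 - (1 - level) / 2, fits[[1L]]$fit$df.residual)
  rows <- lapply(fits, function(f) {
    b <- stats::coef(f$fit)[["ilr1"]]
    se <- sqrt(stats::vcov(f$fit)["ilr1", "ilr1"])
    tval <- b / se
    data.frame(estimate = b, se = se,
               ci_lo = b - tcrit * se, ci_hi = b + tcrit * se,
               p = 2 * stats::pt(abs(tval), f$fit$df.residual,
                                 lower.tail = FALSE))
  })
  out <- cbind(data.frame(band = parts, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "omnibus") <- omnibus_test(fits[[1L]])
  attr(out, "level") <- level
  class(out) <- c("pivot_scan", "data.frame")
  out
}

#' @export
print.pivot_scan <- function(x, digits = 3, ...) {
  om <- attr(x, "omnibus")
  cat("Pivot scan: band-vs-remaining associations\n")
  if (!is.null(om)) print(om)
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pivot_scan <- function(x, ...) {
  n <- nrow(x)
  graphics::plot(seq_len(n), x$estimate, ylim = range(x$ci_lo, x$ci_hi, 0),
                 xaxt = "n", xlab = "Intensity band",
                 ylab = "First pivot coordinate coefficient",
                 pch = 19, ...)
  graphics::axis(1, at = seq_len(n), labels = x$band, las = 2,
                 cex.axis = 0.8)
  graphics::segments(seq_len(n), x$ci_lo, seq_len(n), x$ci_hi)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Sex-moderation workflow
#'
#' Fits the pooled model with sex as a covariate; if sex is significantly
#' associated with the outcome (partial F-test at \code{alpha}), reruns the
#' pivot scan separately within each sex with sex removed from the
#' covariates.
#'
#' @inheritParams coda_lm
#' @param sex_col Name of the sex column (coded "girl"/"boy").
#' @param alpha Threshold for triggering stratification.
#' @return List of class \code{sex_stratification}: \code{pooled}
#'   (pivot_scan), \code{sex_F}, \code{sex_p}, \code{stratified} (named
#'   list of per-sex pivot_scan results, or \code{NULL} when not triggered).
#' @export
stratify_by_sex <- function(formula, data, parts, sex_col = "sex",
                            alpha = 0.05, total = 960, pseudo = 1 / 120) {
  sexes <- unique(as.character(data[[sex_col]]))
  if (length(sexes) < 2L) {
    covars <- setdiff(attr(stats::terms(formula, data = data),
                           "term.labels"), sex_col)
    f0 <- stats::reformulate(if (length(covars)) covars else "1",
                             response = all.vars(formula)[1L])
    return(structure(list(pooled = pivot_scan(f0, data, parts,
                                              total = total,
                                              pseudo = pseudo),
                          sex_F = NA_real_, sex_p = NA_real_,
                          stratified = NULL),
                     class = "sex_stratification"))
  }
  pooled <- pivot_scan(formula, data, parts, total = total, pseudo = pseudo)
  full <- attr(pooled, "fits")[[1L]]
  # partial F for the sex term(s) against the full model
  mf <- stats::model.frame(full$fit)
  response <- names(mf)[1L]
  keep <- setdiff(names(mf), c(response, sex_col))
  f_nosex <- stats::reformulate(keep, response = response)
  fit_nosex <- stats::lm(f_nosex, data = mf)
  rss_f <- sum(stats::residuals(full$fit)^2)
  rss_r <- sum(stats::residuals(fit_nosex)^2)
  df1 <- fit_nosex$df.residual - full$fit$df.residual
  df2 <- full$fit$df.residual
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  sex_p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  strat <- NULL
  if (is.finite(sex_p) && sex_p < alpha) {
    covars <- setdiff(attr(stats::terms(formula, data = data),
                           "term.labels"), sex_col)
    f_strat <- stats::reformulate(if (length(covars)) covars else "1",
                                  response = all.vars(formula)[1L])
    strat <- lapply(split(data, as.character(data[[sex_col]])),
                    function(d) pivot_scan(f_strat, d, parts, total = total,
                                           pseudo = pseudo))
  }
  structure(list(pooled = pooled, sex_F = Fstat, sex_p = sex_p,
                 stratified = strat),
            class = "sex_stratification")
}

#' @export
print.sex_stratification <- function(x, ...) {
  print(x$pooled)
  if (!is.na(x$sex_p)) {
    cat(sprintf("\nSex term: F = %.2f, p = %.3g -> %s\n", x$sex_F, x$sex_p,
                if (is.null(x$stratified)) "no stratification"
                else "stratified analyses performed"))
  }
  for (nm in names(x$stratified)) {
    cat("\n---", nm, "---\n")
    print(x$stratified[[nm]])
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' \code{VIF_k = 1/(1 - R^2_k)} where \code{R^2_k} comes from regressing
#' predictor k on all other predictors (intercept excluded from scoring).
#' Perfectly collinear predictors report \code{Inf}.
#'
#' @param x A \code{coda_lm} fit, an \code{lm} fit, or a numeric design
#'   matrix of predictors (no intercept column).
#' @return Named vector of VIFs, one per predictor.
#' @export
vif <- function(x) {
  if (inherits(x, "coda_lm")) x <- x$fit
  if (inherits(x, "lm")) {
    X <- stats::model.matrix(x)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    X <- as.matrix(x)
  }
  if (ncol(X) < 2L) stop("VIF needs at least two predictors")
  vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' One-way random-effects intraclass correlation
#'
#' ANOVA estimator of the between-group share of outcome variance:
#' \code{ICC = (MSB - MSW) / (MSB + (n0 - 1) MSW)} with \code{n0} the
#' ANOVA-harmonised mean group size
#' \code{(N - sum(n_i^2)/N) / (k - 1)}. Negative estimates are truncated to
#' zero.
#'
#' @param y Outcome vector.
#' @param group Grouping factor (e.g. school id).
#' @return The ICC estimate in [0, 1).
#' @export
icc_oneway <- function(y, group) {
  group <- as.factor(group)
  sizes <- table(group)
  if (length(sizes) < 2L || length(y) - length(sizes) < 1L) {
    stop("ICC needs >= 2 groups and at least one group with >= 2 members")
  }
  fit <- stats::aov(y ~ group)
  tab <- summary(fit)[[1L]]
  msb <- tab["group", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  N <- length(y)
  k <- length(sizes)
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  max(0, (msb - msw) / (msb + (n0 - 1) * msw))
}
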