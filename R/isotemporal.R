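#' Maximum minutes reallocatable from a band
#'
#' Largest whole number of minutes that can be taken from a band while
#' leaving at least \code{floor_min} minutes in it. With the default 1-min
#' floor, a geometric mean of 11.1 min allows 10 min and 6.3 min allows
#' 5 min.
#'
#' @param comp Baseline composition (typically the sample geometric mean).
#' @param band Band index or name.
#' @param floor_min Minimum time that must remain in the band.
#' @return Whole minutes (>= 0).
#' @export
max_reallocatable <- function(comp, band, floor_min = 1) {
  j <- resolve_band(comp, band)
  max(0L, as.integer(floor(comp[[j]] - floor_min)))
}

#' Predicted outcome difference for one time reallocation
#'
#' One-for-remaining isotemporal substitution: \code{t} minutes are added to
#' one band and removed equally from the remaining bands (negative \code{t}
#' reverses the direction), and the difference in predicted outcome between
#' the reallocated and baseline compositions is computed from the fitted
#' compositional regression.
#'
#' The difference depends only on the ILR coordinate change
#' \code{d = ilr(new) - ilr(base)}: covariate terms cancel exactly, so
#' \code{delta = b_ilr . d} with standard error \code{sqrt(d' V d)} (delta
#' method on the coefficient covariance \code{V}) and a t-based confidence
#' interval at the model's residual df.
#'
#' @param model A [coda_lm()] fit.
#' @param base Baseline composition (named by band, closed to the model
#'   total).
#' @param band Band receiving \code{minutes} (name or index).
#' @param minutes Signed reallocation in minutes.
#' @param level Confidence level.
#' @return One-row data frame of class \code{substitution_result}:
#'   \code{band}, \code{minutes}, \code{delta}, \code{ci_lo}, \code{ci_hi},
#'   \code{significant}.
#' @export
predicted_difference <- function(model, base, band, minutes, level = 0.95) {
  stopifnot(inherits(model, "coda_lm"))
  base <- close_composition(base, total = model$total)
  new <- if (minutes == 0) base else reallocate(base, band, minutes)
  d <- pivot_ilr(new, model$basis) - pivot_ilr(base, model$basis)
  b <- stats::coef(model$fit)[model$znames]
  V <- stats::vcov(model$fit)[model$znames, model$znames]
  delta <- sum(b * d)
  se <- sqrt(drop(t(d) %*% V %*% d))
  tcrit <- stats::qt(1 - (1 - level) / 2, model$fit$df.residual)
  lo <- delta - tcrit * se
  hi <- delta + tcrit * se
  out <- data.frame(band = band_label(base, band), minutes = minutes,
                    delta = delta, ci_lo = lo, ci_hi = hi,
                    significant = (lo > 0 | hi < 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("substitution_result", "data.frame")
  out
}

band_label <- function(comp, band) {
  j <- resolve_band(comp, band)
  if (!is.null(names(comp))) names(comp)[j] else as.character(j)
}

#' Substitution curve over a grid of reallocations
#'
#' Evaluates [predicted_difference()] on a grid of signed reallocation
#' minutes. The negative arm is truncated at [max_reallocatable()] so that
#' no band is driven below the positivity floor.
#'
#' @inheritParams predicted_difference
#' @param t_max_plus Largest addition to the band, in minutes (default 20).
#' @param t_max_minus Largest subtraction from the band; default the maximum
#'   feasible under the floor rule.
#' @param floor_min Floor passed to [max_reallocatable()].
#' @param step Grid step in minutes.
#' @return Data frame of class \code{substitution_curve} with one
#'   [predicted_difference()] row per grid point (t = 0 excluded), plus
#'   attributes \code{base} and \code{band}. Supports \code{plot} and
#'   [write_curve_csv()].
#' @export
substitution_curve <- function(model, base, band, t_max_plus = 20,
                               t_max_minus = NULL, floor_min = 1,
                               step = 1, level = 0.95) {
  base <- close_composition(base, total = model$total)
  if (is.null(t_max_minus)) {
    t_max_minus <- max_reallocatable(base, band, floor_min = floor_min)
  }
  grid <- sort(unique(c(if (t_max_minus >= step) -seq(step, t_max_minus,
                                                      by = step),
                        if (t_max_plus >= step) seq(step, t_max_plus,
                                                    by = step))))
  rows <- lapply(grid, function(t) {
    predicted_difference(model, base, band, t, level = level)
  })
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  attr(out, "band") <- band_label(base, band)
  class(out) <- c("substitution_curve", "data.frame")
  out
}

#' @export
print.substitution_curve <- function(x, digits = 3, ...) {
  cat("One-for-remaining substitution curve, band:", attr(x, "band"), "\n")
  df <- as.data.frame(x)
  df[c("delta", "ci_lo", "ci_hi")] <-
    lapply(df[c("delta", "ci_lo", "ci_hi")], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.substitution_curve <- function(x, ...) {
  graphics::plot(x$minutes, x$delta, type = "b", pch = 19,
                 ylim = range(x$ci_lo, x$ci_hi, 0),
                 xlab = "Reallocated minutes",
                 ylab = "Predicted outcome difference",
                 main = paste("Band", attr(x, "band"),
                              "vs remaining bands"), ...)
  graphics::lines(x$minutes, x$ci_lo, col = 2)
  graphics::lines(x$minutes, x$ci_hi, col = 2)
  graphics::abline(h = 0, lty = 2)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Write a substitution curve to CSV
#'
#' Columns: band, t, delta, ci_lo, ci_hi, significant.
#'
#' @param curve A [substitution_curve()].
#' @param file Output path.
#' @export
write_curve_csv <- function(curve, file) {
  df <- as.data.frame(curve)
  names(df)[names(df) == "minutes"] <- "t"
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
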