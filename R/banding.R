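#' Euclidean norm minus one (ENMO)
#'
#' Vector magnitude of tri-axial acceleration with 1 g subtracted and
#' negative values truncated to zero, expressed in mg. The epoch-level
#' intensity metric from which the band scheme is populated.
#'
#' @param x,y,z Acceleration in g along the three axes (vectorised).
#' @return ENMO in mg, >= 0.
#' @examples
#' enmo(0, 0, 1)   # resting on gravity: 0 mg
#' enmo(0, 0, 2)   # 1000 mg
#' @export
enmo <- function(x, y, z) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop("acceleration values must be finite")
  }
  pmax(0, sqrt(x^2 + y^2 + z^2) - 1) * 1000
}

#' Band minutes from an epoch series
#'
#' Assigns each worn epoch to exactly one acceleration band (half-open
#' lower-inclusive intervals; the top band is closed below and unbounded
#' above) and converts epoch counts to minutes. Unworn epochs contribute
#' nothing; partial wear is handled downstream by closure, not imputation.
#'
#' @param enmo_mg Epoch-level ENMO values in mg.
#' @param scheme A [band_scheme()].
#' @param worn Logical/0-1 wear flag per epoch; default all worn.
#' @param epoch_s Epoch length in seconds (default 1).
#' @return Named vector of minutes per band.
#' @export
band_minutes <- function(enmo_mg, scheme = band_scheme(), worn = NULL,
                         epoch_s = 1) {
  if (any(enmo_mg < 0, na.rm = TRUE)) stop("negative ENMO value")
  if (is.null(worn)) worn <- rep(TRUE, length(enmo_mg))
  v <- enmo_mg[as.logical(worn)]
  # findInterval with left-closed bands: [edge_k, edge_{k+1})
  idx <- findInterval(v, scheme$edges)
  counts <- tabulate(idx, nbins = length(scheme$edges))
  stats::setNames(counts * epoch_s / 60, scheme$labels)
}

#' Wear-validity screening
#'
#' A day is valid iff it has at least \code{min_minutes} of wear; a
#' participant is included iff at least \code{min_days} valid days are
#' available and the post-calibration error does not exceed
#' \code{max_calib_error_mg}.
#'
#' @param worn_minutes Vector of worn minutes per day for one participant.
#' @param calib_error_mg Post-calibration error in mg.
#' @param min_minutes Valid-day threshold in min (default 600).
#' @param min_days Minimum number of valid days (default 3).
#' @param max_calib_error_mg Maximum tolerated calibration error (default 10).
#' @return List with \code{included} (logical), \code{valid_days},
#'   \code{reason} ("" when included, otherwise the failed rule(s)).
#' @export
screen_wear <- function(worn_minutes, calib_error_mg,
                        min_minutes = 600, min_days = 3,
                        max_calib_error_mg = 10) {
  if (calib_error_mg < 0) stop("calibration error must be >= 0")
  valid_days <- sum(worn_minutes >= min_minutes)
  reasons <- character(0)
  if (valid_days < min_days) reasons <- c(reasons, "insufficient valid days")
  if (calib_error_mg > max_calib_error_mg) {
    reasons <- c(reasons, "calibration error")
  }
  list(included = length(reasons) == 0L,
       valid_days = valid_days,
       reason = paste(reasons, collapse = "; "))
}

#' Average daily composition across valid days
#'
#' Component-wise arithmetic mean of per-day band minutes across valid days,
#' then closed to the standardised day length. Days with partial wear (row
#' sums below the total) are rescaled by the closure.
#'
#' @param day_minutes Matrix of band minutes, one valid day per row.
#' @param total Closure constant in minutes (default 960).
#' @return One closed composition (named as the matrix columns).
#' @export
average_composition <- function(day_minutes, total = 960) {
  if (!is.matrix(day_minutes)) {
    day_minutes <- matrix(day_minutes, nrow = 1,
                          dimnames = list(NULL, names(day_minutes)))
  }
  if (nrow(day_minutes) < 1L) stop("no valid days to average")
  close_composition(colMeans(day_minutes), total = total)
}

#' Band an epoch-level data frame into per-participant compositions
#'
#' Driver for epoch CSV input: computes per-day band minutes, screens wear
#' validity, and averages valid days into one closed composition per
#' included participant.
#'
#' @param epochs Data frame with columns \code{participant_id}, \code{day},
#'   \code{worn} (0/1) and either \code{enmo_mg} or \code{x_g,y_g,z_g}.
#' @param scheme A [band_scheme()].
#' @param calib_error Optional named vector of post-calibration errors in mg
#'   per participant (default 0 for all).
#' @param epoch_s Epoch length in seconds.
#' @param total Day length in minutes.
#' @param ... Screening thresholds passed to [screen_wear()].
#' @return List with \code{compositions} (matrix, included participants) and
#'   \code{screening} (data frame: participant_id, included, valid_days,
#'   reason).
#' @export
band_epoch_data <- function(epochs, scheme = band_scheme(),
                            calib_error = NULL, epoch_s = 1, total = 960,
                            ...) {
  need <- c("participant_id", "day", "worn")
  if (!all(need %in% names(epochs))) {
    stop("epoch data must have columns: ", paste(need, collapse = ", "))
  }
  if (!"enmo_mg" %in% names(epochs)) {
    if (!all(c("x_g", "y_g", "z_g") %in% names(epochs))) {
      stop("epoch data needs either enmo_mg or x_g, y_g, z_g columns")
    }
    epochs$enmo_mg <- enmo(epochs$x_g, epochs$y_g, epochs$z_g)
  }
  ids <- unique(epochs$participant_id)
  comp <- list()
  scr <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pid <- ids[i]
    sub <- epochs[epochs$participant_id == pid, , drop = FALSE]
    days <- split(sub, sub$day)
    dm <- t(vapply(days, function(d) {
      band_minutes(d$enmo_mg, scheme, worn = d$worn, epoch_s = epoch_s)
    }, numeric(length(scheme$labels))))
    worn_min <- vapply(days, function(d) sum(d$worn) * epoch_s / 60,
                       numeric(1))
    err <- if (!is.null(calib_error)) calib_error[[as.character(pid)]] else 0
    s <- screen_wear(worn_min, err, ...)
    scr[[i]] <- data.frame(participant_id = pid, included = s$included,
                           valid_days = s$valid_days, reason = s$reason,
                           stringsAsFactors = FALSE)
    if (s$included) {
      valid <- worn_min >= list(...)$min_minutes %||% 600
      comp[[as.character(pid)]] <-
        average_composition(dm[valid, , drop = FALSE], total = total)
    }
  }
  list(compositions = do.call(rbind, comp),
       screening = do.call(rbind, scr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
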