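#' Sequential exclusion cascade
#'
#' Removes records in a fixed order — (1) missing outcome, (2) failed wear
#' screening, (3) missing socioeconomic decile — logging the number removed
#' at each stage. Stage counts are order-dependent: a record failing several
#' rules is counted once, at the first rule it fails.
#'
#' @param records Data frame with columns \code{bmi_z}, \code{wear_ok}
#'   (logical) and \code{eimd_decile}; \code{NA} marks a missing value.
#' @return List of class \code{exclusion_cascade}: \code{data} (retained
#'   records), \code{counts} (named: missing_outcome, wear_failure,
#'   missing_ses), \code{n_input}, \code{n_retained}.
#' @export
exclusion_cascade <- function(records) {
  n0 <- nrow(records)
  m1 <- is.na(records$bmi_z)
  r1 <- records[!m1, , drop = FALSE]
  m2 <- !r1$wear_ok
  r2 <- r1[!m2, , drop = FALSE]
  m3 <- is.na(r2$eimd_decile)
  r3 <- r2[!m3, , drop = FALSE]
  counts <- c(missing_outcome = sum(m1),
              wear_failure = sum(m2),
              missing_ses = sum(m3))
  structure(list(data = r3, counts = counts,
                 n_input = n0, n_retained = nrow(r3)),
            class = "exclusion_cascade")
}

#' @export
print.exclusion_cascade <- function(x, ...) {
  cat("Exclusion cascade:", x$n_input, "records in\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  - %-16s %d removed\n", nm, x$counts[[nm]]))
  }
  cat("  =", x$n_retained, "retained\n")
  invisible(x)
}

#' Group-mean centre age
#'
#' Subtracts the group (school) mean age from each participant's age, so the
#' centred age has mean zero within every school. Used to aid model
#' interpretation and reduce collinearity with school-level covariates.
#'
#' @param records Data frame with an age column and a grouping column.
#' @param group Name of the grouping column (default \code{"school_id"}).
#' @param age Name of the age column (default \code{"age"}).
#' @return \code{records} with an added \code{age_c} column.
#' @export
center_age_by_group <- function(records, group = "school_id", age = "age") {
  if (!group %in% names(records)) stop("missing grouping column: ", group)
  if (any(is.na(records[[group]]))) stop("every record needs a group")
  mu <- stats::ave(records[[age]], records[[group]], FUN = mean)
  records$age_c <- records[[age]] - mu
  records
}

#' Descriptive cohort table
#'
#' Means (SD) of continuous fields and percentages of categorical fields,
#' overall and by sex.
#'
#' @param records Retained cohort records (data frame with a \code{sex}
#'   column coded "girl"/"boy").
#' @param continuous Names of continuous columns to summarise.
#' @param categorical Names of categorical columns to summarise.
#' @return Data frame of class \code{cohort_description}: one row per
#'   statistic, columns \code{all}, \code{boys}, \code{girls}.
#' @export
describe_cohort <- function(records,
                            continuous = intersect(c("age", "bmi_z"),
                                                   names(records)),
                            categorical = intersect(
                              c("school_type", "accel_model", "samp_freq"),
                              names(records))) {
  strata <- list(all = records,
                 boys = records[records$sex == "boy", , drop = FALSE],
                 girls = records[records$sex == "girl", , drop = FALSE])
  rows <- list()
  rows[["n"]] <- vapply(strata, nrow, numeric(1))
  for (v in continuous) {
    rows[[paste0(v, "_mean")]] <-
      vapply(strata, function(s) if (nrow(s)) mean(s[[v]], na.rm = TRUE)
             else NA_real_, numeric(1))
    rows[[paste0(v, "_sd")]] <-
      vapply(strata, function(s) if (nrow(s) > 1)
        stats::sd(s[[v]], na.rm = TRUE) else NA_real_, numeric(1))
  }
  pct_girls <- vapply(strata, function(s) if (nrow(s))
    100 * mean(s$sex == "girl") else NA_real_, numeric(1))
  rows[["pct_girls"]] <- pct_girls
  for (v in categorical) {
    lev <- sort(unique(as.character(records[[v]])))
    for (l in lev) {
      rows[[paste0(v, "_pct_", l)]] <-
        vapply(strata, function(s) if (nrow(s))
          100 * mean(as.character(s[[v]]) == l) else NA_real_, numeric(1))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- names(strata)
  class(out) <- c("cohort_description", class(out))
  out
}

#' @export
print.cohort_description <- function(x, digits = 1, ...) {
  cat("Cohort description (rows are statistics):\n")
  print.data.frame(round(as.data.frame(x), digits))
  invisible(x)
}
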