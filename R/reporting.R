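#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis on a synthetic cohort: generation,
#' exclusion cascade, descriptive tabulation, the sex-moderated nine-band
#' pivot scan, model diagnostics (VIF, school ICC), and one-for-remaining
#' substitution curves for every band-stratum pair whose band-vs-remaining
#' coefficient is significant. Deterministic per (config, seed).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   (cohort CSV, cascade JSON, scan CSVs, curve CSVs, a run manifest with
#'   checksums, and a Markdown report).
#' @param formula Covariate formula for the regression stage.
#' @param t_max_plus Largest addition in the substitution grid (minutes).
#' @param alpha Significance threshold for stratification and band
#'   follow-up.
#' @return List of class \code{codaspectrum_run} with elements
#'   \code{cohort}, \code{cascade}, \code{description}, \code{analysis}
#'   (sex_stratification), \code{diagnostics}, \code{curves},
#'   \code{baseline}, \code{seed}, \code{config}.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         out_dir = NULL,
                         formula = bmi_z ~ sex + age_c + eimd_decile +
                           accel_model + samp_freq,
                         t_max_plus = 20, alpha = 0.05) {
  parts <- config$band_labels
  cohort <- generate_cohort(config, seed = seed)
  casc <- exclusion_cascade(cohort)
  dat <- casc$data
  desc <- describe_cohort(dat)
  analysis <- stratify_by_sex(formula, dat, parts, alpha = alpha)

  fit1 <- attr(analysis$pooled, "fits")[[1L]]
  diagnostics <- list(
    vif = vif(fit1),
    icc_school = icc_oneway(dat$bmi_z, dat$school_id),
    omnibus = attr(analysis$pooled, "omnibus"))

  scans <- if (is.null(analysis$stratified)) list(pooled = analysis$pooled)
           else analysis$stratified
  strata_data <- if (is.null(analysis$stratified)) list(pooled = dat)
                 else split(dat, as.character(dat$sex))

  comp_cols <- function(d) {
    X <- as.matrix(d[, parts, drop = FALSE])
    storage.mode(X) <- "double"
    close_composition(zero_replace(X), total = config$total)
  }
  baseline <- lapply(strata_data, function(d) {
    gmean_composition(comp_cols(d), total = config$total)
  })

  curves <- list()
  for (s in names(scans)) {
    scan <- scans[[s]]
    sig <- scan$band[scan$p < alpha]
    for (b in sig) {
      fit <- attr(scan, "fits")[[b]]
      curves[[paste(s, b, sep = ":")]] <-
        substitution_curve(fit, baseline[[s]], b, t_max_plus = t_max_plus)
    }
  }

  run <- structure(list(cohort = cohort, cascade = casc,
                        description = desc, analysis = analysis,
                        diagnostics = diagnostics, curves = curves,
                        baseline = baseline, seed = seed, config = config),
                   class = "codaspectrum_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.codaspectrum_run <- function(x, ...) {
  print(x$cascade)
  cat("\n")
  print(x$analysis)
  cat(sprintf("\nSchool ICC = %.3f; VIF range %.2f-%.2f\n",
              x$diagnostics$icc_school,
              min(x$diagnostics$vif), max(x$diagnostics$vif)))
  cat("Substitution curves:", length(x$curves),
      if (length(x$curves)) paste0("(", paste(names(x$curves),
                                              collapse = ", "), ")"),
      "\n")
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, "cohort.csv")
  utils::write.csv(run$cohort, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "cascade.json")
  jsonlite::write_json(list(stages = as.list(run$cascade$counts),
                            n_input = run$cascade$n_input,
                            n_retained = run$cascade$n_retained),
                       p, auto_unbox = TRUE)
  paths <- c(paths, p)

  scans <- if (is.null(run$analysis$stratified))
    list(pooled = run$analysis$pooled) else run$analysis$stratified
  for (s in names(scans)) {
    p <- file.path(out_dir, paste0("pivot_scan_", s, ".csv"))
    utils::write.csv(as.data.frame(scans[[s]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(run$curves)) {
    p <- file.path(out_dir,
                   paste0("curve_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
    write_curve_csv(run$curves[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "baseline.json")
  jsonlite::write_json(lapply(run$baseline, function(b)
    as.list(round(b, 4))), p, auto_unbox = TRUE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "report.md")
  render_report(run, p)
  paths <- c(paths, p)

  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = run$seed,
    package_version = as.character(utils::packageVersion("codaspectrum")),
    outputs = lapply(stats::setNames(paths, basename(paths)),
                     function(f) list(md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Render a human-readable run report
#'
#' Markdown summary of a pipeline run: cascade counts, descriptive table,
#' the geometric-mean composition with percentage-of-day column,
#' the pivot-scan table(s), diagnostics, and substitution-curve anchors.
#' All rounding happens here; machine outputs keep full precision.
#'
#' @param run A [run_pipeline()] result.
#' @param file Output path (Markdown).
#' @return The path, invisibly.
#' @export
render_report <- function(run, file) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add("# Intensity-spectrum compositional analysis report")
  add("")
  add("## Exclusion cascade")
  add("")
  add("| stage | removed |")
  add("|---|---|")
  for (nm in names(run$cascade$counts)) {
    add("| ", nm, " | ", run$cascade$counts[[nm]], " |")
  }
  add("| **retained** | **", run$cascade$n_retained, "** |")
  add("")
  add("## Cohort description")
  add("")
  d <- round(as.data.frame(run$description), 1)
  add("| statistic | all | boys | girls |")
  add("|---|---|---|---|")
  for (r in rownames(d)) {
    add("| ", r, " | ", d[r, 1], " | ", d[r, 2], " | ", d[r, 3], " |")
  }
  add("")
  add("## Geometric-mean composition (min/day and % of the day)")
  add("")
  add("| band | ", paste(names(run$baseline), collapse = " | "), " |")
  add("|", strrep("---|", length(run$baseline) + 1))
  total <- run$config$total
  for (b in run$config$band_labels) {
    cells <- vapply(run$baseline, function(g) {
      sprintf("%.1f (%.1f%%)", g[[b]], 100 * g[[b]] / total)
    }, character(1))
    add("| ", b, " | ", paste(cells, collapse = " | "), " |")
  }
  add("")
  add("## Band-vs-remaining associations")
  om <- run$diagnostics$omnibus
  add("")
  add(sprintf("Omnibus ILR test: F(%d, %d) = %.1f, p = %.3g.",
              om$df1, om$df2, om$F, om$p))
  if (!is.na(run$analysis$sex_p)) {
    add(sprintf("Sex term p = %.3g (%s).", run$analysis$sex_p,
                if (is.null(run$analysis$stratified))
                  "no stratification" else "stratified"))
  }
  scans <- if (is.null(run$analysis$stratified))
    list(pooled = run$analysis$pooled) else run$analysis$stratified
  for (s in names(scans)) {
    add("")
    add("### ", s)
    add("")
    add("| band | beta_ilr1 | 95% CI | p |")
    add("|---|---|---|---|")
    sc <- scans[[s]]
    for (i in seq_len(nrow(sc))) {
      add(sprintf("| %s | %.2f | %.2f, %.2f | %.3g |", sc$band[i],
                  sc$estimate[i], sc$ci_lo[i], sc$ci_hi[i], sc$p[i]))
    }
  }
  add("")
  add("## Diagnostics")
  add("")
  add(sprintf("- VIF range: %.2f to %.2f",
              min(run$diagnostics$vif), max(run$diagnostics$vif)))
  add(sprintf("- School ICC: %.3f", run$diagnostics$icc_school))
  add("")
  add("## Substitution curves")
  add("")
  if (!length(run$curves)) {
    add("No band reached the follow-up threshold; no curves computed.")
  } else {
    for (nm in names(run$curves)) {
      cv <- run$curves[[nm]]
      lo_t <- min(cv$minutes); hi_t <- max(cv$minutes)
      at <- function(t) cv[cv$minutes == t, ]
      a <- at(hi_t); b <- at(lo_t)
      add(sprintf(paste0("- %s: at +%d min delta = %.2f (%.2f, %.2f); ",
                         "at %d min delta = %.2f (%.2f, %.2f)"),
                  nm, hi_t, a$delta, a$ci_lo, a$ci_hi,
                  lo_t, b$delta, b$ci_lo, b$ci_hi))
    }
  }
  writeLines(ln, file)
  invisible(file)
}
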