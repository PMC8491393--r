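# Full outcome-analysis report for a scored cohort, mirroring the trial's
# analysis set, with JSON export.

#' Run the full outcome analysis on a scored cohort
#'
#' Composes the stratified disease-control contingency analyses, ROC cutoff
#' selection, Kaplan-Meier/log-rank survival comparisons, univariate +
#' multivariate regression models for all three endpoints, the grade-trend
#' correlation, the feasibility summary, and the TP53->VEGFi sensitivity
#' analysis.
#'
#' @param x An `ms_scored` object.
#' @param stratification Primary stratification for contingency/survival
#'   blocks (default `"ge60"`).
#' @return An `ms_analysis` list with components `dcr`, `dcr_three`,
#'   `dcr_gt50`, `roc`, `pfs`, `os`, `models` (list of `ms_fit` by
#'   endpoint), `grade_trend`, `feasibility`, `sensitivity_tp53`, and a
#'   `parameters` header.
#' @export
analyze_cohort <- function(x, stratification = "ge60") {
  stopifnot(inherits(x, "ms_scored"))
  tbl <- scored_table(x)
  ev <- dplyr::filter(tbl, .data$disease_control != "not_evaluable")
  structure(list(
    parameters = list(
      stratification = stratification,
      kb_version = attr(x, "kb_version"),
      dedupe_reports = attr(x, "dedupe_reports"),
      n_treated = nrow(tbl), n_evaluable_dcr = nrow(ev)
    ),
    dcr = dcr_contingency(tbl, stratification),
    dcr_three = dcr_contingency(tbl, "three"),
    dcr_gt50 = dcr_contingency(tbl, "gt50"),
    roc = roc_cutoff(ev$score, ev$disease_control),
    pfs = km_by_stratum(tbl, "pfs", stratification),
    os = km_by_stratum(tbl, "os", stratification),
    models = list(
      dcr = fit_models(tbl, "dcr"),
      pfs = fit_models(tbl, "pfs"),
      os = fit_models(tbl, "os")
    ),
    grade_trend = tryCatch(grade_trend(tbl), error = function(e) NULL),
    feasibility = feasibility_summary(x),
    sensitivity_tp53 = sensitivity_exclude_tp53(x, stratification)
  ), class = "ms_analysis")
}

#' @export
print.ms_analysis <- function(x, ...) {
  cat("== Disease control ==\n"); print(x$dcr)
  cat("== ROC ==\n"); print(x$roc)
  cat("== PFS ==\n"); print(as.data.frame(x$pfs$by_stratum))
  cat(sprintf("   log-rank p = %.4g\n", x$pfs$logrank$p))
  cat("== OS ==\n"); print(as.data.frame(x$os$by_stratum))
  cat(sprintf("   log-rank p = %.4g\n", x$os$logrank$p))
  for (ep in names(x$models)) print(x$models[[ep]])
  if (!is.null(x$grade_trend)) {
    cat("== Grade trend ==\n")
    print(as.data.frame(x$grade_trend))
  }
  cat("== Sensitivity (TP53->VEGFi removed):", x$sensitivity_tp53$n_excluded,
      "patients excluded ==\n")
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serialises the tidy content of every analysis block (contingency tables,
#' ROC curve, KM medians, model estimates, trend, feasibility, sensitivity)
#' plus the parameter header.
#'
#' @param x An `ms_analysis` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_json <- function(x, path) {
  stopifnot(inherits(x, "ms_analysis"))
  km_block <- function(km) list(
    by_stratum = km$by_stratum,
    logrank = dplyr::select(km$logrank, -"n")
  )
  doc <- list(
    parameters = x$parameters,
    dcr = list(by_stratum = tidy(x$dcr), summary = glance(x$dcr)),
    dcr_three = list(by_stratum = tidy(x$dcr_three), summary = glance(x$dcr_three)),
    dcr_gt50 = list(by_stratum = tidy(x$dcr_gt50), summary = glance(x$dcr_gt50)),
    roc = glance(x$roc),
    pfs = km_block(x$pfs),
    os = km_block(x$os),
    models = purrr::map(x$models, tidy),
    grade_trend = if (!is.null(x$grade_trend)) as.data.frame(x$grade_trend),
    feasibility = x$feasibility,
    sensitivity_tp53 = list(
      excluded_ids = x$sensitivity_tp53$excluded_ids,
      n_excluded = x$sensitivity_tp53$n_excluded,
      dcr = glance(x$sensitivity_tp53$dcr),
      pfs = km_block(x$sensitivity_tp53$pfs),
      os = km_block(x$sensitivity_tp53$os)
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
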