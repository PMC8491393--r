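# Disease-control classification, stratified contingency analysis, and
# ROC-based score cutoff selection.

#' Classify disease control
#'
#' Disease control = stable disease lasting >= 6 months, or partial/complete
#' response. SD that is still ongoing at < 6 months, `too_early`, and
#' `not_evaluable` rows are not evaluable for the disease-control rate.
#'
#' @param best_response Character vector of RECIST best-response categories
#'   (`CR`, `PR`, `SD`, `PD`, `not_evaluable`, `too_early`).
#' @param sd_duration_months SD duration in months (required where
#'   `best_response == "SD"`).
#' @param sd_ongoing Is the SD still ongoing (on treatment without
#'   progression)?
#' @return Character vector: `"dc_yes"`, `"dc_no"` or `"not_evaluable"`.
#' @export
classify_disease_control <- function(best_response, sd_duration_months = NA,
                                     sd_ongoing = FALSE) {
  n <- length(best_response)
  sd_duration_months <- rep_len(sd_duration_months, n)
  sd_ongoing <- dplyr::coalesce(rep_len(sd_ongoing, n), FALSE)
  is_sd <- !is.na(best_response) & best_response == "SD"
  if (any(is_sd & is.na(sd_duration_months))) {
    abort("SD rows require sd_duration_months")
  }
  dplyr::case_when(
    is.na(best_response) ~ "not_evaluable",
    best_response %in% c("CR", "PR") ~ "dc_yes",
    is_sd & sd_duration_months >= 6 ~ "dc_yes",
    is_sd & sd_ongoing ~ "not_evaluable",
    is_sd ~ "dc_no",
    best_response == "PD" ~ "dc_no",
    TRUE ~ "not_evaluable"
  )
}

# Coerce an ms_scored object or flat data frame to the analysis table:
# requires `score` (stratifications recomputed if absent) and
# `disease_control` (classified from outcome columns if absent).
as_scored_tbl <- function(x) {
  if (inherits(x, "ms_scored")) return(scored_table(x))
  x <- tibble::as_tibble(x)
  if (!"score" %in% names(x)) abort("need a `score` column or an ms_scored object")
  need_grade <- setdiff(c("stratum", "stratum50", "fine_grade"), names(x))
  if (length(need_grade) > 0) {
    x <- dplyr::bind_cols(
      dplyr::select(x, -dplyr::any_of(c("stratum", "stratum50", "fine_grade"))),
      dplyr::select(assign_grade(x$score), -"score")
    )
  }
  if (!"disease_control" %in% names(x) && "best_response" %in% names(x)) {
    x$disease_control <- classify_disease_control(
      x$best_response,
      x$sd_duration_months %||% NA,
      x$sd_ongoing %||% FALSE
    )
  }
  x
}

strat_column <- function(tbl, stratification) {
  switch(stratification,
    ge60 = factor(dplyr::if_else(tbl$stratum == "ge60", ">=60", "<60"),
                  levels = c(">=60", "<60")),
    three = factor(tbl$stratum, levels = c("ge60", "s1_59", "unmatched")),
    gt50 = factor(tbl$stratum50, levels = c("gt50", "le50")),
    matched = factor(dplyr::if_else(tbl$score > 0, "matched", "unmatched"),
                     levels = c("matched", "unmatched")),
    fine = factor(tbl$fine_grade, levels = rev(FINE_GRADES))
  )
}

#' Stratified disease-control contingency analysis
#'
#' Restricts to evaluable patients, cross-tabulates disease control against
#' the chosen score stratification, and computes the two-sided Fisher exact
#' p-value (sum of table probabilities no larger than the observed table's).
#' A binary logistic-regression Wald p-value is reported alongside, since
#' the two conventions appear interchangeably in trial reports; the Fisher
#' value is the reference.
#'
#' @param x An `ms_scored` object or a data frame with `score` plus either
#'   `disease_control` or outcome columns.
#' @param stratification `"ge60"` (score >= 60 vs < 60, default), `"three"`
#'   (>= 60 / 1-59 / unmatched), `"gt50"`, `"matched"`, or `"fine"` (five
#'   grades).
#' @return An `ms_contingency` object: `table` (strata x {dc_yes, dc_no}),
#'   `by_stratum` tibble with counts and rates, `p_fisher`, `p_logistic`,
#'   `stratification`, `n_evaluable`. [tidy()] returns the per-stratum
#'   tibble; [glance()] the one-row summary.
#' @export
dcr_contingency <- function(x, stratification = c("ge60", "three", "gt50",
                                                  "matched", "fine")) {
  stratification <- match.arg(stratification)
  tbl <- as_scored_tbl(x)
  if (!"disease_control" %in% names(tbl)) {
    abort("no disease_control column and no outcome columns to derive it from")
  }
  tbl$group <- strat_column(tbl, stratification)
  ev <- dplyr::filter(tbl, .data$disease_control != "not_evaluable",
                      !is.na(.data$group))
  counts <- table(ev$group, factor(ev$disease_control,
                                   levels = c("dc_yes", "dc_no")))
  if (any(rowSums(counts) == 0)) {
    abort(paste0("empty stratum: ",
                 paste(rownames(counts)[rowSums(counts) == 0], collapse = ", ")))
  }
  by_stratum <- tibble::tibble(
    stratum = rownames(counts),
    n = as.integer(rowSums(counts)),
    dc = as.integer(counts[, "dc_yes"]),
    rate = as.numeric(counts[, "dc_yes"] / rowSums(counts))
  )
  p_fisher <- fisher.test(counts)$p.value
  p_logistic <- tryCatch({
    fit <- glm((disease_control == "dc_yes") ~ group, binomial, data = ev)
    z <- coef(summary(fit))[-1, "Pr(>|z|)"]
    min(z)
  }, error = function(e) NA_real_)
  structure(
    list(table = unclass(counts), by_stratum = by_stratum,
         p_fisher = p_fisher, p_logistic = p_logistic,
         stratification = stratification, n_evaluable = nrow(ev)),
    class = "ms_contingency"
  )
}

#' @export
print.ms_contingency <- function(x, ...) {
  cat("<DCR contingency>", x$stratification, "stratification,",
      x$n_evaluable, "evaluable\n")
  for (i in seq_len(nrow(x$by_stratum))) {
    with(x$by_stratum[i, ],
         cat(sprintf("  %-10s %d/%d = %.0f%%\n", stratum, dc, n, 100 * rate)))
  }
  cat(sprintf("  Fisher exact p = %.4g (logistic Wald p = %.4g)\n",
              x$p_fisher, x$p_logistic))
  invisible(x)
}

#' @rdname dcr_contingency
#' @param ... Unused.
#' @export
tidy.ms_contingency <- function(x, ...) x$by_stratum

#' @rdname dcr_contingency
#' @export
glance.ms_contingency <- function(x, ...) {
  tibble::tibble(stratification = x$stratification,
                 n_evaluable = x$n_evaluable,
                 p_fisher = x$p_fisher, p_logistic = x$p_logistic)
}

#' ROC analysis and score-cutoff selection for disease control
#'
#' AUC uses the rank (Mann-Whitney) definition with midranks for ties.
#' Candidate cutoffs are the observed score values; a score >= cutoff is
#' called positive. The default selected cutoff maximizes Youden's J
#' (sensitivity + specificity - 1), ties broken toward the higher cutoff;
#' the cutoff maximizing the disease-control rate difference between the
#' >= cutoff and < cutoff groups is reported as an alternative, and the full
#' per-cutoff table is returned for audit.
#'
#' @param score Numeric score vector.
#' @param dc Disease-control indicator: logical, 0/1, or
#'   `"dc_yes"`/`"dc_no"` (not-evaluable entries dropped).
#' @return An `ms_roc` object: `auc`, `cutoff` (Youden), `cutoff_rate_diff`,
#'   `curve` (per-cutoff sensitivity, specificity, J, DC rates and their
#'   difference), `n_pos`, `n_neg`.
#' @export
roc_cutoff <- function(score, dc) {
  if (is.character(dc)) {
    keep <- dc %in% c("dc_yes", "dc_no")
    score <- score[keep]
    dc <- dc[keep] == "dc_yes"
  }
  dc <- as.logical(dc)
  keep <- !is.na(score) & !is.na(dc)
  score <- score[keep]; dc <- dc[keep]
  n1 <- sum(dc); n0 <- sum(!dc)
  if (n1 == 0 || n0 == 0) abort("both outcome classes must be present")
  r <- rank(score)                       # midranks
  auc <- (sum(r[dc]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cutoffs <- sort(unique(score))
  curve <- purrr::map_dfr(cutoffs, function(cut) {
    pos <- score >= cut
    tibble::tibble(
      cutoff = cut,
      sensitivity = sum(pos & dc) / n1,
      specificity = sum(!pos & !dc) / n0,
      rate_ge = if (any(pos)) mean(dc[pos]) else NA_real_,
      rate_lt = if (any(!pos)) mean(dc[!pos]) else NA_real_
    )
  }) |>
    dplyr::mutate(
      youden_j = .data$sensitivity + .data$specificity - 1,
      rate_diff = .data$rate_ge - dplyr::coalesce(.data$rate_lt, 0)
    )
  pick_highest <- function(stat) {
    ok <- which(!is.na(stat) & stat == max(stat, na.rm = TRUE))
    curve$cutoff[max(ok)]                # ties broken toward the higher cutoff
  }
  structure(
    list(auc = auc, cutoff = pick_highest(curve$youden_j),
         cutoff_rate_diff = pick_highest(curve$rate_diff),
         curve = curve, n_pos = n1, n_neg = n0),
    class = "ms_roc"
  )
}

#' @export
print.ms_roc <- function(x, ...) {
  cat(sprintf("<ROC> AUC = %.3f (%d events / %d non-events)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff: score >= %g; max rate-difference cutoff: >= %g\n",
              x$cutoff, x$cutoff_rate_diff))
  invisible(x)
}

#' @rdname roc_cutoff
#' @param x An `ms_roc` object.
#' @param ... Unused.
#' @export
tidy.ms_roc <- function(x, ...) x$curve

#' @rdname roc_cutoff
#' @export
glance.ms_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff,
                 cutoff_rate_diff = x$cutoff_rate_diff,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Feasibility summary of a scored cohort
#'
#' Counts and proportions (with exact binomial confidence intervals) for the
#' feasibility endpoints: patients treated among enrolled, patients with at
#' least one matched drug (score > 0) among treated, and per-bin score
#' counts.
#'
#' @param x An `ms_scored` object or flat data frame with a `score` column.
#' @param conf_level Confidence level for the exact binomial intervals.
#' @return A list with `summary` (one row per proportion: n, total,
#'   proportion, conf.low, conf.high) and `bins` (per fine-grade counts).
#' @export
feasibility_summary <- function(x, conf_level = 0.95) {
  tbl <- as_scored_tbl(x)
  n_enrolled <- if (inherits(x, "ms_scored")) nrow(x$cohort$patients) else nrow(tbl)
  prop_row <- function(label, k, total) {
    ci <- binom.test(k, total, conf.level = conf_level)$conf.int
    tibble::tibble(measure = label, n = k, total = total,
                   proportion = k / total,
                   conf.low = ci[1], conf.high = ci[2])
  }
  summary <- dplyr::bind_rows(
    prop_row("treated_of_enrolled", nrow(tbl), n_enrolled),
    prop_row("matched_of_treated", sum(tbl$score > 0), nrow(tbl))
  )
  bins <- tbl |>
    dplyr::count(.data$fine_grade, name = "n") |>
    tidyr::complete(fine_grade = factor(FINE_GRADES, levels = FINE_GRADES,
                                        ordered = TRUE),
                    fill = list(n = 0L))
  list(summary = summary, bins = bins)
}
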