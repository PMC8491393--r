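# Kaplan-Meier estimation, log-rank comparison, and the TP53->VEGFi
# sensitivity analysis.

#' Kaplan-Meier curve and median for one stratum
#'
#' Product-limit estimator; the median is the earliest time at which the
#' survival curve drops to 0.5 or below, and "not reached" (`NA` with
#' `reached = FALSE`) when the curve never does.
#'
#' @param time Nonnegative times in months.
#' @param event Event indicator (TRUE = progression/death observed; FALSE =
#'   censored).
#' @return A list with `curve` (tibble: `time`, `n_risk`, `n_event`,
#'   `surv`), `median` (months or `NA`), and `reached` (logical).
#' @export
km_median <- function(time, event) {
  if (length(time) == 0) abort("empty stratum")
  if (any(is.na(time)) || any(time < 0)) abort("times must be nonnegative")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  curve <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv
  )
  med <- unname(summary(fit)$table["median"])
  list(curve = curve, median = med, reached = !is.na(med))
}

#' Log-rank comparison of survival across strata
#'
#' @param time,event As in [km_median()].
#' @param group Stratum labels.
#' @return A tibble with `chisq`, `df`, `p`, and per-group `n`.
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) abort("need >= 2 nonempty strata")
  if (sum(event) == 0) abort("no events in any stratum")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- length(sd$n) - 1
  tibble::tibble(
    chisq = sd$chisq, df = df,
    p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
    n = list(as.integer(sd$n))
  )
}

#' Kaplan-Meier medians and log-rank test by score stratum
#'
#' Convenience wrapper running [km_median()] per stratum and [logrank()]
#' across strata for one survival endpoint of a scored cohort.
#'
#' @param x An `ms_scored` object or flat data frame (see
#'   [dcr_contingency()]).
#' @param endpoint `"pfs"` or `"os"`.
#' @param stratification As in [dcr_contingency()].
#' @return A list with `by_stratum` (tibble: stratum, n, events, median,
#'   reached), `logrank` (tibble), `curves` (named list of per-stratum
#'   curves).
#' @export
km_by_stratum <- function(x, endpoint = c("pfs", "os"),
                          stratification = c("ge60", "three", "gt50",
                                             "matched", "fine")) {
  endpoint <- match.arg(endpoint)
  stratification <- match.arg(stratification)
  tbl <- as_scored_tbl(x)
  time <- tbl[[paste0(endpoint, "_months")]]
  event <- tbl[[paste0(endpoint, "_event")]]
  tbl$group <- strat_column(tbl, stratification)
  keep <- !is.na(time) & !is.na(event) & !is.na(tbl$group)
  tbl <- tbl[keep, ]; time <- time[keep]; event <- event[keep]
  groups <- levels(droplevels(tbl$group))
  fits <- purrr::map(setNames(groups, groups), function(g) {
    sel <- tbl$group == g
    km_median(time[sel], event[sel])
  })
  by_stratum <- purrr::imap_dfr(fits, function(f, g) {
    sel <- tbl$group == g
    tibble::tibble(stratum = g, n = sum(sel), events = sum(event[sel]),
                   median = f$median, reached = f$reached)
  })
  list(
    by_stratum = by_stratum,
    logrank = logrank(time, event, tbl$group),
    curves = purrr::map(fits, "curve")
  )
}

#' Sensitivity analysis: drop patients matched only through TP53->VEGFi
#'
#' Identifies patients with at least one countable unit whose match
#' provenance is solely the `tp53_vegf` rule (the audit tags a unit
#' `tp53_vegf` only when no drug matches it directly), removes them, and
#' re-runs the disease-control contingency and survival analyses on the
#' remaining subcohort.
#'
#' @param x An `ms_scored` object (the audit breakdown is required).
#' @param stratification As in [dcr_contingency()].
#' @return A list with `excluded_ids`, `n_excluded`, `dcr`
#'   (`ms_contingency`), `pfs` and `os` (each as returned by
#'   [km_by_stratum()]).
#' @export
sensitivity_exclude_tp53 <- function(x, stratification = "ge60") {
  stopifnot(inherits(x, "ms_scored"))
  excluded <- x$audit |>
    dplyr::filter(.data$rule == "tp53_vegf") |>
    dplyr::pull(.data$patient_id) |>
    unique()
  sub <- dplyr::filter(scored_table(x), !.data$patient_id %in% excluded)
  list(
    excluded_ids = excluded,
    n_excluded = length(excluded),
    dcr = dcr_contingency(sub, stratification),
    pfs = km_by_stratum(sub, "pfs", stratification),
    os = km_by_stratum(sub, "os", stratification)
  )
}
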