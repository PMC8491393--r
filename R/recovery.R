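# Parameter-recovery harness: simulate -> score with the real engine ->
# refit, and summarise bias, RMSE, CI coverage and rejection rates against
# the truths implied by the simulation parameters.

#' Parameter recovery across simulated cohorts
#'
#' For each replicate: simulates a cohort from `params` (replicate r uses
#' `seed + r`), scores it with the real Matching Score engine against the
#' seed knowledge base, and re-estimates the disease-control log odds ratio
#' (logistic regression, high vs low score stratum), the PFS and OS log
#' hazard ratios (Cox, Efron ties), the Fisher exact p for disease control
#' and the log-rank p for OS. Truths are implied by `params`: the log-OR
#' from the two disease-control probabilities and log-HRs from the
#' exponential medians (HR = median_low / median_high). Failed fits are
#' counted, not fatal.
#'
#' @param params An [sim_params()] object.
#' @param n_replicates Number of simulated cohorts (>= 2; >= 100 for stable
#'   coverage estimates).
#' @param seed Base integer seed.
#' @param conf_level Wald confidence level whose coverage is assessed.
#' @return An `ms_recovery` object: `summary` (one row per estimand:
#'   truth, mean estimate, bias, relative bias, RMSE, CI coverage, Wald
#'   rejection rate), `tests` (Fisher and log-rank rejection rates),
#'   `n_replicates`, `n_failed`, and the per-replicate `draws`.
#' @export
recover_parameters <- function(params = sim_params(), n_replicates = 200,
                               seed = 1, conf_level = 0.95) {
  stopifnot(n_replicates >= 2)
  kb <- kb_seed()
  truth <- c(
    log_or_dcr = unname(qlogis(params$dc_prob["high"]) -
                          qlogis(params$dc_prob["low"])),
    log_hr_pfs = unname(log(params$pfs_median["low"] / params$pfs_median["high"])),
    log_hr_os = unname(log(params$os_median["low"] / params$os_median["high"]))
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  draws <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    sim <- simulate_cohort(params, seed = seed + r, kb = kb)
    tbl <- scored_table(score_cohort(sim$cohort, kb))
    tbl$high <- tbl$stratum == "ge60"
    out <- tibble::tibble(replicate = r)
    ev <- dplyr::filter(tbl, .data$disease_control != "not_evaluable")
    fit <- tryCatch({
      g <- glm((disease_control == "dc_yes") ~ high, binomial, data = ev)
      cf <- coef(summary(g))["highTRUE", ]
      if (abs(cf["Estimate"]) > 10 || cf["Std. Error"] > 10) abort("separation")
      cf
    }, error = function(e) NULL)
    out$est_log_or_dcr <- if (is.null(fit)) NA_real_ else unname(fit["Estimate"])
    out$se_log_or_dcr <- if (is.null(fit)) NA_real_ else unname(fit["Std. Error"])
    for (ep in c("pfs", "os")) {
      fit <- tryCatch({
        cx <- survival::coxph(
          survival::Surv(tbl[[paste0(ep, "_months")]],
                         tbl[[paste0(ep, "_event")]]) ~ high,
          data = tbl, ties = "efron"
        )
        c(coef(cx)[1], sqrt(vcov(cx)[1, 1]))
      }, error = function(e) c(NA_real_, NA_real_))
      # truth HR is high vs low; the coefficient is for high = TRUE
      out[[paste0("est_log_hr_", ep)]] <- unname(fit[1])
      out[[paste0("se_log_hr_", ep)]] <- unname(fit[2])
    }
    out$p_fisher <- tryCatch(
      fisher.test(table(ev$high, ev$disease_control))$p.value,
      error = function(e) NA_real_
    )
    out$p_logrank <- tryCatch(
      logrank(tbl$os_months, tbl$os_event, tbl$high)$p,
      error = function(e) NA_real_
    )
    out
  })
  summarise_est <- function(name) {
    est <- draws[[paste0("est_", name)]]
    se <- draws[[paste0("se_", name)]]
    ok <- is.finite(est) & is.finite(se)
    tr <- truth[[name]]
    tibble::tibble(
      estimand = name, truth = tr, n_ok = sum(ok),
      mean_estimate = mean(est[ok]),
      bias = mean(est[ok]) - tr,
      rel_bias = if (tr != 0) (mean(est[ok]) - tr) / abs(tr) else NA_real_,
      rmse = sqrt(mean((est[ok] - tr)^2)),
      se_mean = stats::sd(est[ok]) / sqrt(sum(ok)),
      coverage = mean(est[ok] - z * se[ok] <= tr & tr <= est[ok] + z * se[ok]),
      wald_rejection = mean(abs(est[ok] / se[ok]) > z)
    )
  }
  summary <- dplyr::bind_rows(
    summarise_est("log_or_dcr"),
    summarise_est("log_hr_pfs"),
    summarise_est("log_hr_os")
  )
  tests <- tibble::tibble(
    test = c("fisher_dcr", "logrank_os"),
    rejection_rate = c(mean(draws$p_fisher <= 0.05, na.rm = TRUE),
                       mean(draws$p_logrank <= 0.05, na.rm = TRUE))
  )
  structure(
    list(summary = summary, tests = tests,
         n_replicates = as.integer(n_replicates),
         n_failed = sum(!complete.cases(
           draws[, c("est_log_or_dcr", "est_log_hr_pfs", "est_log_hr_os")])),
         draws = draws, truth = truth),
    class = "ms_recovery"
  )
}

#' @export
print.ms_recovery <- function(x, ...) {
  cat("<parameter recovery>", x$n_replicates, "replicates (",
      x$n_failed, "with failed fits )\n")
  print(as.data.frame(dplyr::mutate(x$summary, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, 3)))))
  print(as.data.frame(x$tests))
  invisible(x)
}

#' @rdname recover_parameters
#' @param x An `ms_recovery` object.
#' @param ... Unused.
#' @export
tidy.ms_recovery <- function(x, ...) x$summary

#' @rdname recover_parameters
#' @export
glance.ms_recovery <- function(x, ...) {
  tibble::tibble(n_replicates = x$n_replicates, n_failed = x$n_failed,
                 fisher_rejection = x$tests$rejection_rate[1],
                 logrank_rejection = x$tests$rejection_rate[2])
}
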