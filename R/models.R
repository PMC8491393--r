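# Logistic / Cox modeling with the univariate P < 0.15 entry rule, and the
# grade-trend correlation.

#' Candidate covariate set for the trial's regression models
#'
#' Named list of functions mapping the flat analysis table to logical
#' covariates; the default candidate set of [fit_models()]. Supply a
#' modified list to add or drop candidates.
#'
#' @return Named list of functions.
#' @export
default_covariates <- function() {
  list(
    high_score = function(d) d$stratum == "ge60",
    matched = function(d) d$score > 0,
    age_ge63 = function(d) d$age >= 63,
    male = function(d) d$sex == "male",
    multi_drug = function(d) d$n_drugs >= 2,
    gi_hpb = function(d) d$tumor_type %in%
      c("gi_noncolorectal", "colorectal", "appendiceal", "hepatobiliary",
        "pancreatic"),
    cup = function(d) d$tumor_type == "cup",
    breast = function(d) d$tumor_type == "breast"
  )
}

wald_row <- function(est, se, exponentiate = TRUE, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  tf <- if (exponentiate) exp else identity
  tibble::tibble(
    estimate = tf(est), conf.low = tf(est - z * se),
    conf.high = tf(est + z * se),
    p.value = 2 * pnorm(-abs(est / se))
  )
}

fit_one <- function(data, endpoint, terms, conf_level = 0.95) {
  # returns one row per model term: exp(coef) with Wald CI and p
  if (endpoint == "dcr") {
    data$.y <- data$disease_control == "dc_yes"
    data <- dplyr::filter(data, .data$disease_control != "not_evaluable")
    fml <- stats::reformulate(terms, ".y")
    fit <- glm(fml, binomial, data = data)
    cf <- coef(summary(fit))[-1, , drop = FALSE]
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  } else {
    fml <- stats::reformulate(
      terms, sprintf("survival::Surv(%s_months, %s_event)", endpoint, endpoint)
    )
    fit <- survival::coxph(fml, data = data, ties = "efron")
    cf <- coef(summary(fit))
    est <- cf[, "coef"]; se <- cf[, "se(coef)"]
  }
  if (nrow(cf) < length(terms)) {
    abort("degenerate covariate (zero variance or collinear)")
  }
  if (any(!is.finite(est)) || any(!is.finite(se)) || any(se > 50)) {
    abort("unstable fit (separation or non-convergence)")
  }
  dplyr::bind_cols(
    tibble::tibble(term = sub("TRUE$", "", rownames(cf))),
    wald_row(est, se, conf_level = conf_level)
  )
}

#' Univariate screening and multivariate modeling of an endpoint
#'
#' Fits one univariate model per candidate covariate (logistic regression
#' for disease control; Cox proportional hazards with the Efron tie
#' correction for PFS/OS), then enters every covariate with univariate
#' p < `entry_p` (default 0.15) into a single multivariate model. Odds or
#' hazard ratios are reported with Wald 95% confidence intervals. A
#' covariate whose univariate fit fails (separation, non-convergence, zero
#' variance) is recorded with an `error` note and skipped, not fatal to the
#' batch.
#'
#' @param x An `ms_scored` object or flat data frame with `score`, outcome
#'   columns, and any covariate inputs (`age`, `sex`, `n_drugs`,
#'   `tumor_type`).
#' @param endpoint `"dcr"`, `"pfs"` or `"os"`.
#' @param covariates Named list of functions mapping the analysis table to a
#'   logical/numeric covariate column; defaults to the trial's candidate
#'   set (high Matching Score, matched vs unmatched, age >= 63, sex,
#'   >= 2 drugs, GI/hepatobiliary-pancreatic cancer, unknown primary,
#'   breast cancer).
#' @param entry_p Univariate p-value threshold for multivariate entry.
#' @return An `ms_fit` object with `univariate` and `multivariate` tibbles
#'   (term, estimate = OR/HR, conf.low, conf.high, p.value, and for the
#'   univariate table `entered`), plus `endpoint`, `entered`, `n`. [tidy()]
#'   stacks both tables with a `model` column; [glance()] summarises.
#' @export
fit_models <- function(x, endpoint = c("dcr", "pfs", "os"),
                       covariates = default_covariates(), entry_p = 0.15) {
  endpoint <- match.arg(endpoint)
  tbl <- as_scored_tbl(x)
  if (endpoint == "dcr" && !"disease_control" %in% names(tbl)) {
    abort("disease-control classification unavailable")
  }
  usable <- purrr::imap(covariates, function(f, nm) {
    tryCatch(f(tbl), error = function(e) NULL)
  })
  usable <- purrr::compact(usable)
  data <- tbl
  for (nm in names(usable)) data[[nm]] <- usable[[nm]]

  uni <- purrr::imap_dfr(usable, function(col, nm) {
    res <- tryCatch(fit_one(data, endpoint, nm), error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(term = nm, estimate = NA_real_, conf.low = NA_real_,
                     conf.high = NA_real_, p.value = NA_real_,
                     error = conditionMessage(res))
    } else {
      dplyr::mutate(res, term = nm, error = NA_character_)
    }
  })
  entered <- uni$term[!is.na(uni$p.value) & uni$p.value < entry_p]
  multi <- if (length(entered) > 0) {
    res <- tryCatch(fit_one(data, endpoint, entered), error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(term = entered, estimate = NA_real_, conf.low = NA_real_,
                     conf.high = NA_real_, p.value = NA_real_,
                     error = conditionMessage(res))
    } else {
      dplyr::mutate(res, error = NA_character_)
    }
  } else {
    tibble::tibble(term = character(), estimate = numeric(),
                   conf.low = numeric(), conf.high = numeric(),
                   p.value = numeric(), error = character())
  }
  structure(
    list(endpoint = endpoint,
         univariate = dplyr::mutate(uni, entered = .data$term %in% entered),
         multivariate = multi,
         entered = entered,
         n = nrow(data)),
    class = "ms_fit"
  )
}

#' @export
print.ms_fit <- function(x, ...) {
  lab <- if (x$endpoint == "dcr") "OR" else "HR"
  cat("<", toupper(x$endpoint), " models> n = ", x$n,
      "; entered into multivariate: ",
      if (length(x$entered) > 0) paste(x$entered, collapse = ", ") else "none",
      "\n", sep = "")
  if (nrow(x$multivariate) > 0) {
    for (i in seq_len(nrow(x$multivariate))) {
      with(x$multivariate[i, ], cat(sprintf(
        "  %-12s %s %.2f (%.2f-%.2f), p = %.3g\n",
        term, lab, estimate, conf.low, conf.high, p.value)))
    }
  }
  invisible(x)
}

#' @rdname fit_models
#' @param ... Unused.
#' @export
tidy.ms_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(x$univariate, -"entered"), model = "univariate"),
    dplyr::mutate(x$multivariate, model = "multivariate")
  )
}

#' @rdname fit_models
#' @export
glance.ms_fit <- function(x, ...) {
  tibble::tibble(endpoint = x$endpoint, n = x$n,
                 n_entered = length(x$entered),
                 entered = paste(x$entered, collapse = ","))
}

#' Linear trend of outcomes across fine score grades
#'
#' Per populated fine grade, computes the disease-control rate and the
#' Kaplan-Meier median PFS, then the Pearson correlation of each against
#' the grade's x-encoding (ordinal index 0-4 by default, or the bin
#' midpoint). Reports R and R-squared; a zero-variance outcome yields an
#' undefined correlation, reported as `NA`. Grades whose KM median is not
#' reached are dropped from the PFS correlation.
#'
#' @param x An `ms_scored` object or flat data frame.
#' @param x_encoding `"ordinal"` (0-4) or `"midpoint"` (0, 20, 50, 79.5,
#'   100).
#' @return A tibble with one row per metric (`dcr`, `pfs_median`): `r`,
#'   `r_squared`, `p.value`, `n_grades`, plus the per-grade values in
#'   `by_grade`.
#' @export
grade_trend <- function(x, x_encoding = c("ordinal", "midpoint")) {
  x_encoding <- match.arg(x_encoding)
  tbl <- as_scored_tbl(x)
  xs <- setNames(
    if (x_encoding == "ordinal") 0:4 else c(0, 20, 49.5, 79.5, 100),
    FINE_GRADES
  )
  by_grade <- purrr::map_dfr(FINE_GRADES, function(g) {
    d <- dplyr::filter(tbl, .data$fine_grade == g)
    if (nrow(d) == 0) return(NULL)
    dcr <- if ("disease_control" %in% names(d)) {
      ev <- d$disease_control[d$disease_control != "not_evaluable"]
      if (length(ev) > 0) mean(ev == "dc_yes") else NA_real_
    } else NA_real_
    pfs <- if ("pfs_months" %in% names(d)) {
      km_median(d$pfs_months, d$pfs_event)$median
    } else NA_real_
    tibble::tibble(fine_grade = g, grade_x = xs[[g]], n = nrow(d),
                   dc_rate = dcr, pfs_median = pfs)
  })
  if (nrow(by_grade) < 3) abort("need >= 3 populated grades")
  trend_row <- function(y, metric) {
    ok <- !is.na(y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(metric = metric, r = NA_real_,
                            r_squared = NA_real_, p.value = NA_real_,
                            n_grades = sum(ok)))
    }
    ct <- stats::cor.test(by_grade$grade_x[ok], y[ok])
    tibble::tibble(metric = metric, r = unname(ct$estimate),
                   r_squared = unname(ct$estimate)^2, p.value = ct$p.value,
                   n_grades = sum(ok))
  }
  out <- dplyr::bind_rows(
    trend_row(by_grade$dc_rate, "dcr"),
    trend_row(by_grade$pfs_median, "pfs_median")
  )
  attr(out, "by_grade") <- by_grade
  attr(out, "x_encoding") <- x_encoding
  out
}
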