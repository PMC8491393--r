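kb <- kb_seed()

sim_tbl <- function(seed, n = 76, ...) {
  sim <- simulate_cohort(sim_params(n_patients = n, ...), seed = seed, kb = kb)
  scored_table(score_cohort(sim$cohort, kb))
}

test_that("multivariate covariate set equals the univariate p < 0.15 set", {
  tbl <- sim_tbl(21)
  for (ep in c("dcr", "os")) {
    fit <- fit_models(tbl, ep)
    uni <- fit$univariate
    expect_setequal(fit$entered,
                    uni$term[!is.na(uni$p.value) & uni$p.value < 0.15])
    expect_setequal(fit$multivariate$term, fit$entered)
    expect_identical(sort(uni$term[uni$entered]), sort(fit$entered))
  }
})

test_that("a null covariate estimates OR/HR near 1 and is not entered", {
  # pool several simulated cohorts; sex is independent of outcome by design
  tbl <- dplyr::bind_rows(purrr::map(22:25, sim_tbl))
  fit <- fit_models(tbl, "dcr")
  male <- dplyr::filter(fit$univariate, term == "male")
  expect_lt(abs(log(male$estimate)), 0.5)
  fit_os <- fit_models(tbl, "os")
  male_os <- dplyr::filter(fit_os$univariate, term == "male")
  expect_lt(abs(log(male_os$estimate)), 0.4)
})

test_that("a true high-score effect is recovered within its Wald CI", {
  tbl <- sim_tbl(26, n = 500,
                 dc_prob = c(high = 0.586, low = 0.30),
                 os_median = c(high = 27.62, low = 11.6),
                 frac_inevaluable = 0)
  fit <- fit_models(tbl, "dcr")
  hs <- dplyr::filter(fit$univariate, term == "high_score")
  expect_true(hs$conf.low < 3.31 && 3.31 < hs$conf.high)
  fit_os <- fit_models(tbl, "os")
  hs_os <- dplyr::filter(fit_os$univariate, term == "high_score")
  expect_true(hs_os$conf.low < 0.42 && 0.42 < hs_os$conf.high)
  # estimates are odds/hazard ratios with CIs containing the point estimate
  expect_true(all(fit$univariate$conf.low <= fit$univariate$estimate,
                  na.rm = TRUE))
  expect_true(all(fit$univariate$estimate <= fit$univariate$conf.high,
                  na.rm = TRUE))
})

test_that("degenerate covariates are reported per term, not fatal", {
  tbl <- sim_tbl(27)
  covs <- c(default_covariates()[c("high_score", "male")],
            list(constant = function(d) rep(TRUE, nrow(d))))
  fit <- fit_models(tbl, "dcr", covariates = covs)
  const <- dplyr::filter(fit$univariate, term == "constant")
  expect_false(is.na(const$error))
  expect_false("constant" %in% fit$entered)
  expect_true("high_score" %in% fit$univariate$term)
})

test_that("tidy/glance expose both model stages", {
  fit <- fit_models(sim_tbl(28), "pfs")
  td <- tidy(fit)
  expect_setequal(unique(td$model), c("univariate", "multivariate"))
  g <- glance(fit)
  expect_identical(g$endpoint, "pfs")
  expect_identical(g$n_entered, length(fit$entered))
})

test_that("grade trend is exactly 1 for a linear response and NA when flat", {
  lin <- tibble::tibble(
    score = rep(c(0, 20, 50, 80, 100), each = 20),
    disease_control = unlist(purrr::map(c(2, 6, 10, 14, 18),
      ~ rep(c("dc_yes", "dc_no"), c(.x, 20 - .x))))
  )
  tr <- grade_trend(lin)
  expect_equal(dplyr::filter(tr, metric == "dcr")$r_squared, 1)

  flat <- dplyr::mutate(lin,
    disease_control = rep(rep(c("dc_yes", "dc_no"), c(10, 10)), 5))
  tr2 <- grade_trend(flat)
  expect_true(is.na(dplyr::filter(tr2, metric == "dcr")$r_squared))

  expect_error(grade_trend(dplyr::filter(lin, score %in% c(0, 100))),
               "3 populated grades")
})

test_that("a generated linear grade -> DCR map yields a strong trend", {
  tbl <- sim_tbl(29, n = 500,
                 dc_prob_by_grade = c(g0 = 0.1, g1_39 = 0.25, g40_59 = 0.4,
                                      g60_99 = 0.55, g100 = 0.7),
                 frac_inevaluable = 0)
  tr <- grade_trend(tbl)
  expect_gt(dplyr::filter(tr, metric == "dcr")$r_squared, 0.9)
})

test_that("full analysis report assembles and serialises to JSON", {
  sim <- simulate_cohort(sim_params(), seed = 31, kb = kb)
  an <- analyze_cohort(score_cohort(sim$cohort, kb))
  expect_s3_class(an, "ms_analysis")
  expect_identical(an$parameters$n_treated, 76L)
  expect_s3_class(an$models$os, "ms_fit")
  path <- withr::local_tempfile(fileext = ".json")
  write_analysis_json(an, path)
  parsed <- jsonlite::fromJSON(path)
  expect_true(all(c("parameters", "dcr", "roc", "pfs", "os", "models",
                    "feasibility", "sensitivity_tp53") %in% names(parsed)))
  expect_equal(parsed$dcr$summary$p_fisher, an$dcr$p_fisher)
})
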