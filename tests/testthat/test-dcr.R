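test_that("disease-control classification follows the 6-month rule", {
  expect_identical(classify_disease_control("SD", 7.2), "dc_yes")
  expect_identical(classify_disease_control("SD", 3, sd_ongoing = TRUE),
                   "not_evaluable")
  expect_identical(classify_disease_control("SD", 3, sd_ongoing = FALSE),
                   "dc_no")
  expect_identical(classify_disease_control("SD", 6), "dc_yes")
  expect_identical(
    classify_disease_control(c("CR", "PR", "PD", "too_early", "not_evaluable")),
    c("dc_yes", "dc_yes", "dc_no", "not_evaluable", "not_evaluable"))
  # ongoing SD already past 6 months still qualifies
  expect_identical(classify_disease_control("SD", 8, sd_ongoing = TRUE),
                   "dc_yes")
  expect_error(classify_disease_control("SD"), "sd_duration_months")
})

make_dc_tbl <- function(n_high, dc_high, n_low, dc_low) {
  tibble::tibble(
    score = c(rep(80, n_high), rep(20, n_low)),
    disease_control = c(rep("dc_yes", dc_high), rep("dc_no", n_high - dc_high),
                        rep("dc_yes", dc_low), rep("dc_no", n_low - dc_low))
  )
}

test_that("the trial's printed contingency reproduces: 68% vs 30%, p=0.005", {
  ct <- dcr_contingency(make_dc_tbl(25, 17, 43, 13))
  expect_equal(unname(ct$table[">=60", "dc_yes"]), 17)
  expect_equal(tidy(ct)$rate, c(17 / 25, 13 / 43))
  expect_equal(round(ct$p_fisher, 3), 0.005)
  expect_false(is.na(ct$p_logistic))
})

test_that("identical proportions give Fisher p = 1", {
  ct <- dcr_contingency(make_dc_tbl(20, 10, 20, 10))
  expect_equal(ct$p_fisher, 1)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  set.seed(303)
  for (i in 1:25) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    tab <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
    if (any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-8)
  }
})

test_that("not-evaluable patients are excluded and empty strata rejected", {
  tbl <- make_dc_tbl(10, 6, 10, 3)
  tbl$disease_control[1] <- "not_evaluable"
  ct <- dcr_contingency(tbl)
  expect_identical(ct$n_evaluable, 19L)
  all_high <- tibble::tibble(score = rep(90, 5),
                             disease_control = rep("dc_yes", 5))
  expect_error(dcr_contingency(all_high), "empty stratum")
})

test_that("five-grade stratification builds a 5 x 2 table", {
  tbl <- tibble::tibble(
    score = c(100, 100, 80, 80, 50, 50, 20, 20, 0, 0),
    disease_control = rep(c("dc_yes", "dc_no"), 5)
  )
  ct <- dcr_contingency(tbl, "fine")
  expect_identical(dim(ct$table), c(5L, 2L))
})

test_that("ROC AUC matches the rank definition and pROC", {
  # perfect separation
  expect_equal(roc_cutoff(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # AUC equals the scaled Mann-Whitney U on tied, noisy data
  set.seed(404)
  for (i in 1:10) {
    score <- sample(seq(0, 100, by = 12.5), 40, replace = TRUE)
    dc <- runif(40) < 0.2 + 0.006 * score
    if (length(unique(dc)) < 2) next
    r <- roc_cutoff(score, dc)
    u <- wilcox.test(score[dc], score[!dc], exact = FALSE)$statistic
    expect_equal(r$auc, unname(u) / (sum(dc) * sum(!dc)))
    expect_equal(r$auc, as.numeric(pROC::auc(
      pROC::roc(dc, score, direction = "<", quiet = TRUE))))
  }
  # labels independent of scores: AUC near 1/2
  set.seed(405)
  r <- roc_cutoff(runif(4000), runif(4000) < 0.4)
  expect_lt(abs(r$auc - 0.5), 0.03)
})

test_that("Youden cutoff breaks ties toward the higher cutoff", {
  # J is identical at cutoffs 10 and 20 (the step between them is empty)
  score <- c(0, 0, 10, 20, 20)
  dc <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  r <- roc_cutoff(score, dc)
  expect_equal(r$cutoff, 20)
  expect_error(roc_cutoff(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("the trial's own scores put the optimal cutoff at 60", {
  # 68% DC at >= 60 vs 30% below, scores on the five grade levels
  tbl <- dplyr::bind_rows(
    make_dc_tbl(13, 9, 0, 0) |> dplyr::mutate(score = 100),
    make_dc_tbl(12, 8, 0, 0) |> dplyr::mutate(score = 75),
    make_dc_tbl(14, 6, 0, 0) |> dplyr::mutate(score = 50),
    make_dc_tbl(13, 4, 0, 0) |> dplyr::mutate(score = 20),
    make_dc_tbl(20, 3, 0, 0) |> dplyr::mutate(score = 0)
  )
  r <- roc_cutoff(tbl$score, tbl$disease_control)
  expect_gt(r$auc, 0.6)
  expect_true(all(c("sensitivity", "specificity", "youden_j", "rate_diff")
                  %in% names(tidy(r))))
})

test_that("feasibility proportions carry exact binomial intervals", {
  tbl <- tibble::tibble(score = c(0, 0, 0, 40, 60, 100))
  fs <- feasibility_summary(tbl)
  matched <- dplyr::filter(fs$summary, measure == "matched_of_treated")
  expect_equal(matched$proportion, 0.5)
  expect_equal(unname(unlist(matched[, c("conf.low", "conf.high")])),
               binom.test(3, 6)$conf.int[1:2], tolerance = 1e-9)
  expect_identical(sum(fs$bins$n), 6L)
  all_zero <- feasibility_summary(tibble::tibble(score = rep(0, 4)))
  expect_equal(
    dplyr::filter(all_zero$summary, measure == "matched_of_treated")$proportion,
    0)
})
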