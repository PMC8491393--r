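kb <- kb_seed()

test_that("same-gene collapse follows the counting rules", {
  # two same-gene point mutations with the same impact count once
  two_kras <- alterations(c("KRAS", "KRAS"))
  expect_identical(nrow(collapse_alterations(two_kras)), 1L)
  expect_identical(collapse_alterations(two_kras)$n_collapsed, 2L)
  # structurally distinct events in one gene count twice
  egfr <- alterations(c("EGFR", "EGFR"),
                      alteration_class = c("amplification", "mutation"))
  expect_identical(nrow(collapse_alterations(egfr)), 2L)
  # different annotated impact groups stay separate
  braf <- alterations(c("BRAF", "BRAF"),
                      impact_group = c("activating", "kinase_dead"))
  expect_identical(nrow(collapse_alterations(braf)), 2L)
  # reports are counted independently by default, collapsible on request
  dup <- alterations(c("KRAS", "KRAS"), report_id = c("tissue", "blood"))
  expect_identical(nrow(collapse_alterations(dup)), 2L)
  expect_identical(nrow(collapse_alterations(dup, dedupe_reports = TRUE)), 1L)
  # empty input and VUS-only input give empty output
  expect_identical(nrow(collapse_alterations(alterations(character()))), 0L)
  expect_identical(
    nrow(collapse_alterations(alterations("KRAS", pathogenicity = "vus"))), 0L)
})

test_that("genomic fraction reproduces the worked counting examples", {
  six <- alterations(c("BRAF", "ERBB2", "EGFR", "APC", "SMAD4", "MYC"))
  gf <- genomic_fraction(six, biomarker_profile(),
                         c("dabrafenib", "erlotinib", "trastuzumab"), kb)
  expect_identical(c(gf$numerator, gf$denominator), c(3L, 6L))
  expect_equal(gf$x, 0.5)

  # synergy pair on the sole alteration: counted twice on both sides
  gf <- genomic_fraction(alterations("BRAF"), biomarker_profile(),
                         c("dabrafenib", "trametinib"), kb)
  expect_identical(c(gf$numerator, gf$denominator), c(2L, 2L))
  expect_equal(gf$x, 1)

  # hormone rule adds one matched unit to both sides
  gf <- genomic_fraction(alterations(c("APC", "SMAD4", "MYC", "RB1")),
                         biomarker_profile(er_positive = TRUE),
                         "letrozole", kb)
  expect_identical(c(gf$numerator, gf$denominator), c(1L, 5L))
  expect_equal(gf$x, 0.2)
  expect_error(
    genomic_fraction(six, biomarker_profile(), "phantomib", kb),
    "unknown drug"
  )
})

test_that("io component follows biomarkers and requires checkpoint blockade", {
  ici <- c("pembrolizumab", "gemcitabine")
  expect_identical(
    immunotherapy_component(biomarker_profile(msi_status = "msi_high"), ici, kb),
    "full")
  expect_identical(
    immunotherapy_component(biomarker_profile(tmb_category = "high"), ici, kb),
    "full")
  expect_identical(
    immunotherapy_component(biomarker_profile(pdl1_category = "high_positive"),
                            ici, kb), "full")
  expect_identical(
    immunotherapy_component(biomarker_profile(tmb_category = "intermediate"),
                            ici, kb), "half")
  expect_identical(
    immunotherapy_component(biomarker_profile(pdl1_category = "low_positive"),
                            ici, kb), "half")
  # full outranks half when both apply
  expect_identical(
    immunotherapy_component(biomarker_profile(msi_status = "msi_high",
                                              tmb_category = "intermediate"),
                            ici, kb), "full")
  # no checkpoint inhibitor administered -> no component
  expect_identical(
    immunotherapy_component(biomarker_profile(tmb_category = "high"),
                            "gemcitabine", kb), "none")
  expect_identical(immunotherapy_component(biomarker_profile(), ici, kb), "none")
})

test_that("matching score combines components per the worked examples", {
  # TMB-intermediate + checkpoint blockade + FGFR inhibitor on
  # {PIK3CA, FGFR}: 50% + 25% = 75%
  ms <- matching_score(alterations(c("PIK3CA", "FGFR2")),
                       biomarker_profile(tmb_category = "intermediate"),
                       c("pembrolizumab", "erdafitinib"), kb)
  expect_equal(ms$score, 75)
  expect_identical(ms$io_component, "half")
  expect_equal(ms$genomic_fraction, 0.5)

  # no matched drug, no qualifying biomarker
  ms <- matching_score(alterations(c("APC", "SMAD4")), biomarker_profile(),
                       "gemcitabine", kb)
  expect_equal(ms$score, 0)

  # full io component scores 100 regardless of untargeted alterations (cap)
  ms <- matching_score(alterations(paste0("GENE", 1:10)),
                       biomarker_profile(msi_status = "msi_high"),
                       "pembrolizumab", kb)
  expect_equal(ms$score, 100)
  expect_error(matching_score(alterations("BRAF"), biomarker_profile(),
                              character(), kb), "nonempty")
})

test_that("breakdown accessors expose the audit trail", {
  ms <- matching_score(alterations(c("BRAF", "APC")), biomarker_profile(),
                       c("dabrafenib", "trametinib"), kb)
  units <- tidy(ms)
  expect_identical(nrow(units), 2L)
  expect_identical(units$weight[units$gene == "BRAF"], 2L)
  expect_identical(units$rule[units$gene == "BRAF"], "direct_target")
  g <- glance(ms)
  expect_identical(g$numerator, 2L)
  expect_identical(g$denominator, 3L)
  expect_equal(g$score, 100 * 2 / 3)
})

test_that("grade boundaries are honoured in all three stratifications", {
  g <- assign_grade(c(60, 0, 75, 50, 50.5, 100, 39.9, 40, 59.9, 99.9, 1))
  expect_identical(g$stratum,
                   c("ge60", "unmatched", "ge60", "s1_59", "s1_59", "ge60",
                     "s1_59", "s1_59", "s1_59", "ge60", "s1_59"))
  expect_identical(g$stratum50,
                   c("gt50", "le50", "gt50", "le50", "gt50", "gt50", "le50",
                     "le50", "gt50", "gt50", "le50"))
  expect_identical(as.character(g$fine_grade),
                   c("g60_99", "g0", "g60_99", "g40_59", "g40_59", "g100",
                     "g1_39", "g40_59", "g40_59", "g60_99", "g1_39"))
  expect_error(assign_grade(-1), "0, 100")
  expect_error(assign_grade(101), "0, 100")
})

test_that("score properties hold over random patients", {
  set.seed(101)
  for (i in 1:60) {
    p <- random_patient(kb)
    ms <- matching_score(p$alt, p$bm, p$drugs, kb)
    # bounds and the io cap
    expect_gte(ms$score, 0)
    expect_lte(ms$score, 100)
    if (ms$io_component == "full") expect_equal(ms$score, 100)

    # adding a drug never decreases the score
    extra <- sample(setdiff(kb$drugs$name, p$drugs), 1)
    ms2 <- matching_score(p$alt, p$bm, c(p$drugs, extra), kb)
    expect_gte(ms2$score + 1e-9, ms$score)

    # adding an untargeted characterized alteration never increases it
    diluted <- dplyr::bind_rows(p$alt, alterations("NOVELGENE1"))
    ms3 <- matching_score(diluted, p$bm, p$drugs, kb)
    expect_lte(ms3$score - 1e-9, ms$score)

    # VUS are inert
    with_vus <- dplyr::bind_rows(p$alt,
      alterations(c("BRAF", "TP53", "NOVELGENE2"), pathogenicity = "vus"))
    ms4 <- matching_score(with_vus, p$bm, p$drugs, kb)
    expect_equal(ms4$score, ms$score)
  }
})

test_that("engine agrees with the literal rule-by-rule oracle", {
  set.seed(202)
  for (i in 1:80) {
    p <- random_patient(kb, max_units = 6, max_drugs = 4)
    ms <- matching_score(p$alt, p$bm, p$drugs, kb)
    oc <- oracle_score(p$alt, p$bm, p$drugs, kb)
    expect_identical(as.integer(ms$numerator), as.integer(oc$numerator))
    expect_identical(as.integer(ms$denominator), as.integer(oc$denominator))
    expect_identical(ms$io_component, oc$io)
    expect_equal(ms$score, oc$score)
  }
})
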