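test_that("bundled seed rules file loads and matches the built-in seed", {
  path <- system.file("extdata", "kb_seed.json", package = "oncomatch")
  kb <- kb_load(path)
  seed <- kb_seed()
  expect_s3_class(kb, "ms_kb")
  expect_setequal(kb$drugs$name, seed$drugs$name)
  for (d in c("dabrafenib", "trametinib", "trastuzumab", "pertuzumab",
              "letrozole", "erdafitinib", "carboplatin", "olaparib",
              "bevacizumab", "pembrolizumab")) {
    expect_true(d %in% kb$drugs$name, label = d)
  }
  i <- match(seed$drugs$name, kb$drugs$name)
  expect_true(all(purrr::map2_lgl(kb$drugs$targets[i], seed$drugs$targets,
                                  setequal)))
  expect_identical(kb$version, seed$version)
})

test_that("load -> write -> load round-trips losslessly", {
  tmp <- withr::local_tempfile(fileext = ".json")
  kb1 <- kb_load(system.file("extdata", "kb_seed.json", package = "oncomatch"))
  kb_write(kb1, tmp)
  kb2 <- kb_load(tmp)
  expect_equal(kb2$drugs, kb1$drugs)
  expect_equal(kb2$synergy_pairs, kb1$synergy_pairs)
  expect_equal(kb2$special_rules, kb1$special_rules)
  expect_identical(kb2$version, kb1$version)
})

test_that("validation rejects broken knowledge bases, naming the record", {
  seed <- kb_seed()
  bad <- seed
  bad$synergy_pairs$drug_a[1] <- "phantomib"
  expect_error(kb_validate(bad), "phantomib")

  expect_error(
    knowledge_base(dplyr::bind_rows(seed$drugs, seed$drugs[1, ])),
    "duplicate drug name.*dabrafenib"
  )
  expect_error(
    knowledge_base(tibble::tibble(name = "x", drug_class = "potion",
                                  targets = list("GENE1"))),
    "unknown drug_class"
  )
  expect_error(
    knowledge_base(tibble::tibble(name = "x", drug_class = "small_molecule",
                                  targets = list(character()))),
    "nonempty target"
  )
  missing_rule <- seed
  missing_rule$special_rules <- seed$special_rules[1, ]
  expect_error(kb_validate(missing_rule), "tp53_vegf")
  # shared target must belong to both drugs of a synergy pair
  bad2 <- seed
  bad2$synergy_pairs$shared_target[1] <- "EGFR"
  expect_error(kb_validate(bad2), "not a target")
})

test_that("missing rules file errors", {
  expect_error(kb_load("no/such/rules.json"), "not found")
})

test_that("drug-alteration verdicts carry a single correct provenance tag", {
  kb <- kb_seed()
  v <- drug_matches_alteration(kb, "dabrafenib", "BRAF")
  expect_true(v$matched)
  expect_identical(v$rule, "direct_target")

  v <- drug_matches_alteration(kb, "carboplatin", "BRCA1")
  expect_true(v$matched)
  expect_identical(v$rule, "brca_platinum_parp")

  v <- drug_matches_alteration(kb, "bevacizumab", "TP53")
  expect_true(v$matched)
  expect_identical(v$rule, "tp53_vegf")

  # gene symbols compared case-insensitively after trimming
  expect_true(drug_matches_alteration(kb, "dabrafenib", " braf ")$matched)
  expect_false(drug_matches_alteration(kb, "gemcitabine", "BRAF")$matched)
  expect_error(drug_matches_alteration(kb, "phantomib", "BRAF"), "unknown drug")
  # determinism
  expect_identical(drug_matches_alteration(kb, "pazopanib", "TP53"),
                   drug_matches_alteration(kb, "pazopanib", "TP53"))
})

test_that("disabling tp53_vegf changes verdicts only for TP53 triggers", {
  kb_on <- kb_seed()
  kb_off <- kb_set_rule(kb_on, "tp53_vegf", FALSE)
  genes <- c("TP53", "BRAF", "BRCA1", "EGFR", "APC", "VEGFA")
  grid <- tidyr::expand_grid(drug = kb_on$drugs$name, gene = genes)
  v_on <- purrr::map2_dfr(grid$drug, grid$gene,
                          ~ drug_matches_alteration(kb_on, .x, .y))
  v_off <- purrr::map2_dfr(grid$drug, grid$gene,
                           ~ drug_matches_alteration(kb_off, .x, .y))
  changed <- v_on$matched != v_off$matched
  expect_true(any(changed))
  expect_true(all(v_on$gene[changed] == "TP53"))
  expect_true(all(v_on$rule[changed] == "tp53_vegf"))
  expect_false(drug_matches_alteration(kb_off, "bevacizumab", "TP53")$matched)
})

test_that("hormone rule needs both a positive receptor and a modulator", {
  kb <- kb_seed()
  er_pos <- biomarker_profile(er_positive = TRUE)
  expect_true(hormone_match(kb, er_pos, c("letrozole", "gemcitabine")))
  expect_true(hormone_match(kb, biomarker_profile(ar_positive = TRUE),
                            "enzalutamide"))
  expect_false(hormone_match(kb, er_pos, c("dabrafenib", "gemcitabine")))
  expect_false(hormone_match(kb, biomarker_profile(er_positive = FALSE),
                             "letrozole"))
  expect_false(hormone_match(kb, biomarker_profile(), "letrozole"))
})

test_that("drug-target export is one row per pair", {
  kb <- kb_seed()
  tab <- kb_export_targets(kb)
  expect_identical(nrow(tab), sum(purrr::map_int(kb$drugs$targets, length)))
  expect_true(all(c("drug", "drug_class", "target") %in% names(tab)))
})
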