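# Independent oracles, written against the counting rules directly in base
# R, deliberately sharing no code with the package internals.

# Literal rule-by-rule Matching Score: collapse within report by
# (gene, impact, class); a unit is matched if some administered drug hits
# its gene directly or an enabled special rule fires; synergy pairs double
# a matched shared-target unit on both sides; hormone IHC adds 1/1; io
# component full/half per biomarker; score = 100, 50 + X/2*100, or 100X,
# capped at 100.
oracle_score <- function(alt, bm, drugs, kb) {
  alt <- alt[alt$pathogenicity == "characterized", , drop = FALSE]
  if (is.null(alt$impact_group)) alt$impact_group <- NA
  imp <- ifelse(is.na(alt$impact_group), alt$alteration_class, alt$impact_group)
  keys <- unique(paste(alt$report_id, toupper(trimws(alt$gene)), imp,
                       alt$alteration_class, sep = "|"))
  genes <- vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 2)

  kb_idx <- match(drugs, kb$drugs$name)
  tsets <- kb$drugs$targets[kb_idx]
  classes <- kb$drugs$drug_class[kb_idx]
  sr <- kb$special_rules[kb$special_rules$enabled, , drop = FALSE]
  unit_matched <- vapply(genes, function(g) {
    direct <- any(vapply(tsets, function(t) g %in% t, TRUE))
    if (direct) return(TRUE)
    for (i in seq_len(nrow(sr))) {
      if (!g %in% sr$trigger_genes[[i]]) next
      sat <- any(classes %in% sr$satisfying_classes[[i]]) ||
        any(vapply(tsets, function(t)
          length(intersect(t, sr$satisfying_targets[[i]])) > 0, TRUE))
      if (sat) return(TRUE)
    }
    FALSE
  }, TRUE)
  weights <- rep(1, length(genes))
  for (i in seq_len(nrow(kb$synergy_pairs))) {
    sp <- kb$synergy_pairs[i, ]
    if (sp$drug_a %in% drugs && sp$drug_b %in% drugs) {
      hit <- unit_matched & genes == sp$shared_target
      weights[hit] <- 2
    }
  }
  num <- sum(weights[unit_matched]); den <- sum(weights)
  horm <- (isTRUE(bm$er_positive) || isTRUE(bm$ar_positive)) &&
    any(classes == "hormone_modulator")
  if (horm) { num <- num + 1; den <- den + 1 }
  x <- if (den == 0) 0 else num / den
  has_ici <- any(classes == "checkpoint_inhibitor")
  io <- if (!has_ici) "none"
  else if (bm$msi_status == "msi_high" || bm$tmb_category == "high" ||
           bm$pdl1_category == "high_positive") "full"
  else if (bm$tmb_category == "intermediate" ||
           bm$pdl1_category == "low_positive") "half"
  else "none"
  score <- switch(io, full = 100, half = 50 + 100 * x / 2, none = 100 * x)
  list(numerator = num, denominator = den, x = x, io = io,
       score = min(100, score))
}

# Two-sided Fisher exact p by exhaustive enumeration over all 2x2 tables
# with the observed margins: sum of hypergeometric probabilities <= the
# observed table's.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1))
  }, 0)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact power of the two-sided Fisher test for a two-arm binomial design,
# by enumeration over all (x, y) outcome pairs.
oracle_fisher_power <- function(n1, n2, p1, p2, alpha = 0.05) {
  total <- 0
  for (x in 0:n1) {
    px <- dbinom(x, n1, p1)
    for (y in 0:n2) {
      p <- oracle_fisher_p(matrix(c(x, n1 - x, y, n2 - y), 2, byrow = TRUE))
      if (p <= alpha) total <- total + px * dbinom(y, n2, p2)
    }
  }
  total
}

# random small patient for property tests: up to max_units distinct-gene
# characterized alterations drawn from the seed gene universe, up to
# max_drugs drugs from the seed base
random_patient <- function(kb, max_units = 6, max_drugs = 4) {
  gene_pool <- unique(c(unlist(kb$drugs$targets), "APC", "SMAD4", "MYC",
                        "TP53", "BRCA1", "RB1"))
  n <- sample(0:max_units, 1)
  alt <- alterations(
    gene = if (n > 0) sample(gene_pool, n) else character(),
    alteration_class = if (n > 0)
      sample(c("mutation", "amplification"), n, replace = TRUE) else character()
  )
  nd <- sample(1:max_drugs, 1)
  bm <- biomarker_profile(
    tmb_category = sample(c("low", "intermediate", "high", "unknown"), 1),
    msi_status = sample(c("stable", "msi_high"), 1, prob = c(0.85, 0.15)),
    er_positive = sample(c(NA, TRUE, FALSE), 1)
  )
  list(alt = alt, bm = bm, drugs = sample(kb$drugs$name, nd))
}

demo_cohort_dir <- function() {
  system.file("extdata", "demo_cohort", package = "oncomatch")
}
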