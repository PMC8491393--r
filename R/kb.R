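# Drug-target knowledge base: curated drug records, synergy pairs, and the
# special match rules (BRCA-related genes -> platinum/PARP inhibitor,
# TP53 -> VEGF-pathway inhibitor) that decide whether a drug is "matched"
# to an alteration.

DRUG_CLASSES <- c(
  "small_molecule", "antibody", "checkpoint_inhibitor", "platinum_chemo",
  "parp_inhibitor", "hormone_modulator", "cytotoxic_other"
)

SPECIAL_RULE_IDS <- c("brca_platinum_parp", "tp53_vegf")

norm_gene <- function(x) toupper(trimws(as.character(x)))

#' Construct a knowledge base from its component tables
#'
#' A knowledge base holds the curated drug-target map used by the Matching
#' Score engine. Drug-target sets encode curated potency (preclinical IC50
#' for the target, or its immediate downstream effector, generally < 100 nM);
#' potency itself is never computed here. Gene identifiers are HGNC-style
#' symbols, compared case-insensitively after trimming.
#'
#' @param drugs Tibble with columns `name`, `drug_class` (one of
#'   `r paste(DRUG_CLASSES, collapse = ", ")`), `targets` (list column of
#'   character vectors of gene symbols), and optionally `notes`.
#' @param synergy_pairs Tibble with columns `drug_a`, `drug_b`,
#'   `shared_target`: established synergistic two-drug combinations
#'   co-targeting one aberration (counted twice in numerator and denominator).
#' @param special_rules Tibble with columns `rule_id`, `trigger_genes` (list
#'   column), `satisfying_classes` (list column of drug classes),
#'   `satisfying_targets` (list column of gene symbols), `enabled` (logical).
#'   Both built-in rules must be present; either can be disabled, e.g. for
#'   the TP53 sensitivity analysis.
#' @param version Free-text version string recorded in provenance metadata.
#'
#' @return A validated object of class `ms_kb`.
#' @seealso [kb_seed()], [kb_load()], [drug_matches_alteration()]
#' @export
knowledge_base <- function(drugs, synergy_pairs = NULL, special_rules = NULL,
                           version = "unversioned") {
  drugs <- tibble::as_tibble(drugs)
  if (!"notes" %in% names(drugs)) drugs$notes <- ""
  if (is.null(synergy_pairs)) {
    synergy_pairs <- tibble::tibble(
      drug_a = character(), drug_b = character(), shared_target = character()
    )
  }
  if (is.null(special_rules)) special_rules <- default_special_rules()
  kb <- structure(
    list(
      drugs = dplyr::mutate(drugs,
        targets = purrr::map(.data$targets, norm_gene)
      ),
      synergy_pairs = tibble::as_tibble(synergy_pairs) |>
        dplyr::mutate(shared_target = norm_gene(.data$shared_target)),
      special_rules = tibble::as_tibble(special_rules) |>
        dplyr::mutate(trigger_genes = purrr::map(.data$trigger_genes, norm_gene),
                      satisfying_targets = purrr::map(.data$satisfying_targets, norm_gene)),
      version = as.character(version)
    ),
    class = "ms_kb"
  )
  kb_validate(kb)
  kb
}

default_special_rules <- function() {
  tibble::tibble(
    rule_id = SPECIAL_RULE_IDS,
    trigger_genes = list(
      c("BRCA1", "BRCA2", "ATM", "PALB2", "BARD1", "CHEK2"),
      "TP53"
    ),
    satisfying_classes = list(c("platinum_chemo", "parp_inhibitor"), character()),
    satisfying_targets = list(character(), c("VEGFA", "KDR", "FLT1", "FLT4")),
    enabled = c(TRUE, TRUE)
  )
}

#' Validate knowledge-base referential integrity
#'
#' Checks drug-name uniqueness, drug-class levels, nonempty target sets for
#' small molecules and antibodies, that synergy pairs reference known drugs
#' and that the shared target is a target of both, and that both built-in
#' special rules are present. Errors name the offending record.
#'
#' @param kb An `ms_kb` object.
#' @return `kb`, invisibly, if valid; otherwise an error.
#' @export
kb_validate <- function(kb) {
  drugs <- kb$drugs
  if (nrow(drugs) == 0 || any(!nzchar(drugs$name))) {
    abort("knowledge base must contain at least one drug with a nonempty name")
  }
  dup <- drugs$name[duplicated(drugs$name)]
  if (length(dup) > 0) {
    abort(paste0("duplicate drug name(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_class <- setdiff(unique(drugs$drug_class), DRUG_CLASSES)
  if (length(bad_class) > 0) {
    abort(paste0("unknown drug_class: ", paste(bad_class, collapse = ", ")))
  }
  need_targets <- drugs$drug_class %in% c("small_molecule", "antibody")
  empty <- need_targets & purrr::map_int(drugs$targets, length) == 0
  if (any(empty)) {
    abort(paste0(
      "small molecules/antibodies must have nonempty target sets: ",
      paste(drugs$name[empty], collapse = ", ")
    ))
  }
  sp <- kb$synergy_pairs
  if (nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      pair_id <- paste0(sp$drug_a[i], "+", sp$drug_b[i])
      for (d in c(sp$drug_a[i], sp$drug_b[i])) {
        if (!d %in% drugs$name) {
          abort(paste0("synergy pair ", pair_id, " references unknown drug: ", d))
        }
        tg <- drugs$targets[[match(d, drugs$name)]]
        if (!sp$shared_target[i] %in% tg) {
          abort(paste0(
            "synergy pair ", pair_id, ": shared target ", sp$shared_target[i],
            " is not a target of ", d
          ))
        }
      }
    }
  }
  sr <- kb$special_rules
  missing_rule <- setdiff(SPECIAL_RULE_IDS, sr$rule_id)
  if (length(missing_rule) > 0) {
    abort(paste0("built-in special rule(s) missing: ",
                 paste(missing_rule, collapse = ", ")))
  }
  bad_cls <- setdiff(unique(unlist(sr$satisfying_classes)), DRUG_CLASSES)
  if (length(bad_cls) > 0) {
    abort(paste0("special rule names unknown drug class: ",
                 paste(bad_cls, collapse = ", ")))
  }
  invisible(kb)
}

#' Enable or disable a special match rule
#'
#' @param kb An `ms_kb` object.
#' @param rule_id `"brca_platinum_parp"` or `"tp53_vegf"`.
#' @param enabled Logical scalar.
#' @return The modified knowledge base.
#' @export
kb_set_rule <- function(kb, rule_id, enabled) {
  rule_id <- match.arg(rule_id, SPECIAL_RULE_IDS)
  kb$special_rules$enabled[kb$special_rules$rule_id == rule_id] <- isTRUE(enabled)
  kb
}

#' The bundled seed knowledge base
#'
#' Curated drug records covering the targeted agents, antibodies, platinum
#' and PARP agents, hormone modulators, VEGF-pathway inhibitors and immune
#' checkpoint inhibitors needed to score the worked examples and to drive
#' the synthetic cohort generator, together with the dabrafenib+trametinib
#' (BRAF) and pertuzumab+trastuzumab (ERBB2) synergy pairs and both special
#' rules (enabled). MEK inhibition is encoded by listing upstream MAPK genes
#' (BRAF, KRAS, NRAS) in trametinib's target set: matching on the immediate
#' downstream effector is data, not pathway inference.
#'
#' @return An `ms_kb` object.
#' @export
kb_seed <- function() {
  drug <- function(name, drug_class, targets, notes = "") {
    tibble::tibble(name = name, drug_class = drug_class,
                   targets = list(targets), notes = notes)
  }
  drugs <- dplyr::bind_rows(
    drug("dabrafenib", "small_molecule", "BRAF", "BRAF inhibitor"),
    drug("trametinib", "small_molecule", c("MAP2K1", "MAP2K2", "BRAF", "KRAS", "NRAS"),
         "MEK inhibitor; MEK is the immediate downstream effector of BRAF/RAS"),
    drug("trastuzumab", "antibody", "ERBB2", "anti-HER2 antibody"),
    drug("pertuzumab", "antibody", "ERBB2", "anti-HER2 dimerization antibody"),
    drug("erdafitinib", "small_molecule", c("FGFR1", "FGFR2", "FGFR3", "FGFR4"),
         "pan-FGFR inhibitor"),
    drug("erlotinib", "small_molecule", "EGFR", "EGFR inhibitor"),
    drug("cetuximab", "antibody", "EGFR", "anti-EGFR antibody"),
    drug("alpelisib", "small_molecule", "PIK3CA", "PI3K-alpha inhibitor"),
    drug("everolimus", "small_molecule", c("MTOR", "PIK3CA", "AKT1", "PTEN", "TSC1", "TSC2"),
         "mTOR inhibitor; mTOR is downstream of PI3K/AKT/PTEN/TSC"),
    drug("palbociclib", "small_molecule", c("CDK4", "CDK6", "CCND1", "CDKN2A"),
         "CDK4/6 inhibitor; downstream of cyclin D1 and CDKN2A loss"),
    drug("crizotinib", "small_molecule", c("ALK", "MET", "ROS1"), "ALK/MET/ROS1 inhibitor"),
    drug("larotrectinib", "small_molecule", c("NTRK1", "NTRK2", "NTRK3"), "TRK inhibitor"),
    drug("pazopanib", "small_molecule", c("KDR", "FLT1", "FLT4", "KIT", "PDGFRA", "PDGFRB"),
         "multikinase VEGFR inhibitor"),
    drug("bevacizumab", "antibody", "VEGFA", "anti-VEGF-A antibody"),
    drug("carboplatin", "platinum_chemo", character(), "platinum agent"),
    drug("olaparib", "parp_inhibitor", character(), "PARP inhibitor"),
    drug("letrozole", "hormone_modulator", character(), "aromatase inhibitor"),
    drug("enzalutamide", "hormone_modulator", character(), "androgen receptor antagonist"),
    drug("pembrolizumab", "checkpoint_inhibitor", c("PDCD1", "CD274"),
         "anti-PD-1; CD274 amplification treated as a direct genomic target"),
    drug("nivolumab", "checkpoint_inhibitor", c("PDCD1", "CD274"), "anti-PD-1"),
    drug("gemcitabine", "cytotoxic_other", character(), "nucleoside analogue"),
    drug("paclitaxel", "cytotoxic_other", character(), "taxane")
  )
  synergy <- tibble::tibble(
    drug_a = c("dabrafenib", "pertuzumab"),
    drug_b = c("trametinib", "trastuzumab"),
    shared_target = c("BRAF", "ERBB2")
  )
  knowledge_base(drugs, synergy, default_special_rules(), version = "seed-1")
}

#' Load a knowledge base from a JSON rules file
#'
#' The file is a single JSON document with top-level keys `drugs` (array of
#' objects with `name`, `drug_class`, `targets`, optional `notes`),
#' `synergy_pairs`, `special_rules`, and `version`. The loaded object is
#' fully validated; load -> write -> load round-trips losslessly.
#'
#' @param path Path to the JSON rules file.
#' @return An `ms_kb` object.
#' @seealso [kb_write()], [kb_export_targets()]
#' @export
kb_load <- function(path) {
  if (!file.exists(path)) abort(paste0("rules file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("drugs", "version")) {
    if (is.null(raw[[key]])) abort(paste0("rules file missing key: ", key))
  }
  chr0 <- function(x) if (is.null(x)) character() else as.character(unlist(x))
  drugs <- purrr::map_dfr(raw$drugs, function(d) {
    if (is.null(d$name) || is.null(d$drug_class)) {
      abort(paste0("drug record missing name or drug_class: ",
                   d$name %||% "<unnamed>"))
    }
    tibble::tibble(
      name = d$name, drug_class = d$drug_class,
      targets = list(chr0(d$targets)), notes = d$notes %||% ""
    )
  })
  synergy <- purrr::map_dfr(raw$synergy_pairs, function(s) {
    tibble::tibble(drug_a = s$drug_a, drug_b = s$drug_b,
                   shared_target = s$shared_target)
  })
  if (nrow(synergy) == 0) synergy <- NULL
  rules <- purrr::map_dfr(raw$special_rules, function(r) {
    tibble::tibble(
      rule_id = r$rule_id,
      trigger_genes = list(chr0(r$trigger_genes)),
      satisfying_classes = list(chr0(r$satisfying_classes)),
      satisfying_targets = list(chr0(r$satisfying_targets)),
      enabled = isTRUE(r$enabled)
    )
  })
  if (nrow(rules) == 0) rules <- NULL
  knowledge_base(drugs, synergy, rules, version = raw$version)
}

#' Write a knowledge base to a JSON rules file
#'
#' @param kb An `ms_kb` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
kb_write <- function(kb, path) {
  doc <- list(
    version = kb$version,
    drugs = purrr::pmap(kb$drugs, function(name, drug_class, targets, notes) {
      list(name = name, drug_class = drug_class, targets = as.list(targets),
           notes = notes)
    }),
    synergy_pairs = purrr::pmap(kb$synergy_pairs, function(drug_a, drug_b, shared_target) {
      list(drug_a = drug_a, drug_b = drug_b, shared_target = shared_target)
    }),
    special_rules = purrr::pmap(kb$special_rules,
      function(rule_id, trigger_genes, satisfying_classes, satisfying_targets, enabled) {
        list(rule_id = rule_id, trigger_genes = as.list(trigger_genes),
             satisfying_classes = as.list(satisfying_classes),
             satisfying_targets = as.list(satisfying_targets), enabled = enabled)
      })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export the drug-target map as a flat table
#'
#' One row per drug-target pair, for human review of the curated map.
#'
#' @param kb An `ms_kb` object.
#' @param path Optional TSV output path.
#' @return A tibble with columns `drug`, `drug_class`, `target`.
#' @export
kb_export_targets <- function(kb, path = NULL) {
  tab <- kb$drugs |>
    dplyr::select("name", "drug_class", "targets") |>
    tidyr::unnest_longer("targets", values_to = "target") |>
    dplyr::rename(drug = "name") |>
    dplyr::filter(!is.na(.data$target))
  if (!is.null(path)) readr::write_tsv(tab, path)
  tab
}

#' @export
print.ms_kb <- function(x, ...) {
  cat("<knowledge base> version", x$version, "\n")
  cat(" ", nrow(x$drugs), "drugs,",
      sum(purrr::map_int(x$drugs$targets, length)), "drug-target pairs,",
      nrow(x$synergy_pairs), "synergy pairs\n")
  sr <- x$special_rules
  cat("  special rules:",
      paste0(sr$rule_id, ifelse(sr$enabled, " (on)", " (off)"), collapse = ", "),
      "\n")
  invisible(x)
}

kb_drug_row <- function(kb, drug) {
  i <- match(drug, kb$drugs$name)
  if (is.na(i)) abort(paste0("unknown drug: ", drug))
  kb$drugs[i, ]
}

#' Does a drug match a single genomic alteration?
#'
#' The verdict is true iff (a) the alteration's gene is in the drug's curated
#' target set (which already encodes immediate downstream effectors), tagged
#' `direct_target`; or (b) an enabled special rule fires: a BRCA-related
#' repair-gene alteration with a platinum agent or PARP inhibitor
#' (`brca_platinum_parp`), or a TP53 alteration with a drug that has
#' anti-VEGF/VEGFR activity (`tp53_vegf`). Exactly one provenance tag is
#' returned; the direct-target clause takes precedence.
#'
#' @param kb An `ms_kb` object.
#' @param drug Drug name (must exist in `kb`).
#' @param gene Gene symbol of the alteration.
#' @return A one-row tibble with columns `drug`, `gene`, `matched` (logical)
#'   and `rule` (`direct_target`, `brca_platinum_parp`, `tp53_vegf`, `none`).
#' @export
drug_matches_alteration <- function(kb, drug, gene) {
  d <- kb_drug_row(kb, drug)
  g <- norm_gene(gene)
  rule <- "none"
  if (g %in% d$targets[[1]]) {
    rule <- "direct_target"
  } else {
    sr <- dplyr::filter(kb$special_rules, .data$enabled)
    for (i in seq_len(nrow(sr))) {
      if (!g %in% sr$trigger_genes[[i]]) next
      class_ok <- d$drug_class %in% sr$satisfying_classes[[i]]
      target_ok <- length(intersect(d$targets[[1]], sr$satisfying_targets[[i]])) > 0
      if (class_ok || target_ok) {
        rule <- sr$rule_id[i]
        break
      }
    }
  }
  tibble::tibble(drug = d$name, gene = g, matched = rule != "none", rule = rule)
}

#' Does the hormone-receptor IHC rule fire?
#'
#' True iff the biomarker profile records estrogen- or androgen-receptor
#' positive IHC and at least one administered drug is a hormone modulator
#' (e.g. letrozole). When it fires, scoring adds exactly one matched unit to
#' both the numerator and the denominator.
#'
#' @param kb An `ms_kb` object.
#' @param biomarkers A biomarker profile (see [biomarker_profile()]), or any
#'   list/one-row tibble with `er_positive` and `ar_positive` fields that are
#'   `TRUE`, `FALSE` or `NA` (unknown).
#' @param drugs Character vector of administered drug names.
#' @return Logical scalar.
#' @export
hormone_match <- function(kb, biomarkers, drugs) {
  receptor_pos <- isTRUE(as.logical(biomarkers$er_positive)) ||
    isTRUE(as.logical(biomarkers$ar_positive))
  if (!receptor_pos || length(drugs) == 0) return(FALSE)
  cls <- purrr::map_chr(drugs, function(d) kb_drug_row(kb, d)$drug_class)
  any(cls == "hormone_modulator")
}
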