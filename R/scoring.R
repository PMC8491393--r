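# Matching Score engine. The score is the fraction of countable genomic
# units targeted by the administered regimen, expressed as a percentage,
# combined with an immunotherapy biomarker component:
#   score = 100          if the io component is full (MSI-high, TMB-high,
#                        or PD-L1 high positive, with checkpoint blockade)
#   score = 50 + 100*X/2 if the io component is half (TMB-intermediate or
#                        PD-L1 low positive, with checkpoint blockade)
#   score = 100*X        otherwise,
# where X = matched units / countable units, capped at 100.

ALTERATION_CLASSES <- c("mutation", "amplification", "deletion", "fusion", "other")
TMB_LEVELS <- c("high", "intermediate", "low", "unknown")
MSI_LEVELS <- c("msi_high", "stable", "unknown")
PDL1_LEVELS <- c("high_positive", "low_positive", "negative", "unknown")

#' Construct a biomarker profile
#'
#' Categorical immunotherapy and hormone-receptor biomarkers for one patient.
#' If a numeric TMB (mutations/Mb) is supplied it is mapped deterministically
#' onto the trial's cutoffs: high >= 20, intermediate 6-19, low <= 5.
#'
#' @param tmb_category `"high"`, `"intermediate"`, `"low"` or `"unknown"`.
#' @param msi_status `"msi_high"`, `"stable"` or `"unknown"`.
#' @param pdl1_category `"high_positive"` (>= 30% tumor-cell staining),
#'   `"low_positive"` (>= 1% and < 30%), `"negative"` or `"unknown"`.
#' @param er_positive,ar_positive Logical or `NA` (unknown): estrogen /
#'   androgen receptor positivity by IHC.
#' @param tmb Optional numeric TMB overriding `tmb_category`.
#' @return A one-row tibble with the five categorical fields.
#' @export
biomarker_profile <- function(tmb_category = "unknown", msi_status = "unknown",
                              pdl1_category = "unknown", er_positive = NA,
                              ar_positive = NA, tmb = NULL) {
  if (!is.null(tmb)) {
    stopifnot(is.numeric(tmb), tmb >= 0)
    tmb_category <- if (tmb >= 20) "high" else if (tmb >= 6) "intermediate" else "low"
  }
  tibble::tibble(
    tmb_category = match.arg(tmb_category, TMB_LEVELS),
    msi_status = match.arg(msi_status, MSI_LEVELS),
    pdl1_category = match.arg(pdl1_category, PDL1_LEVELS),
    er_positive = as.logical(er_positive),
    ar_positive = as.logical(ar_positive)
  )
}

#' Construct an alteration table
#'
#' One row per reported genomic aberration. `impact_group` labels the
#' functional signal/pathway impact used by the same-gene collapse rule;
#' when unannotated (`NA`) it defaults to the alteration class, so same-gene
#' same-class events collapse by default.
#'
#' @param gene Gene symbols.
#' @param alteration_class One of
#'   `r paste(ALTERATION_CLASSES, collapse = ", ")` (recycled).
#' @param pathogenicity `"characterized"` or `"vus"`; variants of unknown
#'   significance never enter scoring (recycled).
#' @param report_id Genomic report identifier (tissue or blood); alterations
#'   from different reports are counted independently (recycled).
#' @param impact_group Optional impact label (recycled).
#' @return A tibble with the five columns above.
#' @export
alterations <- function(gene, alteration_class = "mutation",
                        pathogenicity = "characterized", report_id = "r1",
                        impact_group = NA_character_) {
  tibble::tibble(
    report_id = report_id, gene = gene,
    alteration_class = alteration_class,
    impact_group = impact_group,
    pathogenicity = pathogenicity
  )
}

check_alterations <- function(alt) {
  alt <- tibble::as_tibble(alt)
  required <- c("gene", "alteration_class", "pathogenicity")
  missing <- setdiff(required, names(alt))
  if (length(missing) > 0) {
    abort(paste0("alteration table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"report_id" %in% names(alt)) alt$report_id <- "r1"
  if (!"impact_group" %in% names(alt)) alt$impact_group <- NA_character_
  bad <- setdiff(unique(alt$alteration_class), ALTERATION_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("unknown alteration_class: ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(alt$pathogenicity), c("characterized", "vus"))
  if (length(bad) > 0) {
    abort(paste0("unknown pathogenicity: ", paste(bad, collapse = ", ")))
  }
  if (any(!nzchar(trimws(alt$gene)) | is.na(alt$gene))) {
    abort("alteration gene symbols must be nonempty")
  }
  alt
}

#' Collapse alterations into countable units
#'
#' Applies the counting rules: within one report, two or more aberrations in
#' the same gene with the same impact group and the same alteration class
#' count as one unit; same-gene aberrations that are structurally distinct
#' (e.g. an amplification and a mutation) or that have different impact
#' groups remain separate units. Alterations from different reports are
#' counted independently (tissue/blood heterogeneity); set
#' `dedupe_reports = TRUE` to collapse across reports instead. VUS are
#' excluded before counting.
#'
#' @param alt An alteration table (see [alterations()]).
#' @param dedupe_reports Collapse identical units across genomic reports?
#' @return A tibble of countable units: `report_id`, `gene`,
#'   `alteration_class`, `impact_group`, `n_collapsed`.
#' @export
collapse_alterations <- function(alt, dedupe_reports = FALSE) {
  alt <- check_alterations(alt) |>
    dplyr::filter(.data$pathogenicity == "characterized") |>
    dplyr::mutate(
      gene = norm_gene(.data$gene),
      impact_group = dplyr::coalesce(.data$impact_group, .data$alteration_class)
    )
  keys <- c("report_id", "gene", "impact_group", "alteration_class")
  if (dedupe_reports) keys <- setdiff(keys, "report_id")
  out <- alt |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_collapsed = dplyr::n(), .groups = "drop")
  if (dedupe_reports) out <- dplyr::mutate(out, report_id = "all", .before = 1)
  dplyr::select(out, "report_id", "gene", "alteration_class", "impact_group",
                "n_collapsed")
}

match_units <- function(units, drugs, kb) {
  if (nrow(units) == 0) {
    return(dplyr::mutate(units, matched = logical(), weight = integer(),
                         rule = character(), matched_by = character()))
  }
  # vectorized equivalent of drug_matches_alteration over the regimen:
  # precompute the administered drugs' target union and which special rules
  # some administered drug satisfies, then classify each unit's gene
  idx <- match(drugs, kb$drugs$name)
  if (any(is.na(idx))) {
    abort(paste0("unknown drug: ", paste(drugs[is.na(idx)], collapse = ", ")))
  }
  target_sets <- kb$drugs$targets[idx]
  classes <- kb$drugs$drug_class[idx]
  sr <- dplyr::filter(kb$special_rules, .data$enabled)
  sr_satisfied <- purrr::map_lgl(seq_len(nrow(sr)), function(i) {
    any(classes %in% sr$satisfying_classes[[i]]) ||
      any(purrr::map_lgl(target_sets,
        ~ length(intersect(.x, sr$satisfying_targets[[i]])) > 0))
  })
  classify <- function(g) {
    direct <- purrr::map_lgl(target_sets, ~ g %in% .x)
    # direct-target provenance outranks special rules, so a tp53_vegf tag
    # means the unit is matched solely through that rule
    if (any(direct)) {
      return(list(rule = "direct_target",
                  by = paste(drugs[direct], collapse = ",")))
    }
    for (i in seq_len(nrow(sr))) {
      if (sr_satisfied[i] && g %in% sr$trigger_genes[[i]]) {
        by <- drugs[classes %in% sr$satisfying_classes[[i]] |
                      purrr::map_lgl(target_sets,
                        ~ length(intersect(.x, sr$satisfying_targets[[i]])) > 0)]
        return(list(rule = sr$rule_id[i], by = paste(by, collapse = ",")))
      }
    }
    list(rule = "none", by = "")
  }
  verdicts <- purrr::map(units$gene, classify)
  units$rule <- purrr::map_chr(verdicts, "rule")
  units$matched <- units$rule != "none"
  units$matched_by <- purrr::map_chr(verdicts, "by")
  # synergy: both drugs of an established pair administered and the unit's
  # gene is their shared target -> the unit counts twice on both sides
  firing <- kb$synergy_pairs |>
    dplyr::filter(.data$drug_a %in% drugs & .data$drug_b %in% drugs)
  units$weight <- ifelse(units$matched & units$gene %in% firing$shared_target,
                         2L, 1L)
  units
}

#' Matched fraction of countable genomic units
#'
#' Collapses alterations to countable units, marks each unit matched iff any
#' administered drug matches it, applies synergy double-counting (weight 2
#' in numerator and denominator when both drugs of an established pair
#' co-target the unit), and adds one matched unit to both sides when the
#' hormone IHC rule fires. X = numerator/denominator, 0 when the denominator
#' is 0.
#'
#' @inheritParams collapse_alterations
#' @param biomarkers A biomarker profile ([biomarker_profile()]).
#' @param drugs Character vector of administered drug names (resolvable in
#'   `kb`).
#' @param kb An `ms_kb` knowledge base.
#' @return A list with `units` (audit tibble: one row per countable unit
#'   with `matched`, `weight`, `rule`, `matched_by`), `numerator`,
#'   `denominator`, and `x` (the matched fraction in \[0,1\]).
#' @export
genomic_fraction <- function(alt, biomarkers, drugs, kb, dedupe_reports = FALSE) {
  units <- collapse_alterations(alt, dedupe_reports) |>
    match_units(drugs = drugs, kb = kb)
  if (hormone_match(kb, biomarkers, drugs)) {
    units <- dplyr::bind_rows(units, tibble::tibble(
      report_id = "biomarker", gene = NA_character_,
      alteration_class = "other", impact_group = "hormone_receptor",
      n_collapsed = 1L, matched = TRUE, weight = 1L, rule = "hormone_ihc",
      matched_by = paste(drugs[purrr::map_chr(drugs, function(d)
        kb_drug_row(kb, d)$drug_class) == "hormone_modulator"], collapse = ",")
    ))
  }
  num <- sum(units$weight[units$matched])
  den <- sum(units$weight)
  list(units = units, numerator = num, denominator = den,
       x = if (den == 0) 0 else num / den)
}

#' Immunotherapy biomarker component
#'
#' Contributes nothing unless at least one administered drug is a checkpoint
#' inhibitor. With checkpoint blockade: `"full"` for MSI-high, TMB-high, or
#' PD-L1 high positive (>= 30% IHC); `"half"` for TMB-intermediate or PD-L1
#' low positive; `"none"` otherwise.
#'
#' @inheritParams genomic_fraction
#' @return `"full"`, `"half"` or `"none"`.
#' @export
immunotherapy_component <- function(biomarkers, drugs, kb) {
  if (length(drugs) == 0) return("none")
  cls <- purrr::map_chr(drugs, function(d) kb_drug_row(kb, d)$drug_class)
  if (!any(cls == "checkpoint_inhibitor")) return("none")
  full <- isTRUE(biomarkers$msi_status == "msi_high") ||
    isTRUE(biomarkers$tmb_category == "high") ||
    isTRUE(biomarkers$pdl1_category == "high_positive")
  if (full) return("full")
  half <- isTRUE(biomarkers$tmb_category == "intermediate") ||
    isTRUE(biomarkers$pdl1_category == "low_positive")
  if (half) "half" else "none"
}

#' Compute the Matching Score for one patient
#'
#' Combines the matched genomic fraction X with the immunotherapy component:
#' score = 100 when the component is full, 50 + 100*X/2 when it is half, and
#' 100*X otherwise; no match is scored over 100. The score is kept as an
#' exact double (no rounding) so that fractional values such as 50 + X/2 bin
#' correctly.
#'
#' @inheritParams genomic_fraction
#' @return An object of class `ms_breakdown`: the audit unit table plus
#'   `numerator`, `denominator`, `genomic_fraction`, `io_component` and
#'   `score` (percentage in \[0,100\]). Use [tidy()] for the per-unit audit
#'   rows and [glance()] for the one-row summary.
#' @examples
#' kb <- kb_seed()
#' six <- alterations(c("BRAF", "ERBB2", "EGFR", "APC", "SMAD4", "MYC"))
#' matching_score(six, biomarker_profile(), c("dabrafenib", "erlotinib",
#'   "trastuzumab"), kb)$score  # 50: three of six targeted
#' @export
matching_score <- function(alt, biomarkers, drugs, kb, dedupe_reports = FALSE) {
  if (length(drugs) == 0) abort("treated patients must have a nonempty regimen")
  gf <- genomic_fraction(alt, biomarkers, drugs, kb, dedupe_reports)
  io <- immunotherapy_component(biomarkers, drugs, kb)
  score <- switch(io,
    full = 100,
    half = 50 + 100 * gf$x / 2,
    none = 100 * gf$x
  )
  structure(
    list(units = gf$units, numerator = gf$numerator,
         denominator = gf$denominator, genomic_fraction = gf$x,
         io_component = io, score = min(100, score)),
    class = "ms_breakdown"
  )
}

#' @export
print.ms_breakdown <- function(x, ...) {
  cat(sprintf("<Matching Score breakdown> score = %.1f%%\n", x$score))
  cat(sprintf("  genomic: %d / %d matched (X = %.3f); io component: %s\n",
              x$numerator, x$denominator, x$genomic_fraction, x$io_component))
  invisible(x)
}

#' @rdname matching_score
#' @param x An `ms_breakdown` object.
#' @param ... Unused.
#' @export
tidy.ms_breakdown <- function(x, ...) x$units

#' @rdname matching_score
#' @export
glance.ms_breakdown <- function(x, ...) {
  tibble::tibble(
    numerator = x$numerator, denominator = x$denominator,
    genomic_fraction = x$genomic_fraction, io_component = x$io_component,
    score = x$score
  )
}

FINE_GRADES <- c("g0", "g1_39", "g40_59", "g60_99", "g100")

#' Stratify Matching Scores
#'
#' Returns all three stratifications used in the outcome analyses: the
#' primary three-level stratum (score >= 60 / 1-59 / unmatched 0), the
#' alternate dichotomy (> 50 vs <= 50), and the five fine grades (0, 1-39,
#' 40-59, 60-99, 100). Scores may be fractional; the fine bins are \[60,100),
#' \[40,60), (0,40) with 0 and 100 exact.
#'
#' @param score Numeric vector of scores in \[0,100\].
#' @return A tibble with columns `score`, `stratum`
#'   (`ge60`/`s1_59`/`unmatched`), `stratum50` (`gt50`/`le50`) and
#'   `fine_grade` (ordered factor `g0 < g1_39 < g40_59 < g60_99 < g100`).
#' @export
assign_grade <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 100)) {
    abort("scores must lie in [0, 100]")
  }
  tibble::tibble(
    score = score,
    stratum = dplyr::case_when(
      score >= 60 ~ "ge60",
      score > 0 ~ "s1_59",
      TRUE ~ "unmatched"
    ),
    stratum50 = dplyr::if_else(score > 50, "gt50", "le50"),
    fine_grade = factor(
      dplyr::case_when(
        score == 100 ~ "g100",
        score >= 60 ~ "g60_99",
        score >= 40 ~ "g40_59",
        score > 0 ~ "g1_39",
        TRUE ~ "g0"
      ),
      levels = FINE_GRADES, ordered = TRUE
    )
  )
}
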