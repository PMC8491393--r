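# Cohort container and tab-separated I/O. A cohort is five tables joined on
# patient_id: patients, alterations, biomarkers, treatments (one row per
# administered drug), outcomes. The dialect mirrors per-patient supplementary
# tables (one row per alteration / per drug) so real report data can be
# reformatted into it.

TUMOR_TYPES <- c(
  "gi_noncolorectal", "cup", "hepatobiliary", "colorectal", "pancreatic",
  "head_neck", "appendiceal", "gynecologic", "breast", "nsclc",
  "genitourinary", "melanoma", "other"
)
SEX_LEVELS <- c("female", "male")
RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "not_evaluable", "too_early")

COHORT_TABLES <- c("patients", "alterations", "biomarkers", "treatments", "outcomes")

cohort_col_types <- list(
  patients = readr::cols(
    patient_id = "c", tumor_type = "c", age = "d", sex = "c", treated = "l"
  ),
  alterations = readr::cols(
    patient_id = "c", report_id = "c", gene = "c", alteration_class = "c",
    impact_group = "c", pathogenicity = "c"
  ),
  biomarkers = readr::cols(
    patient_id = "c", tmb_category = "c", msi_status = "c",
    pdl1_category = "c", er_positive = "l", ar_positive = "l"
  ),
  treatments = readr::cols(patient_id = "c", drug = "c"),
  outcomes = readr::cols(
    patient_id = "c", best_response = "c", sd_duration_months = "d",
    sd_ongoing = "l", pfs_months = "d", pfs_event = "l", os_months = "d",
    os_event = "l"
  )
)

check_levels <- function(x, allowed, table, column, allow_na = FALSE) {
  bad <- which(!(x %in% allowed | (allow_na & is.na(x))))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: unknown %s value(s) %s at row(s) %s",
      table, column,
      paste(unique(x[bad]), collapse = ", "),
      paste(head(bad, 5), collapse = ", ")
    ))
  }
}

#' Assemble and validate a cohort from its five tables
#'
#' Checks join-key integrity (every child row's `patient_id` exists in
#' `patients`, no duplicate patients, at most one biomarker/outcome row per
#' patient), categorical levels, and that treated patients have a nonempty
#' treatment plan. Violations are reported with the table and row number.
#'
#' @param patients Tibble: `patient_id`, `tumor_type`, `age`, `sex`,
#'   `treated`.
#' @param alterations Tibble: `patient_id`, `report_id`, `gene`,
#'   `alteration_class`, `impact_group`, `pathogenicity`.
#' @param biomarkers Tibble: `patient_id`, `tmb_category`, `msi_status`,
#'   `pdl1_category`, `er_positive`, `ar_positive`.
#' @param treatments Tibble, one row per administered drug: `patient_id`,
#'   `drug`.
#' @param outcomes Tibble: `patient_id`, `best_response`,
#'   `sd_duration_months`, `sd_ongoing`, `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`.
#' @param provenance Optional named list recorded as an attribute.
#' @return An object of class `ms_cohort` (a named list of the five
#'   validated tibbles).
#' @export
cohort <- function(patients, alterations, biomarkers, treatments, outcomes,
                   provenance = list()) {
  tabs <- list(
    patients = tibble::as_tibble(patients),
    alterations = tibble::as_tibble(alterations),
    biomarkers = tibble::as_tibble(biomarkers),
    treatments = tibble::as_tibble(treatments),
    outcomes = tibble::as_tibble(outcomes)
  )
  for (nm in COHORT_TABLES) {
    expected <- names(cohort_col_types[[nm]]$cols)
    missing <- setdiff(expected, names(tabs[[nm]]))
    if (length(missing) > 0) {
      abort(paste0(nm, ": missing column(s): ", paste(missing, collapse = ", ")))
    }
    tabs[[nm]] <- dplyr::select(tabs[[nm]], dplyr::all_of(expected))
  }
  p <- tabs$patients
  dup <- which(duplicated(p$patient_id))
  if (length(dup) > 0) {
    abort(paste0("patients: duplicate patient_id at row(s) ",
                 paste(dup, collapse = ", ")))
  }
  check_levels(p$tumor_type, TUMOR_TYPES, "patients", "tumor_type")
  check_levels(p$sex, SEX_LEVELS, "patients", "sex", allow_na = TRUE)
  for (nm in setdiff(COHORT_TABLES, "patients")) {
    orphan <- which(!tabs[[nm]]$patient_id %in% p$patient_id)
    if (length(orphan) > 0) {
      abort(sprintf("%s: unknown patient_id %s at row(s) %s", nm,
                    paste(unique(tabs[[nm]]$patient_id[orphan]), collapse = ", "),
                    paste(head(orphan, 5), collapse = ", ")))
    }
  }
  for (nm in c("biomarkers", "outcomes")) {
    dup <- which(duplicated(tabs[[nm]]$patient_id))
    if (length(dup) > 0) {
      abort(sprintf("%s: more than one row per patient at row(s) %s", nm,
                    paste(dup, collapse = ", ")))
    }
  }
  check_levels(tabs$alterations$alteration_class, ALTERATION_CLASSES,
               "alterations", "alteration_class")
  check_levels(tabs$alterations$pathogenicity, c("characterized", "vus"),
               "alterations", "pathogenicity")
  check_levels(tabs$biomarkers$tmb_category, TMB_LEVELS, "biomarkers", "tmb_category")
  check_levels(tabs$biomarkers$msi_status, MSI_LEVELS, "biomarkers", "msi_status")
  check_levels(tabs$biomarkers$pdl1_category, PDL1_LEVELS, "biomarkers", "pdl1_category")
  check_levels(tabs$outcomes$best_response, RESPONSE_LEVELS,
               "outcomes", "best_response", allow_na = TRUE)
  treated_ids <- p$patient_id[p$treated]
  unplanned <- setdiff(treated_ids, tabs$treatments$patient_id)
  if (length(unplanned) > 0) {
    abort(paste0("treated patient(s) with empty treatment plan: ",
                 paste(unplanned, collapse = ", ")))
  }
  structure(tabs, class = "ms_cohort",
            provenance = c(provenance, list(created = as.character(Sys.time()))))
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$patients), "patients (",
      sum(x$patients$treated), "treated ),",
      nrow(x$alterations), "alteration rows,",
      nrow(x$treatments), "drug administrations\n")
  invisible(x)
}

#' Read a cohort from tab-separated tables
#'
#' Expects `patients.tsv`, `alterations.tsv`, `biomarkers.tsv`,
#' `treatments.tsv` and `outcomes.tsv` in `dir` (file names can be
#' overridden via `paths`). All validation of [cohort()] applies; per-table
#' row counts are logged via `message()`.
#'
#' @param dir Directory containing the five tables.
#' @param paths Optional named character vector overriding individual file
#'   locations (names among `patients`, `alterations`, ...).
#' @param quiet Suppress row-count messages?
#' @return An `ms_cohort`.
#' @export
read_cohort <- function(dir = ".", paths = NULL, quiet = FALSE) {
  files <- setNames(file.path(dir, paste0(COHORT_TABLES, ".tsv")), COHORT_TABLES)
  if (!is.null(paths)) files[names(paths)] <- paths
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    abort(paste0("cohort table file(s) not found: ",
                 paste(missing, collapse = ", ")))
  }
  tabs <- purrr::imap(files, function(f, nm) {
    tab <- readr::read_tsv(f, col_types = cohort_col_types[[nm]],
                           progress = FALSE)
    if (!quiet) message(sprintf("read %s: %d rows", nm, nrow(tab)))
    tab
  })
  cohort(tabs$patients, tabs$alterations, tabs$biomarkers, tabs$treatments,
         tabs$outcomes, provenance = list(source = unname(files)))
}

#' Write a cohort to tab-separated tables
#'
#' Inverse of [read_cohort()]; writing then re-reading is lossless.
#'
#' @param x An `ms_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "ms_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in COHORT_TABLES) {
    readr::write_tsv(x[[nm]], file.path(dir, paste0(nm, ".tsv")), progress = FALSE)
  }
  invisible(dir)
}

#' Score every treated patient in a cohort
#'
#' Runs [matching_score()] per treated patient and attaches the per-patient
#' summary plus the full per-unit audit table. Untreated patients pass
#' through unscored. Per-patient scoring errors are collected into a
#' `problems` attribute rather than aborting the batch.
#'
#' @param x An `ms_cohort`.
#' @param kb An `ms_kb` knowledge base.
#' @param dedupe_reports Collapse identical units across genomic reports?
#' @return An object of class `ms_scored` with elements `cohort`, `scores`
#'   (one row per scored patient: numerator, denominator, io component,
#'   score and all three stratifications) and `audit` (one row per countable
#'   unit across the cohort). `attr(, "problems")` holds any per-patient
#'   failures.
#' @export
score_cohort <- function(x, kb, dedupe_reports = FALSE) {
  stopifnot(inherits(x, "ms_cohort"), inherits(kb, "ms_kb"))
  treated <- dplyr::filter(x$patients, .data$treated)
  # patients whose regimen contains a drug the knowledge base cannot
  # resolve are reported, not fatal to the batch
  trt <- dplyr::filter(x$treatments, .data$patient_id %in% treated$patient_id)
  unknown <- dplyr::filter(trt, !.data$drug %in% kb$drugs$name)
  problems <- unknown |>
    dplyr::distinct(.data$patient_id, .data$drug) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(error = paste0("unknown drug: ",
                                    paste(.data$drug, collapse = ", ")),
                     .groups = "drop")
  ok_ids <- setdiff(treated$patient_id, problems$patient_id)
  res <- score_patients_vec(x, kb, ok_ids, dedupe_reports)
  scores <- res$scores
  audits <- res$audit
  if (nrow(scores) > 0) {
    scores <- dplyr::bind_cols(scores,
      dplyr::select(assign_grade(scores$score), -"score"))
  }
  structure(
    list(cohort = x, scores = scores, audit = audits),
    class = "ms_scored",
    problems = problems,
    kb_version = kb$version,
    dedupe_reports = dedupe_reports
  )
}

# Whole-cohort scoring via joined table operations; semantically equivalent
# to running matching_score() per patient (asserted by tests), but one
# grouped pass instead of a per-patient loop.
score_patients_vec <- function(x, kb, ids, dedupe_reports) {
  empty_scores <- tibble::tibble(
    patient_id = character(), numerator = integer(), denominator = integer(),
    genomic_fraction = numeric(), io_component = character(), score = numeric()
  )
  if (length(ids) == 0) {
    return(list(scores = empty_scores, audit = tibble::tibble()))
  }
  trt <- dplyr::filter(x$treatments, .data$patient_id %in% ids) |>
    dplyr::distinct(.data$patient_id, .data$drug) |>
    dplyr::left_join(
      dplyr::select(kb$drugs, drug = "name", "drug_class", "targets"),
      by = "drug"
    )
  # per-patient direct-target map: (patient_id, gene, drugs that hit it)
  direct <- trt |>
    dplyr::select("patient_id", "drug", "targets") |>
    tidyr::unnest_longer("targets", values_to = "gene") |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::group_by(.data$patient_id, .data$gene) |>
    dplyr::summarise(direct_by = paste(.data$drug, collapse = ","),
                     .groups = "drop")
  # which enabled special rules each patient's regimen satisfies
  sr <- dplyr::filter(kb$special_rules, .data$enabled)
  rule_sat <- purrr::map_dfr(seq_len(nrow(sr)), function(i) {
    hit <- trt |>
      dplyr::filter(.data$drug_class %in% sr$satisfying_classes[[i]] |
                      purrr::map_lgl(.data$targets,
                        ~ length(intersect(.x, sr$satisfying_targets[[i]])) > 0))
    if (nrow(hit) == 0) return(NULL)
    hit |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(rule_by = paste(.data$drug, collapse = ","),
                       .groups = "drop") |>
      dplyr::mutate(rule_id = sr$rule_id[i])
  })

  units <- x$alterations |>
    dplyr::filter(.data$patient_id %in% ids,
                  .data$pathogenicity == "characterized") |>
    dplyr::mutate(
      gene = norm_gene(.data$gene),
      impact_group = dplyr::coalesce(.data$impact_group, .data$alteration_class),
      report_id = if (dedupe_reports) "all" else .data$report_id
    ) |>
    dplyr::group_by(.data$patient_id, .data$report_id, .data$gene,
                    .data$impact_group, .data$alteration_class) |>
    dplyr::summarise(n_collapsed = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(direct, by = c("patient_id", "gene"))
  # special-rule provenance where no direct target fires
  units$rule <- ifelse(!is.na(units$direct_by), "direct_target", "none")
  units$matched_by <- dplyr::coalesce(units$direct_by, "")
  if (nrow(rule_sat) > 0) {
    for (i in seq_len(nrow(sr))) {
      sat <- dplyr::filter(rule_sat, .data$rule_id == sr$rule_id[i])
      idx <- units$rule == "none" &
        units$gene %in% sr$trigger_genes[[i]] &
        units$patient_id %in% sat$patient_id
      units$rule[idx] <- sr$rule_id[i]
      units$matched_by[idx] <-
        sat$rule_by[match(units$patient_id[idx], sat$patient_id)]
    }
  }
  units$matched <- units$rule != "none"
  # synergy double-count: both pair drugs administered, unit matched on the
  # shared target
  units$weight <- 1L
  for (i in seq_len(nrow(kb$synergy_pairs))) {
    sp <- kb$synergy_pairs[i, ]
    both <- intersect(
      trt$patient_id[trt$drug == sp$drug_a],
      trt$patient_id[trt$drug == sp$drug_b]
    )
    idx <- units$matched & units$gene == sp$shared_target &
      units$patient_id %in% both
    units$weight[idx] <- 2L
  }
  units <- dplyr::select(units, -"direct_by")

  # hormone IHC rule: one matched unit on both sides when it fires
  bm <- dplyr::filter(x$biomarkers, .data$patient_id %in% ids)
  hormone_ids <- bm$patient_id[
    (dplyr::coalesce(bm$er_positive, FALSE) |
       dplyr::coalesce(bm$ar_positive, FALSE))
  ]
  hormone_by <- trt |>
    dplyr::filter(.data$patient_id %in% hormone_ids,
                  .data$drug_class == "hormone_modulator") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(by = paste(.data$drug, collapse = ","), .groups = "drop")
  if (nrow(hormone_by) > 0) {
    units <- dplyr::bind_rows(units, tibble::tibble(
      patient_id = hormone_by$patient_id, report_id = "biomarker",
      gene = NA_character_, alteration_class = "other",
      impact_group = "hormone_receptor", n_collapsed = 1L,
      rule = "hormone_ihc", matched_by = hormone_by$by, matched = TRUE,
      weight = 1L
    ))
  }

  frac <- units |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      numerator = sum(.data$weight[.data$matched]),
      denominator = sum(.data$weight),
      .groups = "drop"
    )
  # io component per patient
  has_ici <- unique(trt$patient_id[trt$drug_class == "checkpoint_inhibitor"])
  bm_full <- dplyr::left_join(tibble::tibble(patient_id = ids), bm,
                              by = "patient_id")
  io <- dplyr::case_when(
    !bm_full$patient_id %in% has_ici ~ "none",
    dplyr::coalesce(bm_full$msi_status == "msi_high", FALSE) |
      dplyr::coalesce(bm_full$tmb_category == "high", FALSE) |
      dplyr::coalesce(bm_full$pdl1_category == "high_positive", FALSE) ~ "full",
    dplyr::coalesce(bm_full$tmb_category == "intermediate", FALSE) |
      dplyr::coalesce(bm_full$pdl1_category == "low_positive", FALSE) ~ "half",
    TRUE ~ "none"
  )
  scores <- tibble::tibble(patient_id = ids, io_component = io) |>
    dplyr::left_join(frac, by = "patient_id") |>
    dplyr::mutate(
      numerator = dplyr::coalesce(.data$numerator, 0L),
      denominator = dplyr::coalesce(.data$denominator, 0L),
      genomic_fraction = dplyr::if_else(.data$denominator == 0, 0,
                                        .data$numerator / .data$denominator),
      score = pmin(100, dplyr::case_when(
        .data$io_component == "full" ~ 100,
        .data$io_component == "half" ~ 50 + 100 * .data$genomic_fraction / 2,
        TRUE ~ 100 * .data$genomic_fraction
      ))
    ) |>
    dplyr::select("patient_id", "numerator", "denominator",
                  "genomic_fraction", "io_component", "score")
  list(scores = scores, audit = units)
}

#' @export
print.ms_scored <- function(x, ...) {
  cat("<scored cohort>", nrow(x$scores), "scored patients; bins:\n")
  print(table(x$scores$fine_grade))
  pr <- attr(x, "problems")
  if (nrow(pr) > 0) cat("  ", nrow(pr), "patients failed to score\n")
  invisible(x)
}

#' Flat analysis table for a scored cohort
#'
#' One row per scored (treated) patient: demographics, drug count, outcome
#' fields, score and stratifications, plus the disease-control
#' classification of [classify_disease_control()].
#'
#' @param x An `ms_scored` object.
#' @return A tibble.
#' @export
scored_table <- function(x) {
  stopifnot(inherits(x, "ms_scored"))
  ndrug <- x$cohort$treatments |>
    dplyr::count(.data$patient_id, name = "n_drugs")
  x$scores |>
    dplyr::left_join(x$cohort$patients, by = "patient_id") |>
    dplyr::left_join(ndrug, by = "patient_id") |>
    dplyr::left_join(x$cohort$outcomes, by = "patient_id") |>
    dplyr::mutate(disease_control = classify_disease_control(
      .data$best_response, .data$sd_duration_months, .data$sd_ongoing
    ))
}
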