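# Synthetic cohort generator. Emulates the marginal structure of a treated
# N-of-1 precision-oncology cohort: truncated-negative-binomial alteration
# counts (median 5, range 0-15), a five-bin Matching Score distribution,
# checkpoint-inhibitor administration with qualifying biomarkers, and
# score-stratum-dependent disease control and exponential PFS/OS with
# independent exponential censoring. Bin membership is constructed (the
# generator chooses matched/total unit counts whose engine score lands in
# the intended bin), not rejection-sampled, so scoring a simulated cohort
# with the real engine reproduces every patient's intended stratum.

# (gene, drug) catalogue for matched units: one drug per gene, drawn from
# the seed knowledge base; one member per synergy pair so that synergy
# double-counting never fires accidentally and constructed scores are exact
SIM_MATCHED_CATALOG <- c(
  BRAF = "dabrafenib", ERBB2 = "trastuzumab", FGFR2 = "erdafitinib",
  FGFR3 = "erdafitinib", EGFR = "erlotinib", PIK3CA = "alpelisib",
  PTEN = "everolimus", CCND1 = "palbociclib", CDK4 = "palbociclib",
  ALK = "crizotinib", MET = "crizotinib", NTRK1 = "larotrectinib",
  KIT = "pazopanib", BRCA1 = "carboplatin", BRCA2 = "olaparib"
)

# genes no seed drug targets and no special rule triggers on
SIM_UNMATCHED_POOL <- c(
  "APC", "SMAD4", "ARID1A", "MYC", "CTNNB1", "RB1", "STK11", "GNAS",
  "FBXW7", "KMT2D", "ASXL1", "CDH1", "SOX9", "TERT", "KEAP1"
)

SIM_CYTOTOXICS <- c("gemcitabine", "paclitaxel")

#' Simulation parameters for a synthetic cohort
#'
#' Defaults encode the study conditions the generator emulates: 76 treated
#' patients; alteration counts negative binomial (size 3, mean 5.5)
#' truncated to \[0,15\] (median 5); fine score bins in proportions
#' 13:14:14:13:22 over 100 / 60-99 / 40-59 / 1-39 / 0; checkpoint blockade
#' among matched patients with probability 14/54; disease control 0.68 vs
#' 0.30 for score >= 60 vs < 60; exponential PFS medians 11.6 vs 2.8 months
#' and OS medians 18.7 vs 11.6 months; independent exponential
#' administrative censoring at 0.015/month (about 20% censoring in the
#' long-PFS stratum); about 8/76 of patients inevaluable for disease
#' control (ongoing early SD or too early).
#'
#' @param n_patients Number of treated patients.
#' @param bin_props Named proportions over `g100, g60_99, g40_59, g1_39,
#'   g0`; must sum to 1. Counts are allocated by largest remainder, so at
#'   the default n = 76 the bin counts are exact.
#' @param alt_nb_size,alt_nb_mu,alt_max Truncated negative-binomial
#'   alteration-count model.
#' @param vus_fraction Expected VUS rows per characterized alteration
#'   (VUS never enter scoring).
#' @param io_prob Probability a matched patient receives checkpoint
#'   blockade with a qualifying biomarker (applied where the bin arithmetic
#'   permits: full component in the 100% bin, half component in the 60-99
#'   and 40-59 bins).
#' @param dc_prob Named `c(high=, low=)` disease-control probabilities by
#'   score stratum (>= 60 vs < 60).
#' @param pfs_median,os_median Named `c(high=, low=)` exponential medians
#'   in months.
#' @param censor_rate Exponential censoring rate per month.
#' @param frac_inevaluable Fraction of patients inevaluable for disease
#'   control.
#' @param dc_prob_by_grade,pfs_median_by_grade Optional length-5 vectors
#'   (named by fine grade) overriding the two-stratum outcome model with a
#'   per-grade model, e.g. a linear grade-outcome map.
#' @param tumor_type_freqs Named sampling weights over the documented tumor
#'   types.
#' @return A list of validated parameters (class `ms_sim_params`).
#' @export
sim_params <- function(n_patients = 76,
                       bin_props = c(g100 = 13, g60_99 = 14, g40_59 = 14,
                                     g1_39 = 13, g0 = 22) / 76,
                       alt_nb_size = 3, alt_nb_mu = 5.5, alt_max = 15,
                       vus_fraction = 0.3,
                       io_prob = 14 / 54,
                       dc_prob = c(high = 0.68, low = 0.30),
                       pfs_median = c(high = 11.6, low = 2.8),
                       os_median = c(high = 18.7, low = 11.6),
                       censor_rate = 0.015,
                       frac_inevaluable = 8 / 76,
                       dc_prob_by_grade = NULL,
                       pfs_median_by_grade = NULL,
                       tumor_type_freqs = c(
                         gi_noncolorectal = 12, cup = 10, hepatobiliary = 9,
                         colorectal = 7, pancreatic = 7, head_neck = 5,
                         appendiceal = 4, gynecologic = 4, breast = 3,
                         nsclc = 3, genitourinary = 2, melanoma = 2,
                         other = 8) / 76) {
  stopifnot(
    n_patients >= 1,
    abs(sum(bin_props) - 1) < 1e-8,
    all(bin_props >= 0),
    setequal(names(bin_props), FINE_GRADES),
    all(dc_prob > 0 & dc_prob < 1),
    all(pfs_median > 0), all(os_median > 0),
    censor_rate >= 0, frac_inevaluable >= 0, frac_inevaluable < 1,
    io_prob >= 0, io_prob <= 1
  )
  if (io_prob > 0 && all(bin_props[c("g100", "g60_99", "g40_59")] == 0)) {
    abort("io administration requested but no bin compatible with an io component")
  }
  structure(as.list(environment()), class = "ms_sim_params")
}

# largest-remainder allocation of n into named proportions
allocate_counts <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

rnbinom_trunc <- function(n, size, mu, max) {
  probs <- dnbinom(0:max, size = size, mu = mu)
  sample(0:max, n, replace = TRUE, prob = probs / sum(probs))
}

# feasible matched counts m for a total of n units under score target
# [lo, hi) on the engine scale: score = 50 + 50*m/n with a half io
# component, else 100*m/n (0 when n = 0)
feasible_m <- function(n, lo, hi, io_half) {
  m <- 0:n
  score <- if (n == 0) rep(0, length(m)) else if (io_half) {
    50 + 50 * m / n
  } else {
    100 * m / n
  }
  m[score >= lo - 1e-9 & score < hi - 1e-9]
}

# target score interval [lo, hi) per bin; the positive lower bound for
# g1_39 (any value in (0, 100/15]) excludes the all-unmatched m = 0 case
bin_range <- function(bin) {
  switch(bin,
    g100 = c(100, 100.1), g60_99 = c(60, 100), g40_59 = c(40, 60),
    g1_39 = c(0.5, 40), g0 = c(0, 0.5)
  )
}

sim_patient_profile <- function(bin, n_alt, io_prob) {
  io_mode <- "none"
  if (bin == "g100" && runif(1) < io_prob) io_mode <- "full"
  if (bin %in% c("g60_99", "g40_59") && runif(1) < io_prob) io_mode <- "half"
  rng <- bin_range(bin)
  if (io_mode == "full") {
    n <- n_alt
    m <- sample.int(n + 1, 1) - 1     # X unconstrained when the io is full
  } else {
    n <- n_alt
    repeat {
      cand <- feasible_m(n, rng[1], rng[2], io_mode == "half")
      if (length(cand) > 0) break
      n <- n + 1                       # smallest unit count that can hit the bin
    }
    m <- if (length(cand) == 1) cand else sample(cand, 1)
  }
  list(io_mode = io_mode, n_units = n, n_matched = m)
}

sim_expected_score <- function(io_mode, m, n) {
  x <- if (n == 0) 0 else m / n
  switch(io_mode, full = 100, half = 50 + 50 * x, none = 100 * x)
}

#' Simulate a synthetic treated cohort
#'
#' Generates the five cohort tables plus a ground-truth table. Drugs are
#' drawn from the seed knowledge base so that scoring the simulated cohort
#' with the real engine places every patient in their intended score bin;
#' outcomes are drawn from the stratum-specific (or per-grade) models. The
#' same seed reproduces byte-identical tables.
#'
#' @param params An [sim_params()] object.
#' @param seed Integer seed driving all draws.
#' @param kb Knowledge base drugs are drawn from (the seed base; the
#'   generator's catalogues are defined against it).
#' @return A list of class `ms_sim`: `cohort` (a validated [cohort()]) and
#'   `truth` (tibble: patient_id, intended bin, io mode, matched/total unit
#'   counts, expected score, true stratum, true disease-control
#'   probability, true PFS/OS medians).
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1, kb = kb_seed()) {
  stopifnot(inherits(params, "ms_sim_params"))
  set.seed(seed)
  n <- params$n_patients
  bins <- sample(rep(FINE_GRADES,
                     allocate_counts(n, params$bin_props[FINE_GRADES])))
  ids <- sprintf("P%03d", seq_len(n))
  n_alt <- rnbinom_trunc(n, params$alt_nb_size, params$alt_nb_mu, params$alt_max)

  patients <- tibble::tibble(
    patient_id = ids,
    tumor_type = sample(names(params$tumor_type_freqs), n, replace = TRUE,
                        prob = params$tumor_type_freqs),
    age = round(pmin(93, pmax(23, stats::rnorm(n, 62, 13))), 1),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.53, 0.47)),
    treated = TRUE
  )

  # accumulate plain vectors (one tibble at the end keeps this loop fast)
  alt_pid <- list(); alt_gene <- list(); alt_class <- list(); alt_path <- list()
  trt_pid <- list(); trt_drug <- list()
  bm_tmb <- character(n); bm_msi <- character(n); bm_pdl1 <- character(n)
  io_mode <- character(n); n_matched <- integer(n); n_units <- integer(n)
  for (i in seq_len(n)) {
    prof <- sim_patient_profile(bins[i], n_alt[i], params$io_prob)
    m <- prof$n_matched; nu <- prof$n_units
    matched_genes <- if (m > 0) sample(names(SIM_MATCHED_CATALOG), m) else character()
    unmatched_genes <- if (nu - m > 0) sample(SIM_UNMATCHED_POOL, nu - m) else character()
    genes <- c(matched_genes, unmatched_genes)
    classes <- if (nu > 0) {
      sample(c("mutation", "amplification", "deletion", "fusion"), nu,
             replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05))
    } else character()
    n_vus <- stats::rpois(1, params$vus_fraction * max(nu, 1))
    vus_genes <- sample(c(names(SIM_MATCHED_CATALOG), SIM_UNMATCHED_POOL),
                        n_vus, replace = TRUE)
    alt_pid[[i]] <- rep(ids[i], nu + n_vus)
    alt_gene[[i]] <- c(genes, vus_genes)
    alt_class[[i]] <- c(classes, rep("mutation", n_vus))
    alt_path[[i]] <- rep(c("characterized", "vus"), c(nu, n_vus))
    drugs <- unique(unname(SIM_MATCHED_CATALOG[matched_genes]))
    if (prof$io_mode != "none") drugs <- c(drugs, "pembrolizumab")
    if (length(drugs) == 0 || runif(1) < 0.4) {
      drugs <- c(drugs, sample(SIM_CYTOTOXICS, 1))
    }
    trt_pid[[i]] <- rep(ids[i], length(drugs))
    trt_drug[[i]] <- drugs
    bm_tmb[i] <- "unknown"; bm_msi[i] <- "unknown"; bm_pdl1[i] <- "unknown"
    if (prof$io_mode == "full") {
      pick <- sample(c("msi", "tmb", "pdl1"), 1)
      if (pick == "msi") bm_msi[i] <- "msi_high"
      if (pick == "tmb") bm_tmb[i] <- "high"
      if (pick == "pdl1") bm_pdl1[i] <- "high_positive"
    } else if (prof$io_mode == "half") {
      if (runif(1) < 0.5) bm_tmb[i] <- "intermediate"
      else bm_pdl1[i] <- "low_positive"
    }
    io_mode[i] <- prof$io_mode; n_matched[i] <- m; n_units[i] <- nu
  }
  alterations_tab <- tibble::tibble(
    patient_id = unlist(alt_pid), report_id = "r1",
    gene = unlist(alt_gene), alteration_class = unlist(alt_class),
    impact_group = NA_character_, pathogenicity = unlist(alt_path)
  )
  treatments_tab <- tibble::tibble(patient_id = unlist(trt_pid),
                                   drug = unlist(trt_drug))
  biomarkers_tab <- tibble::tibble(
    patient_id = ids, tmb_category = bm_tmb, msi_status = bm_msi,
    pdl1_category = bm_pdl1, er_positive = NA, ar_positive = NA
  )
  truth <- tibble::tibble(
    patient_id = ids, bin = bins, io_mode = io_mode,
    n_matched = n_matched, n_units = n_units,
    expected_score = purrr::pmap_dbl(
      list(io_mode, n_matched, n_units), sim_expected_score)
  ) |>
    dplyr::mutate(
      stratum_true = dplyr::if_else(.data$expected_score >= 60, "high", "low"),
      dc_prob = if (!is.null(params$dc_prob_by_grade)) {
        unname(params$dc_prob_by_grade[.data$bin])
      } else {
        unname(params$dc_prob[.data$stratum_true])
      },
      pfs_median_true = if (!is.null(params$pfs_median_by_grade)) {
        unname(params$pfs_median_by_grade[.data$bin])
      } else {
        unname(params$pfs_median[.data$stratum_true])
      },
      os_median_true = unname(params$os_median[.data$stratum_true])
    )

  outcomes <- sim_outcomes(truth, params)
  coh <- cohort(
    patients, alterations_tab, biomarkers_tab, treatments_tab, outcomes,
    provenance = list(generator = "simulate_cohort", seed = seed,
                      kb_version = kb$version)
  )
  structure(list(cohort = coh, truth = truth, params = params, seed = seed),
            class = "ms_sim")
}

sim_outcomes <- function(truth, params) {
  n <- nrow(truth)
  evaluable <- runif(n) >= params$frac_inevaluable
  dc <- runif(n) < truth$dc_prob
  best_response <- character(n)
  sd_duration <- rep(NA_real_, n)
  sd_ongoing <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!evaluable[i]) {
      if (runif(1) < 5 / 8) {
        best_response[i] <- "SD"
        sd_duration[i] <- round(runif(1, 1, 5.9), 1)
        sd_ongoing[i] <- TRUE
      } else {
        best_response[i] <- "too_early"
      }
    } else if (dc[i]) {
      u <- runif(1)
      if (u < 0.10) {
        best_response[i] <- "CR"
      } else if (u < 0.60) {
        best_response[i] <- "PR"
      } else {
        best_response[i] <- "SD"
        sd_duration[i] <- round(6 + rexp(1, 1 / 6), 1)
      }
    } else if (runif(1) < 0.7) {
      best_response[i] <- "PD"
    } else {
      best_response[i] <- "SD"
      sd_duration[i] <- round(runif(1, 1, 5.9), 1)
    }
  }
  surv_draw <- function(med) {
    t <- rexp(n, log(2) / med)
    if (params$censor_rate > 0) {
      c <- rexp(n, params$censor_rate)
      list(time = round(pmin(t, c), 2), event = t <= c)
    } else {
      list(time = round(t, 2), event = rep(TRUE, n))
    }
  }
  pfs <- surv_draw(truth$pfs_median_true)
  os <- surv_draw(truth$os_median_true)
  tibble::tibble(
    patient_id = truth$patient_id, best_response = best_response,
    sd_duration_months = sd_duration, sd_ongoing = sd_ongoing,
    pfs_months = pfs$time, pfs_event = pfs$event,
    os_months = os$time, os_event = os$event
  )
}

#' @export
print.ms_sim <- function(x, ...) {
  cat("<synthetic cohort> seed", x$seed, "\n")
  print(x$cohort)
  cat("  intended bins:\n")
  print(table(factor(x$truth$bin, levels = FINE_GRADES)))
  invisible(x)
}
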