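---
title: "Matching Scores for N-of-1 precision oncology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching Scores for N-of-1 precision oncology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomatch)
```

## The problem and the statistic

Individualized (N-of-1) combination therapy assembles a drug regimen
against each patient's own tumor profile. The **Matching Score**
quantifies how completely a regimen covers that profile: the percentage of
a patient's countable molecular aberrations that are targeted by the
administered drugs, augmented by an immunotherapy biomarker component.
The package treats the score as the exposure in a set of standard trial
analyses — disease control, progression-free and overall survival — so
that "degree of matching" can be analyzed as a continuous or stratified
predictor.

## Counting rules

Starting from the per-report alteration list (variants of unknown
significance are excluded everywhere):

1. **Same-gene collapse.** Within one genomic report, two or more
   aberrations in the same gene with the same functional impact and the
   same structural class count as **one** unit. The impact label
   (`impact_group`) defaults to the alteration class when unannotated, so
   two same-gene point mutations collapse by default.
2. **Structurally distinct events count separately.** An amplification
   and a mutation of the same gene are two units, as are same-gene events
   with different annotated impact groups.
3. **Synergy pairs.** When two drugs co-target one aberration in an
   established synergistic combination (dabrafenib + trametinib on BRAF;
   pertuzumab + trastuzumab on ERBB2) and both are administered, the
   matched unit is counted **twice in both numerator and denominator**.
4. **Hormone-receptor matching.** ER- or AR-positive IHC targeted by an
   administered hormone modulator adds one matched unit to both sides.
   The unit enters only when the match fires: an untargeted ER-positive
   status does not dilute the score.
5. **Cross-report counting.** If a patient has two or more genomic
   reports (e.g. tissue and ctDNA), units are counted per report,
   reflecting real heterogeneity between samples. Because the same
   variant seen in both reports is arguably one biological event,
   `dedupe_reports = TRUE` collapses across reports instead; the default
   follows the per-report reading.

A drug matches a unit when the unit's gene is in the drug's curated
target set, or when a special rule fires: BRCA-related repair-gene
alterations (BRCA1/2, ATM, PALB2, BARD1, CHEK2) are matched by platinum
agents and PARP inhibitors, and TP53 alterations by drugs with
anti-VEGF/VEGFR activity. Each rule can be disabled — the TP53 rule
toggle drives the sensitivity analysis below. Every verdict carries
exactly one provenance tag (`direct_target` outranks the special rules),
so the per-unit audit table shows *why* each unit matched.

With matched fraction $X$ in $[0,1]$, the score is

$$\text{score} =
\begin{cases}
100 & \text{io component full}\\
50 + 100\,X/2 & \text{io component half}\\
100\,X & \text{otherwise,}
\end{cases}$$

capped at 100. The immunotherapy component requires an administered
checkpoint inhibitor and is *full* for MSI-high, TMB-high
($\ge 20$ Muts/Mb) or PD-L1 high-positive ($\ge 30\%$ IHC), *half* for
TMB-intermediate (6–19) or PD-L1 low-positive ($\ge 1\%$). CD274 (PD-L1)
amplification is deliberately treated as an ordinary genomic unit that
checkpoint inhibitors match directly — the biomarker component is
reserved for the MSI/TMB/PD-L1-IHC states listed above, because the
scoring rules enumerate only those; this is one of the genuinely
ambiguous points in the source material and the choice is recorded here.

### Numerical conventions

Scores are kept as exact doubles until binning — $50 + X/2$ is often
fractional — and the fine grades use half-open intervals
$\{0\}$, $(0,40)$, $[40,60)$, $[60,100)$, $\{100\}$ so every fractional
score bins deterministically. The coarse strata are score $\ge 60$ /
1–59 / 0, and the alternate dichotomy is score $> 50$ vs $\le 50$. Gene
symbols are compared case-insensitively after trimming.

## The knowledge base

The IC50-based potency criterion (target or immediate downstream
effector, generally < 100 nM) is a *curation* criterion: the rules file
stores already-curated drug→target sets and the software never computes
potency. Downstream-effector matching (e.g. a MEK inhibitor for upstream
BRAF/RAS alterations) is encoded by listing the upstream genes in the
inhibitor's target set — matching stays auditable data, not pathway-graph
inference. The bundled seed (`kb_seed()`, also shipped as
`inst/extdata/kb_seed.json`) covers the drugs and genes used in the
worked examples plus enough common targeted agents to drive the
simulator; real analyses are expected to extend the JSON file, which is
validated on load (referential integrity, synergy targets belonging to
both drugs, both special rules present).

## Outcome analyses

- **Disease control** = SD lasting $\ge 6$ months or PR/CR. SD still
  ongoing at < 6 months and too-early/not-evaluable rows are excluded
  from DCR denominators (they are neither success nor failure yet).
- **Contingency analysis** restricts to evaluable patients and uses the
  two-sided Fisher exact test (sum of table probabilities $\le$ the
  observed table's). Because trial reports sometimes attribute the same
  comparison to a binary logistic regression, the Wald p from that model
  is reported alongside; the Fisher value is the reference.
- **ROC cutoff selection** uses the midrank (Mann–Whitney) AUC; candidate
  cutoffs are the observed score values, the default selection maximizes
  Youden's J with ties broken toward the higher cutoff, and the
  maximal-rate-difference criterion is reported as an alternative, with
  the full per-cutoff table returned for audit.
- **Survival**: product-limit curves; the median is the earliest time the
  curve reaches $\le 0.5$ ("not reached" otherwise); log-rank tests
  across strata; Cox models use the Efron tie correction (the common
  default; the choice is immaterial for continuous-ish month scales).
- **Model building** fits one univariate model per candidate covariate
  (high score, matched vs unmatched, age $\ge 63$, sex, $\ge 2$ drugs,
  GI/hepatobiliary-pancreatic, unknown primary, breast) and enters every
  covariate with univariate $P < 0.15$ into a single multivariate model;
  entry decisions are logged in the result and asserted by tests.
  Separation or zero-variance covariates are reported per term, never
  fatal. No multiple-testing correction is applied anywhere, matching
  standard practice for these exploratory trial analyses.
- **Grade trend** computes the DC rate and KM-median PFS per fine grade
  and correlates each against the grade's ordinal index 0–4 (default) or
  the bin midpoint; the encoding is recorded in the result. Grades whose
  KM median is not reached drop out of the PFS correlation; a
  zero-variance outcome yields an undefined correlation reported as `NA`.
- **TP53 sensitivity analysis** removes every patient with at least one
  unit matched *solely* through the TP53→VEGFi rule (the provenance tag
  makes "solely" exact) and re-runs the contingency and survival
  analyses.

## Power

`power_simulation()` draws two binomial arms and applies the two-sided
Fisher test; only distinct count pairs are tested, so 10,000 replicates
take seconds. For the reference design — 25 vs 50 patients at response
probabilities 0.65 vs 0.30, $\alpha = 0.05$ — exhaustive enumeration over
all outcomes gives power 0.808, which the simulation reproduces within
Monte-Carlo error; the a-priori normal approximation
(`power_two_proportions()`) gives 0.859. The gap is real, not noise: the
exact conditional test is conservative (its true size for this design is
0.035 at nominal 0.05), so simulated Fisher power sits a few points below
the closed form, and its null rejection rate sits *below* $\alpha$ rather
than at it. Tests assert validity (never anticonservative) and agreement
with the enumeration, not agreement with the normal approximation beyond
its accuracy.

## The synthetic cohort generator

The generator emulates the *marginal* structure a treated N-of-1 cohort
exhibits, with a known ground truth per patient:

- alteration counts: negative binomial (size 3, mean 5.5) truncated to
  $[0, 15]$, giving median 5 — chosen once to match the reported median
  and range;
- fine score bins in proportions 13 : 14 : 14 : 13 : 22 over
  100 / 60–99 / 40–59 / 1–39 / 0, allocated by largest remainder (exact
  counts at the default n = 76);
- **constructive bin placement**: for each patient the generator chooses
  a matched/total unit count whose engine score lands in the intended
  bin, then draws matched genes from a catalogue of (gene, drug) pairs in
  the seed knowledge base and untargeted genes from a pool no seed drug
  or special rule touches. Scoring the cohort with the real engine
  therefore reproduces every intended bin — asserted per patient in the
  tests — rather than approximating it by rejection sampling;
- checkpoint blockade with probability 14/54 among matched patients,
  restricted to bins where the component arithmetic permits (full in the
  100% bin; half in the 60–99 and 40–59 bins, since a half component
  forces the score to $[50, 100]$);
- outcomes: disease control 0.68 vs 0.30 by score stratum
  ($\ge 60$ vs $< 60$), exponential PFS medians 11.6 vs 2.8 months and OS
  medians 18.7 vs 11.6 months, independent exponential censoring at
  0.015/month (≈ 20% censoring in the long-PFS stratum; no censoring
  proportion is reported for the real cohort, so this is a documented
  free parameter), and ≈ 8/76 of patients inevaluable for disease
  control. Optional per-grade overrides (`dc_prob_by_grade`,
  `pfs_median_by_grade`) generate linear grade–outcome maps for trend
  studies.

Two deliberate simplifications keep the construction exact: the
generator administers only one member of each synergy pair (synergy
weighting is exercised by fixtures and property tests instead), and each
simulated patient has a single genomic report. Exponential survival with
stratum-specific medians is the simplest model consistent with the
reported medians — the goal is a known truth for calibration, not
clinical realism.

### What passing tests do and do not show

The generator does **not** emulate gene co-occurrence structure,
mutational signatures, per-histology effect heterogeneity,
non-proportional hazards, informative censoring, or multi-report
heterogeneity. Passing recovery tests therefore demonstrate that the
pipeline's estimators are unbiased and correctly calibrated *under the
stated generative model* — they do not validate the biological rules
against real patients, and real-data analyses should treat the curated
knowledge base, not the statistics, as the main source of uncertainty.

## Parameter recovery and problem sizes

`recover_parameters()` simulates, scores with the real engine, and
refits: logistic log-OR for disease control, Cox log-HRs for PFS/OS,
Fisher and log-rank rejection rates. Truths are implied by the
parameters (log-OR from the two DC probabilities; log-HR =
$\log(m_\text{low}/m_\text{high})$ for exponential medians). Replicate
$r$ uses seed $+\,r$; all randomness in the package flows through one
explicit seed argument per entry point.

The calibration checks run at n = 76 with 500 replicates: at that size
the Monte-Carlo standard error of a coverage estimate is about 1
percentage point, small enough that the [93%, 97%] acceptance band on
95% CI coverage reflects the estimator rather than simulation noise
(exact enumeration puts the true Wald-logistic coverage for this design
at 0.950 and the Cox coverage near 0.956). Larger sweeps scale linearly
(~0.15 s per replicate).

## Known limitations

- The seed knowledge base is a minimal curated set; per-patient analyses
  of real cohorts will usually need additional drug records, and the
  score depends on the curation (and on the breadth of the gene panel —
  scores from different panels are not directly comparable).
- The operationalization of "same signal/pathway impact" for the
  same-gene collapse is the alteration class unless an explicit impact
  annotation is supplied; richer functional annotation is out of scope.
- Whether identical variants across tissue and ctDNA reports should be
  double-counted is ambiguous in the source convention; both readings are
  implemented (`dedupe_reports`), with per-report counting as default.
- The analysis functions assume durations in months with event flags;
  date arithmetic and interval censoring are out of scope.
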