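---
title: "Paired tumor/NAT recurrence stratification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired tumor/NAT recurrence stratification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After surgical resection of a solid tumor, recurrence risk is carried both
by the biology of the removed tumor and by the non-tumor adjacent tissue
(NAT) that stays behind — the "soil" in which a recurrence grows. This
package implements a complete paired-tissue stratification workflow:
per-protein recurrence screening in each compartment, aggregation of the
screened proteins into per-sample risk scores, dual-tissue subtyping, and
downstream characterization (differential abundance, set enrichment,
immunohistochemistry validation). Because patient-level proteomes of this
kind are rarely redistributable, the package ships a synthetic cohort
generator that reproduces the statistical structure the analysis assumes,
so every stage is exercised end-to-end by the test suite.

## Survival machinery

The survival layer is implemented in the package rather than wrapped,
because the cut-point search sits in the innermost loop of the screen and
its exact conventions (admissibility, tie-breaks, reported p-value) define
the downstream sets.

**Kaplan–Meier and log-rank.** Standard product-limit estimation with right
censoring; the two-group log-rank statistic uses the
observed-minus-expected form with the hypergeometric variance and a
chi-square reference with 1 df. With zero events the statistic is defined
as 0 and p as 1 (a logged convention, not an error).

**Cox proportional hazards.** Newton–Raphson maximization of the partial
likelihood with the Efron approximation for ties by default (minimum-value
imputation produces heavily tied markers, where Efron is distinctly more
accurate); Breslow is available by flag. Wald confidence intervals and
p-values are reported per term. Non-convergence raises an error carrying
the iteration trace. The test suite verifies coefficients, standard errors
and log-likelihoods against `survival::coxph` to ~1e-7, and the score test
at zero against the log-rank chi-square.

**Maximally selected cut-point.** `best_cutpoint()` scans every threshold
placed halfway between consecutive distinct marker values whose induced
groups both contain at least `ceiling(minprop * n)` subjects, and returns
the threshold maximizing the standardized log-rank statistic. `minprop`
defaults to 0.10, the customary floor in survival cut-point tools, and must
lie in (0, 0.5). Ties within 1e-12 of the maximum are resolved toward the
more balanced split, then the smaller threshold, so results are
deterministic. Two p-values are available:

* `logrank_p` — the naive chi-square p at the selected threshold. This is
  what best-cut-off screening conventionally reports and what the RRP
  definition below uses; it is optimistic because the threshold was chosen
  to maximize the statistic.
* `perm_p` (optional, `n_perm > 0`) — a selection-adjusted p from
  permutations of the marker, re-running the full scan each time. It is off
  by default because the screening convention is the naive p; it exists so
  users can quantify the optimism.

The null inflation this creates is real and intentional to reproduce: the
test suite demonstrates that on effect-free synthetic cohorts the fraction
of "significant" proteins at alpha = 0.05 greatly exceeds 0.05.

## Recurrence-related proteins and direction sets

A protein is a recurrence-related protein (RRP) when the log-rank p at its
best cut-point is below alpha (default 0.05, uncorrected — the screening
convention; a Benjamini–Hochberg column is reported for reference but never
used to build sets). The hazard ratio attached to each RRP comes from a
two-group Cox fit on the dichotomized marker, matching the construction of
the subtypes that follows. Direction is a pure function of the HR: above 1
is unfavorable, otherwise (including exactly 1) favorable. Per cohort the
four direction sets are tumor-unfavorable, tumor-favorable,
NAT-unfavorable and NAT-favorable, each restricted to significant proteins.
Across cohorts, sets are combined by plain intersection, and the
drug-target filter keeps proteins significantly unfavorable in at least one
cohort and significantly favorable in none.

Proteins with more than half their values at the global minimum (i.e.
mostly imputed) are screened but flagged, since their cut-points sit on a
tie plateau.

## ssGSEA and the DFS score

`ssgsea_sample()` walks the sample's genes in decreasing-expression order;
the running sum rises by the gene's normalized weight at in-set genes and
falls by 1/(number of out-of-set genes) otherwise. The enrichment score is
the sum of the running-sum deviations (the integrated single-sample form);
a classic max-deviation mode exists for comparison. Weights are
|rank|^alpha with alpha = 0.25 by default, the documented default of the
single-sample implementations in common use. Rank weights (ties averaged)
rather than raw intensities make the score invariant under any strictly
increasing per-sample transform — a property the tests assert — with a
raw-value mode available. Cross-sample range normalization is off by
default because the quantity of interest,

DFS score = ES(unfavorable set) − ES(favorable set),

is a within-sample difference; dividing both terms by a common positive
constant only rescales it. The identities that define the score (zero under
set equality, sign flip under set swap) are enforced exactly.

## Subtyping and integration

Per tissue, samples are dichotomized at the best cut-point of their DFS
scores against the recurrence endpoint. Label "2" (T2, NAT2) is assigned to
the side of the threshold with the excess of observed events, so the label
tracks prognosis rather than the sign convention of the score. The
integrated label is the plain product of the two per-tissue calls (T1-NAT1
… T2-NAT2); patients missing one tissue keep their single-tissue call and
are excluded from integration only. Within clinical strata
(`stratified_km()`), the globally chosen score cut-off is reused rather
than re-optimized per stratum — re-optimizing would compound the selection
optimism and make subtype membership stratum-dependent.

Group comparisons of clinical covariates use the Wilcoxon rank-sum test for
numeric covariates and the chi-square test for categorical ones, with the
standard continuity correction for 2×2 tables and Fisher's exact test when
any expected cell is below 5 (logged). Constant covariates return p = 1
with a warning.

## Differential abundance and enrichment

`groupwise_diff()` compares two sample groups on log2 abundances with
Welch's t-test and reports the linear-scale fold change
(ratio of geometric means). Classification follows FC and p jointly: down
means FC < 1 and p < alpha, up means FC > 1 and p < alpha. A lightweight
variance-moderation mode (equal-weight shrinkage of each per-protein
variance toward the across-protein median) is provided for users who want
moderated-statistic behavior without the full hierarchical model; the plain
Welch test is the default because its sampling theory is exact and the
desk-scale simulations are well powered without shrinkage.

`ora_test()` is the hypergeometric upper tail (enumerated over the
achievable overlap range), restricted to the measurement universe.
`preranked_gsea()` is the classic weighted Kolmogorov–Smirnov enrichment
(weight |stat|^1, maximum deviation), with significance and normalization
by gene-label permutation: NES is the ES divided by the mean |ES| of
same-sign permutations, and the p-value uses the +1-corrected same-sign
tail. Gene permutation was chosen over phenotype permutation because the
treatment arms simulated here have 14 samples each, too few for a stable
phenotype null; the permutation count and seed are explicit arguments.

## IHC composite scoring

The composite score multiplies staining intensity (0–3) by the
percent-positive extent bin (0 = 0%, 1 = (0,25)%, 2 = [25,50)%,
3 = [50,75)%, 4 = [75,100]%), giving the achievable products
{0,1,2,3,4,6,8,9,12} with range 0–12. Two boundary cases the printed bins
leave open are closed deterministically: 100% belongs to bin 4 (a fully
positive core must be scoreable) and any positivity below 1% belongs to
bin 1 (positivity above zero maps to the lowest positive bin). Ingest
rejects scores outside the achievable set. Dual-tissue stratification
dichotomizes each tissue's scores at the best cut-point by default (a fixed
threshold flag exists, since published scoring schemes sometimes fix the
split), and integrates paired patients into four groups. Two-reader
consensus is the per-core mean rounded half-up, reported together with the
exact-agreement fraction and a linearly weighted kappa on the 0–12 scale.

## The synthetic generator

`generate_cohort()` draws, per tissue, log2 abundances that are standard
normal around a location of 20 (MaxQuant-style log2 intensity scale), with
planted sets sharing a patient-level block factor at correlation
`pathway_block_correlation` (default 0.5 — the within-pathway correlation
range typical of co-regulated protein complexes). The patient's log
relative hazard sums, over planted sets, ±`log_hr_per_sd` times the
standardized set-mean abundance (positive for unfavorable sets, negative
for favorable). DFS times are exponential with hazard
`baseline_hazard × exp(lp)`; censoring is an independent exponential race
plus an administrative cap. Defaults: 200 patients, 150 proteins, four
15-protein planted sets at HR 2.5 per SD, baseline median DFS 30 months,
censoring rate 0.01/month, 60-month cap — giving event fractions around
55–60%, in the range surgical HCC series report. Missingness is
masked completely at random at 5% by default; an MNAR flag concentrates
dropout on the low-abundance tail, which is the physically realistic
pattern, but MAR is the default so that imputation-sensitivity tests have a
clean baseline. OS is drawn from the same linear predictor at half the
baseline hazard.

What the generator deliberately does **not** emulate: batch structure,
intensity-dependent variance, correlated censoring, non-proportional
hazards, and real pathway topology. Tests passing on these cohorts
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every artifact of real proteomes.

`generate_treatment_study()` shifts a chosen effect set by a log2 fold
change in the treated arm (14 samples per arm by default, matching a
realistic animal-study size). `generate_ihc_cohort()` draws paired ordinal
staining scores from a shared latent severity, with tumor category
distributions shifted upward (tumor mean composite score ≈ 3 vs ≈ 1.2 in
NAT) and recurrence hazard proportional to `exp(log_hr × severity)`.

All generators save and restore the caller's RNG state and are pure
functions of their spec and seed; the determinism tests assert bitwise
reproducibility.

## Processing order and other numerical choices

* Quantile normalization precedes minimum-value imputation by default (the
  natural reading of "normalized … and missing values were imputed");
  `impute_first = TRUE` swaps the order. Normalization is per matrix, i.e.
  per tissue compartment per cohort, configurable by simply passing a
  combined matrix.
* Quantile-normalization ties receive the mean of the normalized values at
  the tied ranks (average-ties policy), which makes the operation
  idempotent; this is `limma::normalizeQuantiles(ties = TRUE)`.
* The CLR transform refuses nonpositive values unless a pseudo-count (half
  the smallest positive value) is explicitly enabled, since silently
  shifting data changes every downstream ratio.
* Alpha is 0.05 everywhere by default and recorded in the run manifest;
  both tumor and NAT screens use the DFS endpoint unless configured
  otherwise.
* Problem sizes in the test suite and acceptance script are desk-scale by
  design: cohorts of 100–240 patients and 30–150 proteins, 20-seed
  replications for recovery rates, 2,000 subjects for Cox calibration.
  They were chosen as the smallest sizes at which the asymptotic checks
  (3-sigma bands, 5% HR tolerance) are comfortably identified.

## Known limitations

* The naive log-rank p at an optimized threshold is anti-conservative; the
  permutation alternative is provided but not the default, by design.
* The Cox implementation covers fixed covariates only — no time-varying
  covariates, stratified baselines or competing risks.
* ssGSEA scores here feed scoring and ranking, not significance testing;
  there is no permutation null for per-sample ES.
* The pipeline treats each tissue's matrix as complete after imputation;
  proteins absent from a tissue are simply not screened there.
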