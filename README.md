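# natrecur

Postoperative recurrence risk in solid tumors is carried both by the
resected tumor and by the non-tumor adjacent tissue (NAT) left in the
patient. `natrecur` implements a paired tumor/NAT proteomic
recurrence-stratification workflow for biostatisticians and computational
proteomics groups: it screens each tissue compartment for
recurrence-related proteins, converts the screened sets into per-sample
risk scores, calls dual-tissue prognostic subtypes, and validates the
stratification with composite immunohistochemistry (IHC) scoring — all
runnable end-to-end on a built-in synthetic cohort generator, so no
patient-level data are required to exercise any stage.

## The statistics at the core

* **Recurrence-related protein (RRP) screen.** For each protein with
  abundance *x*, the *maximally selected log-rank cut-point* scans every
  admissible threshold *μ* (both groups ≥ `ceiling(minprop·n)`, `minprop`
  = 0.1) and selects the one maximizing the standardized log-rank statistic
  for disease-free survival (DFS). Proteins with log-rank p < 0.05 are
  RRPs; the hazard ratio comes from a Cox proportional-hazards fit
  h(t) = h₀(t)·exp(β·1[x > μ]) on the dichotomized marker (Efron ties).
  HR > 1 ⇒ *unfavorable*, otherwise *favorable*, yielding four direction
  sets per cohort (tumor/NAT × unfavorable/favorable).
* **DFS score.** Per sample, single-sample GSEA (weighted
  Kolmogorov–Smirnov running sum, weight |rank|^0.25, integrated form)
  scores each direction set, and
  `DFS score = ES_unfavor − ES_favor`.
* **Dual-tissue subtypes.** Each tissue's DFS scores are dichotomized at
  their own best cut-point; label 2 (T2/NAT2) always marks the
  higher-hazard side. The integrated four-group label (T1-NAT1 … T2-NAT2)
  is the product of the two calls.
* **Downstream characterization.** Welch differential abundance with
  FC/p classification, hypergeometric over-representation, preranked GSEA
  with gene-permutation NES, cross-cohort set intersection and the
  drug-target filter (unfavorable in ≥ 1 cohort, favorable in none).
* **IHC validation.** Composite score = intensity (0–3) × extent bin
  (0–4), range 0–12 over the achievable products {0,1,2,3,4,6,8,9,12};
  per-tissue cut-point stratification and four-group integration.

The survival machinery (Kaplan–Meier, log-rank, Cox with Efron/Breslow
ties, cut-point search) is implemented in the package and cross-checked
against the `survival` package in the test suite.

## Worked example

```r
library(natrecur)

co <- generate_cohort(cohort_spec(seed = 1))   # 200 patients, 150 proteins
res <- run_cohort_analysis(list(tumor = co$tumor, nat = co$nat,
                                clinical = co$clinical, outdir = "demo_out"))

head(res$rrp_tumor[, c("protein_id", "cutpoint", "hr", "p", "direction")], 3)
#>   protein_id cutpoint        hr            p direction
#> 1      P0019 19.88300 0.2976628 5.473152e-09 favorable
#> 2      P0024 19.65022 0.3475443 6.852680e-08 favorable
#> 3      P0027 19.56663 0.3645224 3.781256e-07 favorable

table(res$subtypes$integrated)
#> T1-NAT1 T1-NAT2 T2-NAT1 T2-NAT2
#>      87      42      36      35

cl <- co$clinical
i <- match(res$subtype_nat$sample_id, cl$sample_id)
cox_fit(cbind(nat2 = as.numeric(res$subtype_nat$subtype == "NAT2")),
        cl$dfs_time[i], cl$dfs_event[i])
#> Cox proportional hazards (efron ties), n = 200, events = 100
#>   term coef    hr ci_low ci_high     se     z         p
#> 1 nat2 1.93 6.889  4.457   10.65 0.2221 8.688 3.675e-18
```

The screen reads the synthetic cohort's planted biology back out: the top
tumor RRPs are planted favorable proteins (HR ≈ 0.3 at their best
cut-points), and the NAT2 subtype — built only from NAT protein scores —
carries a large recurrence hazard (HR ≈ 6.9 here) relative to NAT1.
`demo_out/` receives the RRP tables, the four direction sets (GMT),
per-sample scores, subtype calls, covariate tests, and a JSON manifest
recording every decided default and seed.

The `analysis/` directory holds the numbered workflow the package was
built around — simulate three cohorts, screen and intersect them, test
NAT-subtype complementarity within clinical strata, run enrichment, the
IHC validation and the treatment-arm contrast — each a thin driver over
the exported functions, writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_screen_rrps.R
# ... through 06
```

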