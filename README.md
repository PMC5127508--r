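# ironsig

Survival analysis of **aberrant iron-regulatory gene expression in diffuse
gliomas**. Dysregulated iron handling (uptake via HFE/TFRC, storage,
export, heme synthesis, metalloreduction by the STEAP family) is
increasingly implicated in tumor progression, and small panels of
iron-metabolism genes have been proposed as prognostic signatures in
lower-grade glioma (WHO II–III) and glioblastoma. `ironsig` implements the
full analytical workflow for asking whether *extreme* (aberrant) expression
of such genes stratifies patient survival, and for distilling a compact
prognostic signature out of a larger candidate panel. It is aimed at
computational biologists and biostatisticians working with
cBioPortal-style expression + clinical exports.

## What it computes

**Aberrance calling.** Each gene is z-scored across all samples,
`z = (x − mean)/sd`, and a (gene, sample) cell is *aberrant* when
`|z| > 2` (strict). A sample is aberrant *for a panel* when at least one
panel gene is aberrant — this binarizes the cohort for survival
comparison.

**Group comparison.** Kaplan–Meier product-limit curves
`Ŝ(t) = Π_{tᵢ≤t} (1 − dᵢ/nᵢ)`, median survival (smallest `t` with
`Ŝ(t) ≤ 0.5`), and the unweighted two-group log-rank test
`χ² = (ΣO − ΣE)²/ΣV` with hypergeometric variance, all censoring-aware.

**Feature selection.** Elastic-net penalized Cox proportional hazards,
minimizing

```
−(1/n)·ℓ(β) + λ(α‖β‖₁ + ½(1−α)‖β‖₂²)
```

where `ℓ` is the Breslow partial log-likelihood, fit by cyclic coordinate
descent with IRLS outer steps (compiled in C++), warm starts along a
log-spaced λ path, and 10-fold cross-validation of the
Verweij–van Houwelingen partial-likelihood deviance. Genes with nonzero
coefficients at the deviance-minimizing λ are the selected signature;
`exp(x·β)` gives per-patient relative risks.

**Predictor benchmark.** A leave-one-out 1-nearest-neighbor predictor
(Euclidean distance on panel z-scores; prediction = neighbor's observed
survival) against a random-selection baseline (uniform draw from the other
patients' survival times, 100 replicates). Performance is the median of
absolute residuals `|Y_p − Y_o|`; predictors are compared by Mann–Whitney
U (exact for small samples) and Pearson correlations (`r₁`:
observed vs predicted; `r₂`: relative risk vs survival, expected negative).

**Greedy refinement.** Starting from the selected panel, the gene whose
single-gene aberrance split maximizes the absolute median-survival
difference is chosen first; each subsequent step adds the gene maximizing
the difference of the grown any-aberrant split, with every log-rank test
counted toward a Bonferroni familywise correction.

**Synthetic cohorts.** A seeded generator produces expression (standard
normal with planted outliers) and right-censored exponential survival
under proportional hazards, with signals planted either as linear
per-z-unit log hazard ratios or as hazard multipliers attached to the
aberrance state itself, plus grade strata and an IDH1 flag. Presets
emulate the structure of TCGA LGG (275 samples, ~79% censored) and GBM
(135 samples, ~77% deceased) cohorts, so every stage is testable against
known ground truth.

## Worked example

```r
library(ironsig)

cfg <- cohort_preset("lgg", censor_time = 120,
                     planted_effects = c(ALAS2 = 0.7, FECH = -0.6, LCN2 = 0.5),
                     aberrant_hazard = c(HFE = 6, STEAP3 = 4, TMPRSS6 = 3,
                                         SFXN1 = 3, TFRC = 2.5, UROS = 2,
                                         SLC11A2 = 2, STEAP4 = 2),
                     seed = 42)
cohort <- simulate_cohort(cfg)

z      <- compute_zscores(cohort$expression)
ab     <- call_aberrant(z, threshold = 2)
labels <- panel_aberrance(ab, iron_panel("selected8"))

compare_by_aberrance(cohort$clinical, labels, grades = c("II", "III"))
#> aberrant (n=80): median 14.35 months | non-aberrant (n=195): median 69.70 months
#> log-rank chi2 = 29.310, p = 6.166e-08

cv <- coxnet_cv(z, cohort$clinical$os_months, cohort$clinical$event,
                panel = iron_panel("iron61"), alpha = 0.95, nfolds = 10,
                seed = 42)
head(cv$selected, 5)
#>     gene coefficient
#> 1  ALAS2  0.43919373
#> 2   FECH -0.35822867
#> 3   LCN2  0.21586062
#> 4   UROS  0.04159242
#> 5 NDFIP1  0.02770798

greedy_select(ab, cohort$clinical, iron_panel("selected8"))
#> greedy_trace: 8 step(s), 36 tests, Bonferroni alpha = 0.001389
#>  step    gene objective objective_type logrank_p aberrant_fraction_uncensored
#>     1  STEAP3     53.21         median 7.307e-11                       0.0625
#>     2    UROS     55.11         median 1.210e-15                       0.1146
#>     3     HFE     59.03         median 4.891e-13                       0.1719
#>     ...
#>     8 SLC11A2     55.35         median 6.166e-08                       0.3646
```

Reading the output: samples aberrant in the eight-gene signature live a
median 55 months less than the rest (log-rank p ≈ 6e-8); the
cross-validated Cox fit recovers the three genes that carry planted linear
effects with the correct signs; and the greedy trace shows the
characteristic trade-off — the single best gene gives the largest split on
a small aberrant fraction (6% of uncensored patients), while growing the
panel raises coverage (36%) at a similar split. `run_full_analysis()`
assembles all of this (plus the predictor benchmark and per-grade and
IDH1-stratified comparisons) into one report object.

Panels: `iron_panel("selected8")` is the eight-gene signature (STEAP3,
HFE, TMPRSS6, SFXN1, TFRC, UROS, SLC11A2, STEAP4). The shipped 61-gene
iron-metabolism panel and 16-gene IRGS are curated stand-ins (files marked
`_synthetic`) since the published lists are not available in
machine-readable form; any panel can be supplied as a one-symbol-per-line
file.

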