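# cafsig

Gene-signature modelling of immunotherapy response from cancer-associated
fibroblast (CAF) marker genes, with spatial cell-type proximity analysis
and a full verification battery — exercised end-to-end on synthetic data
with known ground truth.

## Who this is for

Tumour-immunology and computational-biology groups who want to (a) build a
transcriptomic predictor of immune-checkpoint-inhibitor (ICI)
**non-response** from a candidate gene list across multiple bulk cohorts,
(b) quantify how close CAF subtypes sit to other cell populations in mapped
tissue sections, and (c) verify both with standard clinical-prediction
diagnostics. Everything runs on plain matrices and data frames — no
external downloads are required, because the package ships generators that
emulate multi-cohort expression (planted responder-associated genes, batch
shifts) and tissue sections (planted proximity orderings).

## The core methods

**Caf.Sig score.** For sample *s* and gene set *S*, the single-sample
enrichment is a rank-weighted running sum: genes are ordered by expression
and the score accumulates the difference between the weighted in-set CDF
(weight = magnitude rank^α, α = 0.25 by default) and the uniform out-of-set
CDF. The signature score is

    Caf.Sig(s) = ES(s, up-regulated in non-responders) − ES(s, down-regulated)

so higher values predict non-response.

**Ensemble model search.** A manifest of feature-selection × classifier
combinations (9 selector families × 12 classifiers + 5 embedded models =
113 by default) is fitted on a training cohort group: selector on pooled
training data, models with < 5 genes omitted, hyperparameters tuned by
leave-one-out cross-validation, AUC computed in every cohort. Combinations
are ranked by the mean of the training/internal/external group-mean AUCs;
the top one becomes the Caf.Sig model, and its per-sample predictions are
the Caf.Sig risk scores. Per-gene effects are summarized by univariate
logistic odds ratios pooled across cohorts by fixed-effect (or
DerSimonian–Laird) meta-analysis.

**Spatial k-distance + RRA.** For each reference-type cell (e.g. iCAF), the
k-distance to a target type is the mean distance to its k nearest target
cells in the same section. Types are ranked nearest-first per section and
integrated across sections with robust rank aggregation: ρ = min over k of
the binomial tail P(Bin(m, r₍k₎) ≥ k), Bonferroni-corrected by the number
of types. Responder/non-responder contrasts use a Wilcoxon rank-sum test on
pooled per-cell distances.

**Evaluation.** ROC/AUC (trapezoid = Mann–Whitney pair count), confusion
matrices at fixed or Youden thresholds, calibration tables, decision-curve
net benefit NB(pt) = TP/N − (FP/N)·pt/(1−pt), and univariate/multivariate
logistic comparison.

## Worked example

```r
library(cafsig)

# three synthetic cohorts with a planted 8-up/8-down signature
sim <- simulate_cohorts(n_cohorts = 3, samples_per_cohort = 40, n_genes = 60,
                        n_up = 8, n_down = 8, effect_size = 2, seed = 7)
fit <- caf_sig(sim$cohorts,
               split = list(training = "cohort01", internal = "cohort02",
                            external = "cohort03"),
               manifest = reduced_manifest("fast8"), seed = 7)
print(fit)
#> Caf.Sig ensemble model search
#>   combinations evaluated: 8 (0 omitted)
#>   best combination: embedded+lasso (11 model genes)
#>   group AUC  training 1.000 | internal 1.000 | external 1.000
#>   mean AUC: 1.000
```

The planted effect (2 SD on 16 genes) is strong, so every group AUC
saturates; the embedded lasso wins the parsimony tie-break with an
11-gene model. Risk scores for new samples are oriented so that higher
means predicted non-responder:

```r
scores <- predict(fit, sim$cohorts$cohort03$expr)
round(head(scores, 4), 3)
#> cohort03_S001 cohort03_S002 cohort03_S003 cohort03_S004
#>        -5.335        -3.400        -5.877         4.577
roc_auc(scores, sim$cohorts$cohort03$labels)
#> ROC curve: 41 points, AUC = 1.0000
```

Spatial proximity with a planted contrast (CD8_Tex cells placed near iCAFs
in non-responder sections, dispersion sigma 2 vs 12):

```r
tt <- data.frame(type = c("CD8_Tex", "Tem_Teff"),
                 sigma_responder = c(12, 2), sigma_nonresponder = c(2, 12))
sp  <- simulate_sections(tt, seed = 7)
kd  <- k_distance(sp$cells, "iCAF", k = 2)
rra_aggregate(rank_by_proximity(kd[kd$group == "NR", ]))
#>       type     rho corrected position
#> 1  CD8_Tex 0.03125    0.0625        1
#> 2 Tem_Teff 1.00000    1.0000        2
cmp <- compare_groups(kd, "CD8_Tex")
#> median NR 5.36 vs R 7.97, p = 1.54e-11
```

CD8_Tex is ranked nearest to iCAFs in every non-responder section
(ρ = 0.5⁵ = 0.03125), and its k-distance is significantly shorter in
non-responders — the planted structure, recovered.

`run_pipeline(demo_config())` chains all stages (simulate → search →
score → meta-analysis → spatial → evaluate) and writes leaderboard, risk
scores, RRA tables, evaluation reports and a reproducibility manifest to
one directory; rerunning a config reproduces identical bytes.

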