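---
title: "Methods: CAF-signature response modelling, spatial proximity and verification"
author: "cafsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAF-signature response modelling, spatial proximity and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafsig)
```

# The scientific problem

Cancer-associated fibroblasts (CAFs) shape the tumour microenvironment and
modulate the efficacy of immune checkpoint inhibition (ICI). `cafsig`
implements, as a tested and reusable pipeline, the analysis pattern in which
CAF marker genes are turned into a transcriptomic predictor of *not*
responding to immunotherapy:

1. single-sample scoring of gene signatures, and the **Caf.Sig score** —
   the enrichment of genes up-regulated in non-responders minus the
   enrichment of genes down-regulated in non-responders;
2. an **ensemble model search** pairing feature-selection methods with
   classifiers, evaluated by leave-one-out cross-validation (LOOCV) and
   cross-cohort AUC, with the top average-AUC combination elected as the
   final model;
3. **spatial proximity analysis** of cell types around a reference CAF
   subtype (inflammatory CAFs, iCAFs) via k-nearest-neighbour distances,
   per-section rankings and robust rank aggregation (RRA);
4. a **verification battery**: ROC/AUC, confusion matrices, calibration
   tables, decision-curve analysis, univariate/multivariate logistic
   comparison, and per-gene odds-ratio meta-analysis.

Every stage runs end-to-end on synthetic data with known ground truth, so
the package's claims are verifiable without any external download.
Throughout, the positive class is the **non-responder (NR)**: all risk
scores are oriented so that higher values predict failure to respond.

# Single-sample scoring

## Rank-weighted running sum

For one sample, genes are ordered by expression (descending). Walking down
the ordered list, two empirical CDFs are accumulated: the in-set CDF, where
a set gene at magnitude rank $r$ contributes weight $r^\alpha$ (normalized
by the total in-set weight), and the uniform out-of-set CDF. The enrichment
score is the sum of their difference over all positions:

$$ES = \sum_{i=1}^{N}\left[\frac{\sum_{j \le i,\, j \in S} r_j^\alpha}
{\sum_{j \in S} r_j^\alpha} - \frac{\#\{j \le i,\, j \notin S\}}{N - |S|}\right].$$

Only ranks enter the statistic, so any strictly increasing transform of one
sample's expression leaves its score unchanged — important when cohorts are
on different log2 pipelines. Choices:

* **alpha** defaults to 0.25, the convention of the cited single-sample
  enrichment implementation; it is exposed because alpha = 1 is also in
  common use.
* **ties** receive average ranks, with a deterministic secondary ordering
  by gene id, so scores are reproducible to the bit.
* **normalization** (dividing all scores by the global max − min across
  samples) is off by default: raw enrichment keeps the test oracles exact,
  and the subtraction in the Caf.Sig score makes the shared scale factor
  irrelevant for ranking samples within a cohort.

The Caf.Sig score is then
`score(up-regulated set) − score(down-regulated set)`, computed with the
same scorer and parameters for both sets. It is antisymmetric under
swapping the sets and exactly zero when they coincide — both properties are
tested, for this scorer and for the mean-module alternative.

The mean-module scorer (`mean_module_score`) is the light-weight
complement: mean expression of the set minus the mean of control genes
drawn from 25 average-expression bins (seeded sampling, controls exclude
set genes). Of the seven scoring algorithms the source analysis used for
concordance checks, these two span the rank-based and mean-based families;
the remainder are out of scope.

## Single-cell QC

`qc_filter` removes a cell iff (strictly) UMI > 40,000, genes < 500,
genes > 5,000, or mitochondrial percentage > 20. The inequalities are
strict, matching the stated criteria literally, so boundary cells (exactly
20% mitochondrial reads, exactly 500 genes) survive; the removal log names
every rule each removed cell triggered.

# The ensemble model search

## Data model and preprocessing

Cohorts are genes × samples log2 matrices with R/NR labels, assigned to
three groups: training, internal validation, external validation. The
cross-cohort gene space is the intersection; each cohort is gene-wise
standardized (mean 0, SD 1 within cohort) before fitting. This per-cohort
standardization is the package's deliberate stand-in for heavier empirical
Bayes batch correction: it removes exactly the additive per-(cohort, gene)
shifts the synthetic generator plants, and makes coefficients comparable
across cohorts. It does not address gene–gene covariance differences
between platforms, which is a known limitation for real data.

## The 113-combination manifest

Twelve classifier families are registered: random forest, lasso, ridge,
elastic net, stepwise GLM, componentwise linear boosting, linear
discriminant analysis, partial-least-squares logistic, slow-learning
boosted trees, extreme gradient boosting, linear SVM and naive Bayes. Nine
of the registered methods can act as feature selectors (lasso, elastic
net, ridge-coefficient ranking, forward stepwise, componentwise-boosting
importance, random-forest importance, boosted-tree importance, PLS
loadings, recursive feature elimination with a linear margin classifier).
The default manifest is the 9 × 12 product (108) plus the five standalone
embedded models that perform their own selection (lasso, ridge, elastic
net, boosted linear, stepwise GLM): **113 combinations**. The count is a
config contract — the manifest is an explicit, buildable object
(`build_grid(algorithm_registry())`), not an emergent property, because no
published derivation of the number from the twelve algorithms exists.

Componentwise linear boosting and the NIPALS partial-least-squares
transform are implemented in-package (each ~30 lines, deterministic);
boosted trees use xgboost with shallow trees (depth 2, learning rate 0.05)
for the slow-learning family and depth 3 at rate 0.3 for the aggressive
family. Rank-only selectors keep the top `top_k` genes (default 20,
configurable); sparsity-based selectors choose their own support size.

## Fitting protocol

For each combination:

1. the selector is fitted once on the pooled training group;
2. models with fewer than five genes are **omitted** (the published
   fewer-than-five-model-genes rule), with the reason recorded;
3. classifier hyperparameters are tuned by LOOCV on the training pool,
   chosen to maximize held-out AUC. A single LOOCV pass scores every
   candidate parameter set (path-based learners such as glmnet serve all
   candidate penalties from one fit per fold). Classifiers with a single
   configuration are fitted directly — there is nothing to tune — but the
   LOOCV pass still runs to provide held-out training scores;
4. the model is refitted on the full training pool and AUC is computed in
   every cohort. **Training-group cohorts are scored with the LOOCV
   held-out predictions**, not resubstitution: flexible learners
   (random forest, boosting) interpolate their training data, so
   resubstitution AUC would saturate at 1.0 and make the leaderboard's
   training column vacuous. Validation cohorts use the refitted model.

The leaderboard ranks combinations by the mean of the three group-mean
AUCs; exact ties go to the model with fewer genes, then lexicographic
combination id (parsimony first). Risk scores are the linear predictor for
linear models and the predicted non-response probability for non-linear
ones; both are rank-equivalent inputs to AUC, and the orientation (higher =
non-responder) is recorded on the returned vector.

An optional `strict` mode nests feature selection inside every LOOCV fold
(anti-leakage). It is not the default because the default mirrors the
train-then-validate narrative this framework reproduces: selection leakage
inflates only the training column, and model election is driven mainly by
the untouched internal/external columns.

## Per-gene odds-ratio meta-analysis

For each model gene, non-response is regressed on the gene's standardized
expression within each cohort (univariate logistic); per-cohort log odds
ratios are pooled by inverse-variance fixed-effect weighting (default) or
DerSimonian–Laird random effects, via `metafor`. Standardization makes the
OR a per-SD effect comparable across genes; it can be disabled, in which
case the OR for a 0/1 gene reduces exactly to the 2×2 cross-product ratio
(a tested identity). Cohorts with perfect separation are excluded with a
warning. P-values are Benjamini–Hochberg adjusted across genes in the
report; the pooling default is fixed-effect because with a handful of
cohorts the between-cohort variance estimate of random effects is unstable.

# Spatial proximity

For every reference-type cell (iCAFs in the motivating analysis), the
k-distance to a target type is the mean Euclidean distance to its k nearest
target cells *within the same section* — no cross-section geometry exists.
Per (section, type), the summary is the median over reference cells;
sections rank types nearest-first (average ranks on ties); missing
(section, type) entries — fewer than k target cells — conservatively
receive the section's worst rank so the aggregation matrix stays
rectangular.

Robust rank aggregation scores each type by normalizing its section ranks
to $(0, 1]$, sorting them, and taking the minimum over $k$ of the binomial
order-statistic tail

$$p_k = \Pr\!\big(\mathrm{Bin}(m, r_{(k)}) \ge k\big),$$

the probability that at least $k$ of $m$ uniform ranks fall at or below the
observed $k$-th smallest. The reported $\rho$ is $\min_k p_k$, with a
Bonferroni factor equal to the number of types compared (the usual
correction for taking a minimum over order statistics). Small corrected
$\rho$ marks a type consistently near the reference across sections. The
implementation is checked three ways: closed-form constructions
($\rho = 0.1^5$ for a type ranked first of ten in five sections), a
Monte-Carlo oracle that re-estimates each tail from simulated uniforms, and
a 2000-replicate uniform-permutation null confirming the corrected score's
type-I error stays at or below nominal.

Responder/non-responder contrasts (`compare_groups`) pool per-cell
k-distances within each group and use a two-sided Wilcoxon rank-sum test.
Pooling ignores within-section correlation, which anticonservatively
narrows the test under strong section effects; the synthetic experiments
plant the contrast at the cell level, where pooling is appropriate.

# Synthetic data: what it emulates, and what it does not

`simulate_cohorts` draws per-gene baselines from N(6, 1) on the log2 scale,
adds one additive N(0, `batch_sd`) shift per (cohort, gene), plants `n_up`
genes shifted $+$`effect_size`·SD and `n_down` genes $-$`effect_size`·SD in
non-responders, and adds N(0, `noise_sd`) noise. Gaussian-on-log2 matches
log2-transformed bulk inputs; batch shifts are additive because that is the
component per-cohort standardization is claimed to remove — the generator
and the preprocessing are deliberately matched so the pipeline's batch
claim is falsifiable. Defaults (5 cohorts × 100 samples, 200 genes, 20 up +
20 down, effect 1.5 SD, `batch_sd` 0.5, `noise_sd` 1, half non-responders)
are the package's standing study conditions; published cohort sizes are
cited rather than printed in the source analysis, so 100 samples per cohort
is a free but realistic choice for ICI bulk cohorts.

What the generator does **not** emulate: count noise, library-size and
dropout effects of real scRNA-seq, gene–gene correlation, and non-additive
batch structure. Passing recovery tests therefore demonstrates internal
correctness of the search machinery — selection, tuning, ranking,
omission — not performance on real cohorts.

One consequence of the stated conditions is worth recording: forty
independent genes at effect 1.5 SD give an aggregate class separation near
$\sqrt{40} \times 1.5 \approx 9.5$ SD, so many combinations reach AUC
exactly 1.0 in all three groups and the parsimony tie-break elects a
compact model (typically a top-20 importance selector whose genes are all
planted). A compact winner is correct behaviour — precision 1.0 — but its
recall against the 40-gene truth is bounded by its size, while the
sparsity-based selectors further down the (tied) leaderboard carry recall
0.75–0.97. Recovery should therefore be judged jointly by the external AUC
and by the precision of the elected genes, not by recall alone.

`simulate_sections` is a parent–offspring (Neyman–Scott-like) process:
reference cells uniform in the box, each target cell at a uniformly chosen
reference cell plus isotropic Gaussian displacement with a type- and
group-specific sigma, clipped to the box. Sigma ordering is the planted
proximity truth. Because each parent receives on average one offspring per
target type, the dispersion signal concentrates in the *first* neighbour
distance; the proximity experiments therefore use k = 2, while k = 10
remains the package default for real mapped data (the convention of the
cited mapping tool). This choice follows from the generator's structure,
not from the recovery targets.

`simulate_cell_qc_table` plants violators that exceed exactly one QC rule
each, with all clean cells comfortably inside every threshold, so the
filter's removals can be compared to truth cell-by-cell.

# Numerical and reproducibility choices

* All randomness flows through one integer seed per call; internal
  sub-seeds are derived per combination id, and `.Random.seed` is saved and
  restored so package calls never disturb the caller's RNG.
* Stochastic learners run single-threaded (xgboost `nthread = 1`), making
  the full pipeline byte-reproducible; the demo pipeline is asserted to
  rerun to identical CSV bytes.
* ROC curves sweep unique scores with simultaneous steps on ties; the
  trapezoid AUC equals the Mann–Whitney pair count with half-credit ties to
  ~1e-12 (floating-point summation order is the only difference).
* Decision curves use the net-benefit definition
  $NB(p_t) = TP/N - (FP/N)\, p_t/(1-p_t)$ on a 0.01–0.99 grid; $p_t = 1$
  is undefined and excluded.
* The confusion-matrix prediction rule is score ≥ threshold (inclusive);
  the reporting threshold defaults to the Youden-optimal point, with any
  fixed threshold available.
* Degenerate inputs have defined behaviour: constant samples warn and fall
  back to the deterministic tie order; constant genes standardize to zero
  rather than NaN; single-class test cohorts yield missing AUC and are
  excluded from group means; all-omitted searches error.

# Problem sizes used by the shipped experiments

The recovery experiment runs 5 cohorts × 100 samples × 200 genes with a
20-combination manifest spanning all nine selectors; the null-calibration
experiment repeats the same data shape 20 times with no planted effect
under an 8-combination linear-learner manifest (replicate-heavy, so the
fast subset keeps the experiment proportionate); the spatial experiment
uses 100 replicates of 5 + 5 sections with 50 cells per type. These sizes
are the package's standing choices for its own verification experiments
and are stated here so they can be scaled in either direction knowingly.

# Known limitations

* Per-cohort standardization is not a substitute for full batch
  correction on real multi-platform data.
* The LOOCV training estimate is slightly pessimistic at small n (the
  held-out score is anticorrelated with its fold's training set); at the
  package's default sizes the bias is well under 0.03 AUC.
* The Wilcoxon group contrast treats cells as exchangeable across
  sections.
* No survival modelling, nomograms, ligand–receptor inference or
  single-cell-to-spot mapping: mapped coordinates and labels are inputs,
  not outputs, of this package.
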