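---
title: "Serum metabolome screening analysis: models, parameters and design choices"
author: "metabscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum metabolome screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`metabscreen` analyses targeted serum metabolomics from lung-cancer
screening: two independent cohorts (a large training cohort, MOLTEST, and a
small validation cohort, SMAC), three participant groups (Ctr — no lung
alterations, LN — benign nodules, LC — lung cancer), and a fixed 408-analyte
panel in ten classes. Because such patient-level data are not publicly
distributable, the package carries a first-class synthetic generator whose
defaults define the study conditions, and every downstream stage is
specified, tested and calibrated against that generator.

The pipeline order is fixed and enforced: missingness partition → kNN
imputation → truncated-normal below-LOD replacement → log2 → empirical-Bayes
batch correction → statistics / classification. Imputation happens before
batch correction, and class aggregation uses the linear scale after
replacement.

# The synthetic two-cohort generator

Concentrations are log-normal per analyte. On the log2 scale a cell is

$$y_{as} = b_a + \beta_{g(s)a} + \gamma_{a,p(s)} + u_{s,c(a)} +
           \delta_{a,p(s)}\,\varepsilon_{as}$$

* $b_a \sim N(m_c, \tau_c^2)$ — per-analyte baseline drawn from class-level
  hyperparameters. The class log2 means (CE 7.6, hexose 12.3, amino acids
  5.0, PC/LPC 2.7, DG/TG 3.5, AC 1.5, SM 1.7, amines 2.0, in log2 µM) were
  chosen so that the expected aggregate composition matches a serum
  lipidome: cholesteryl esters slightly over half of total lipid mass,
  choline phospholipids about a quarter, glycerides about 14%, hexose near
  5 mM. The within-class spread $\tau_c$ (0.6–1.2) and residual SDs
  (0.25–0.45, i.e. roughly 20–35% CV) are package defaults: real kit data
  report no within-class dispersion to copy.
* $\beta$ — planted group effects (log2 fold changes vs Ctr), each scoped to
  one cohort or both. The default spec plants the qualitative pattern the
  analysis is designed to detect: four lipids (LPC(18:0), PC(32:3),
  DG(39:0), CE(20:5)) shifted −0.45 in LC in *both* cohorts, and a
  triglyceride shift of opposite sign per cohort (−0.25 / +0.25). LN is left
  at baseline: the screening setting expects benign nodules to resemble
  controls.
* $\gamma, \delta$ — per-analyte, per-plate batch shift (SD 0.3) and
  residual scale ($2^{N(0,0.15)}$). This is exactly the location/scale model
  the empirical-Bayes correction assumes; an earlier scalar-per-plate
  variant acted as a global latent factor the corrector cannot represent and
  systematically biased null cross-validation below chance, so the
  model-consistent form is the default.
* $u_{s,c}$ — a per-sample, per-class effect (SD 0.35): within a person,
  whole lipid classes move together (lipoprotein status), amino acids move
  separately. This is the structure that makes correlation-based kNN
  imputation meaningful at all; without it, no donor carries information
  about a recipient beyond its group mean.
* Missingness: a cell is censored to `BLOD` (value 0) exactly when its
  drawn concentration falls below the plate's LOD — per analyte the LOD is a
  quantile of the baseline distribution (default 0.05; a ~30% tranche of
  analytes gets 0.75 and is destined for the presence/absence branch), with
  a small per-plate jitter. Independent calibrant failures (`MISS`, default
  1% of cells; a 5% tranche of analytes gets 15% and is destined for
  exclusion) are applied after censoring and override it. The defaults
  reproduce a realistic plate export: roughly 280 quantitative, 110 binary
  and 18 excluded analytes out of 408.

Samples fill 96-well plates sequentially within cohort with groups
interleaved, so group and plate are not confounded; a `confounded` toggle
exists for stress tests. Everything is a deterministic function of the
spec's seed.

What the generator does **not** emulate: nonlinear calibration drift within
a plate, correlated (run-order) missingness, age/sex/pack-years effects on
metabolite levels (covariates are generated but carry no signal), isomer
ambiguity, and heavy-tailed outlier samples. Passing tests therefore show
that the *procedures* behave as specified under a realistic covariance and
missingness structure — not that real serum data would yield any particular
discovery list.

# Preprocessing decisions

* **Partition rules.** An analyte is excluded when its calibrant-missing
  fraction exceeds 10% in any stratum, else binary when its below-LOD
  fraction exceeds 50% in any stratum, else quantitative. Strata are
  cohort × group by default (the stricter reading of "each patient's
  group"); a pooled-group mode is available by flag.
* **kNN imputation.** A missing cell is the mean of the k = 3 nearest
  donors' values; donors come from the same group *and* plate, nearness is
  1 − Pearson correlation over analytes observed in both samples (≥ 10
  shared required). Donor ranking is computed on log2 profiles — on the
  linear scale the correlation is numerically dominated by hexose and the
  cholesteryl esters and carries no information about the donor. Fallbacks
  (same group across plates, then the group median) are logged. Note an
  inherent property of group-aware imputation: imputed cells of a held-out
  sample carry information about its group label. The package keeps the
  method faithful and quantifies the consequence (at the default 1%
  calibrant rate the effect on null cross-validation accuracy is within a
  couple of percentage points); `mode = "strict"` restricts donors to
  training samples but cannot remove this label dependence.
* **Below-LOD replacement.** Independent draws from
  $N(\mathrm{LOD}/2, (\mathrm{LOD}/4)^2)$ truncated to $[0, \mathrm{LOD}]$
  of the cell's plate, via inverse-CDF sampling. The location/scale choice
  centres the mass in the undetectable interval with negligible boundary
  pile-up; both fractions are configurable.
* **Batch correction.** Parametric empirical-Bayes location/scale
  adjustment, one plate = one batch: standardize per analyte against the
  batch-size-weighted grand mean and pooled variance; per batch estimate
  additive γ and multiplicative δ² per analyte; shrink towards
  method-of-moments normal / inverse-gamma priors shared across analytes
  (iterative solution, tolerance 1e-6); adjust and restore the grand scale.
  No biological covariates are protected — the design names none. A single
  batch is returned unchanged. After correction the plate-label rank test is
  *conservative* (rejection below nominal): any corrector that subtracts
  estimated batch means removes the very differences that test measures;
  the package asserts the honest direction (near-1 rejection before, ≤
  nominal after) rather than exact nominal calibration.
* **Embedding.** UMAP (15 neighbours, min-dist 0.1, single thread) on the
  corrected matrix, seeded, used for visualization only.

# Statistics decisions

* All-tied input to Kruskal–Wallis is defined as H = 0, p = 1 (the
  tie-correction denominator would otherwise vanish); this is the degenerate
  no-information case.
* Conover–Iman p-values are unadjusted across the three pairs within an
  analyte (adjustment is applied across analytes); the Pallant r denominator
  is $\sqrt{n_i + n_j}$ of the compared pair, with a flag for $\sqrt{N}$ —
  the phrase "square root of the sample's size" is ambiguous and the
  pairwise reading matches the cited usage.
* The Jonckheere–Terpstra trend uses the fixed ordering Ctr < LN < LC,
  tie-adjusted variance, two-sided normal p.
* Lancaster weights are cohort sample sizes scaled to mean 2, so equal
  cohorts reduce exactly to Fisher; zero p-values are clamped to machine
  epsilon.
* The presence/absence chi-square switches to the exact test whenever an
  expected count falls below 5 (the small cohort's groups make this common)
  and flags it.
* Effect-size labels use the conventional cut-offs: r at 0.1/0.3/0.5, η² at
  0.01/0.06/0.14; the source design prints N/S/M/L without stating its
  cut-offs, so these are package decisions.
* Cross-cohort concordance calls an analyte "common" when it is significant
  with the same LC direction in both cohorts; per-cohort significance uses
  the unadjusted KW p by default (coherence applied on top of the pooled
  FDR-controlled list — with per-cohort FDR at n = 31/group nothing of
  medium effect size can replicate), with `adjusted = TRUE` available.

# Classifier decisions

* The multinomial logit is fitted by full Newton–Raphson with step halving
  (relative log-likelihood tolerance 1e-8, 200 iterations), reference class
  Ctr. Quasi-perfect separation triggers a small ridge (1e-6·n) and is
  flagged, keeping forward selection total.
* "ΔBIC ≤ 2" is read as: stop when the best candidate improves BIC by at
  most 2 — a BIC difference of 2 is the conventional evidence grade.
* The outer 10 folds are a stratified partition: 10 samples per group per
  fold drawn without replacement (100 per group in test across folds; the
  surplus 23 always train). After the inner 100-repetition MRCV and the
  elbow cut, the per-fold model is refit on all non-test training-cohort
  samples — the design leaves the refit set unstated, and this choice uses
  maximal data without touching the fold's test set.
* Consensus ranking scores features by selection frequency, ties broken by
  mean addition position; the elbow is the point of maximum perpendicular
  distance from the chord joining the first and last points of the sorted
  score curve, earliest index on ties.
* Overall AUC is the unweighted mean of the three one-vs-rest Mann–Whitney
  AUCs from the class posteriors; MAP ties break by fixed class order; 95%
  CIs are mean ± 1.96·SE over the 10 folds. The validation cohort is
  evaluated per fold and averaged, matching the CI structure of the
  reported-metrics table.
* Forward selection over all quantitative analytes × 100 repetitions × 10
  folds is the dominant cost; a per-fold pre-screen to the 60 candidates
  with smallest pool Kruskal–Wallis p is on by default (`candidateCap`),
  logged, and can be disabled for the uncapped run.

# Calibration and problem sizes

The null-calibration check generates study-scale data (462 samples × 408
analytes) with an empty effect list and runs the full pipeline; the mean
outer-test accuracy must sit at the three-class chance level (33.3%) and the
macro AUC at 0.5. A single run's accuracy carries ~3–5 percentage points of
Monte-Carlo dispersion (300 held-out samples, plus dataset-level chance
imbalances of the class factors that generalize within a cohort), so the
check averages six independent replicates, seeds fanned deterministically
from the master seed. The type-I-error check runs 5,000 null Kruskal–Wallis
simulations of 3 × 30 samples. Signal-recovery checks plant 20 analytes at
log2FC 1 (battery power at n = 123/group) and 5 strong features at log2FC
1.5, one per analyte class — features planted inside one correlated class
are mutually redundant, and forward selection would legitimately keep only a
representative. `scripts/acceptance.R` recomputes the two headline
quantities from scratch.

# Known limitations

* The panel's per-class counts sum to 408 while the kit's headline count is
  407 "metabolites or their isomer groups"; the registry follows the
  per-class enumeration and documents the one-unit discrepancy.
* Strict mode removes estimation leakage (partition thresholds, donor
  pools, batch parameters) but, like the original design, cannot make
  group-aware imputation label-free; the validation cohort's plate
  parameters are estimated from its own samples, since no training samples
  lie on that plate.
* Covariate-adjusted modelling (age, sex, pack-years) is out of scope: the
  study design matches groups instead.
* The binary (presence/absence) analytes never enter the classifier; only
  the quantitative set does.
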