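---
title: "RPPA-guided gene signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RPPA-guided gene signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppasig)
```

`rppasig` turns a proteomic readout of pathway activation — RPPA
levels of markers such as phospho-AKT (Ser473) and phospho-mTOR
(Ser2448) — into transcriptomic signatures that can be scored in
expression-only cohorts.  This vignette documents the statistical
model behind each stage, the tunable parameters and their defaults,
the behaviour of the synthetic-cohort generator, and the design
choices made where the procedure admitted more than one reasonable
definition.

## The derivation model

The premise is that a marker's RPPA level reflects an underlying
pathway-activation state, and that this state leaves a detectable
transcriptional footprint.  Derivation therefore treats activation as
a binary class label obtained by dichotomizing the marker:

* **Dichotomization** (`dichotomize_rppa`).  Default is a median
  split (`high` strictly above the median), which keeps the classes
  balanced for cross-validation.  `tertile_extremes` (top vs bottom
  third, middle excluded) is offered for sharper contrasts at the
  cost of sample size.  A marker with all values identical cannot be
  split and is an error.

* **Differential expression** (`differential_expression`).  A Welch
  two-sample *t*-test per gene on log2 values.  Welch rather than a
  pooled-variance or moderated test because it needs no equal-variance
  or exchangeability assumption and, at the class sizes involved
  (≥ 100 per class in a median-split derivation cohort), moderation
  buys little.  Fold change is the difference of log2 means.  Genes
  with missing values are handled complete-case per gene; a gene with
  identical values in both classes gets *p* = 1.

* **Selection** (`select_signature`).  Up genes satisfy
  *q* ≤ `fdr_max` and log2 FC ≥ `fc_min`; down genes the mirrored
  rule.  *q*-values are Benjamini–Hochberg step-up
  (`bh_adjust`, delegating to `stats::p.adjust`).  By construction
  the up and down sets are disjoint; an empty signature is legal and
  flagged downstream.

* **Threshold search** (`nested_cv_derive`).  The grid defaults to
  `fdr_max` ∈ {0.001, 0.01, 0.05, 0.1} × `fc_min` ∈ {0.5, 1.0, 1.5,
  2.0} (log2 units) — spanning strict-to-conventional FDR control and
  1.4× to 4× linear fold changes.  Inner 10-fold CV computes, per grid
  point, the mean AUC of the inner-training-selected signature on the
  inner validation fold; the best point is refit on the outer training
  set and assessed on the outer test fold.  The outer AUC pools scores
  and labels over all outer folds into a single AUC with a
  Mann–Whitney p-value, so it estimates the performance of the whole
  procedure, not of one chosen threshold pair.

Three numerical details of the search matter:

1. **Tie-breaking** on the grid prefers the smaller `fdr_max`, then
   the larger `fc_min` — the sparser signature.  This applies both to
   inner-CV ties and to the final modal-choice tie across outer folds.
2. **Leakage control**: the per-gene rescaling transform used to score
   validation samples is always fit on the corresponding training
   samples only.  A property test verifies that permuting expression
   values inside an outer test fold leaves that fold's inner-CV
   choices unchanged.
3. **Empty signatures** score every validation sample identically and
   contribute an AUC of 0.5; if every grid point is empty on every
   inner split, the derivation returns an empty signature with
   AUC 0.5 and a warning flag rather than failing.

The fitted object (`rppa_signature`) carries the final signature, the
full AUC surface over the grid, and supports `print`, `summary`,
`coef`, `predict` and `plot`.

## Scoring and cross-dataset comparability

Public expression cohorts differ in platform and dynamic range, so
before scoring, each dataset is rescaled per gene: a linear map takes
the central 95% range (2.5th/97.5th percentiles, `q = 0.95`) to
[−1, +1].  This robust-range interpretation of a "0.95 quantile
normalization" preserves each gene's shape while equalising scale
across datasets; genes with zero central range map to zero with a
warning.  The signature score is the mean of direction-weighted
(±1) rescaled expression over the signature genes present; absent
genes are dropped and counted, and only a signature with *no* genes
present is an error.  Weights are direction-only rather than
*t*-statistic magnitudes because the derivation reports gene lists,
not coefficients, and because ±1 weights transfer across platforms
without recalibration.

Tertile stratification (`tertile_groups`) uses type-7 empirical
tertiles with boundary ties assigned to the lower group, which makes
group sizes deterministic (1..10 splits 4/3/3).  An all-equal score
vector yields the degenerate all-`mid` grouping with a flag instead of
an arbitrary 3-way split.

## Overlap networks and Markov clustering

Signatures are compared as four half-sets (each signature's up and
down lists separately), since an up-list of one signature may
legitimately coincide with the down-list of another.  Edge
significance is a one-sided hypergeometric test of the shared-gene
count against sampling from a configurable gene universe (default:
the derivation platform's gene count), BH-corrected across all pairs
at *q* ≤ 0.05.  The test, the correction and the universe are package
choices; they reproduce the intended behaviour — connect signatures
sharing "significantly many" genes — with the field's default
machinery.

`mcl_cluster` is a from-scratch Markov Cluster implementation:
self-loops (weight = maximum incident edge weight, the canonical
regularisation) are added, columns are normalized, and expansion
(matrix power 2) alternates with inflation (elementwise power 2.0 and
renormalization) until the flow matrix changes by less than 10⁻⁶ or
100 iterations.  Entries below 10⁻¹² are pruned for numerical
stability; clusters are the connected components of the limit matrix's
support.  The implementation is deterministic, permutation-equivariant
and keeps columns stochastic to within 10⁻⁹ at every step (asserted in
tests).  Inflation 2.0 is the canonical default; on the planted
two-clique family, raising inflation never merges clusters.

## Survival and association battery

Hazard ratios are reported **per 1 SD of score**, standardized within
the analysed stratum.  The score scale is arbitrary (it depends on
signature size and rescaling), so per-SD units are the only way to
compare HRs across signatures; affine invariance of the HR is covered
by a test.  Multivariable models add age (continuous), tumor size
(continuous), grade (ordinal numeric 1–3) and nodal status (binary),
complete-case per model; constant covariates are dropped with a
warning.  Pooling across datasets is patient-level after per-dataset
rescaling and scoring — not meta-analytic averaging — matching the
comparability purpose of the rescaling step; a dataset-stratified
baseline hazard is deliberately not the default.  Strata with fewer
than 10 events are skipped with a warning.  The forest table flags
nominal *p* < 0.05 without further multiplicity correction, mirroring
the exploratory use of such tables.

Rank tests delegate to `stats::kruskal.test` and
`stats::wilcox.test` (exact below 9 observations per side without
ties, otherwise the tie- and continuity-corrected normal
approximation).  The AUC's own p-value (`auc_mann_whitney`) uses the
tie-corrected normal approximation *without* continuity correction,
which makes the two-group Kruskal–Wallis χ² equal the squared U-test
z-score exactly — a correspondence the tests exploit.  Mutation
contrasts treat a sample as mutated regardless of mutation count, and
PIK3CA is additionally analysed by exon class (9, 20, all others)
against the same wild-type reference; classes under 10 samples per
side are flagged as skipped rather than tested.

## The synthetic-cohort generator

`simulate_cohort` builds the ground truth every stage is tested
against.  Per marker *m*, a latent activation *a<sub>m</sub>* ~
N(0, 1) per sample drives everything:

* **RPPA value** = *a<sub>m</sub>* + N(0, `marker_noise_sd`), default
  SD 0.5.  RPPA is a quantitative assay with high replicate
  reproducibility, so measurement noise well below the biological
  spread (latent SD 1) is the realistic regime; 0.5 corresponds to a
  marker–latent correlation of about 0.89.
* **Expression**: planted genes shift by
  ±(`effect_size`/1.596)·*a<sub>m</sub>* on top of unit-variance
  noise, so the mean log2 difference between activated
  (*a* > 0) and inactivated samples is exactly `effect_size`
  (1.596 = 2√(2/π) is the expected |*a*| gap between the halves).
  Default effect 1.5 log2 units, 40 up + 40 down genes per marker,
  disjoint across markers.
* **Subtype**: luminal B with probability
  logit⁻¹(logit(0.37) + Σ shift<sub>m</sub>·*a<sub>m</sub>*), default
  shifts −1 (pAKT, enriching activation in luminal A) and +1
  (p-mTOR); 0.37 is the luminal-B fraction of a typical luminal RPPA
  cohort.
* **Mutations**: logistic models on the latent — PIK3CA
  (base rate 0.35, +1 log-odds per pAKT latent unit; carriers split
  30/45/25% into exon 9 / exon 20 / other, exon 20 most common as in
  luminal disease) and P53 (base rate 0.20, +1 per p-mTOR unit).
* **Survival**: exponential event times with hazard
  baseline·exp(Σ logHR<sub>m</sub>·z(*a<sub>m</sub>*)), default
  baseline 0.005/month and per-SD hazard ratios 0.79 (pAKT,
  protective) and 1.1 (p-mTOR, deleterious); censoring is an
  independent exponential whose rate is solved numerically so the
  expected censored fraction equals `censor_rate` (default 0.7,
  a typical recurrence-free-survival event yield).

One RNG stream keyed by `seed` produces the whole cohort, so fixtures
are byte-reproducible.  The generator deliberately does **not** mimic
platform-specific microarray noise, batch effects, probe-level
structure, gene–gene correlation beyond the planted latents, or
non-proportional hazards.  Consequently, passing recovery tests shows
the pipeline is correct and well-calibrated under its own model
assumptions; it does not show that real RPPA cohorts carry signal of
the planted strength, nor that real survival follows proportional
hazards.

## Problem sizes used by the test suite

The automated checks run at sizes chosen to make the statistics
decisive while keeping a full run to a few minutes on one CPU:
derivation recovery and disjointness at 300 samples × 5000 genes
(the scale of a TCGA-like luminal RPPA cohort); the no-signal control
over 20 replicate cohorts; Cox recovery at n = 2000 with 50
replicates and null coverage with 200; null calibration of the rank
and log-rank tests at 1000 replicates each; and the oracle
equivalences (AUC vs exhaustive pair enumeration, BH vs brute-force
step-up, hypergeometric vs direct combinatorics) over 1000 random or
exhaustively enumerated small instances.

## Known limitations

* Derivation assumes the dichotomized marker is a meaningful class
  boundary; a marker whose effect on transcription is graded or
  bimodal-with-offset is summarised only through that cut.
* Gene identifiers must be harmonized across cohorts upstream; there
  is no probe-to-gene mapping.
* The Cox battery fits proportional hazards without diagnostics
  (no Schoenfeld tests) and without dataset-stratified baselines by
  default.
* The MCL implementation is dense; it is intended for signature-scale
  graphs (tens to hundreds of nodes), not genome-scale networks.
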