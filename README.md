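# rppasig

Gene-expression signatures of phospho-protein pathway activation in
luminal breast cancer.

Reverse phase protein arrays (RPPA) measure the abundance of
(phospho-)proteins such as pAKT (Ser473) and p-mTOR (Ser2448) per tumor
sample, giving a direct readout of PI3K/AKT/mTOR pathway activation —
but RPPA data are rarely available outside a few reference cohorts.
`rppasig` derives *transcriptomic surrogates* of that readout: gene
signatures whose expression score predicts a sample's high/low
activation status for a chosen marker.  Once derived, the signatures
can be scored in any expression cohort, letting pathway activation be
studied in the thousands of public microarray/RNA-seq datasets that
have survival and mutation annotation but no proteomics.

The package is aimed at computational biologists working on
proteogenomic integration and on prognostic evaluation of pathway
activity in ER-positive breast cancer, and at anyone who needs a
tested, self-contained implementation of the component statistics
(nested cross-validated threshold selection by AUC, sign-weighted
signature scoring with robust quantile rescaling, hypergeometric
overlap networks with Markov clustering, pooled Cox forest tables).

## Method

**Derivation.**  A marker's RPPA values are dichotomized (median split
by default) into activated (*high*) and inactivated (*low*) classes.
Per gene, a Welch *t*-test compares log2 expression between classes,
with Benjamini–Hochberg *q*-values; a candidate signature at thresholds
(*q*<sub>max</sub>, *fc*<sub>min</sub>) is

- up genes: *q* ≤ *q*<sub>max</sub> and log2 FC ≥ *fc*<sub>min</sub>,
- down genes: *q* ≤ *q*<sub>max</sub> and log2 FC ≤ −*fc*<sub>min</sub>.

The thresholds are selected over a grid by **nested 10-fold
cross-validation**: inner folds pick the grid point with the highest
mean AUC of the signature score against the held-out labels; outer
folds, untouched by selection, estimate the AUC of the whole procedure
(pooled over test folds, with a Mann–Whitney p-value).  The final
signature is fit on all samples at the modal grid point.

**Scoring.**  Each dataset is first rescaled per gene so its central
95% expression range maps linearly to [−1, +1] (cross-platform
comparability); the signature score of a sample is the mean of
(±1-weighted) rescaled expression over signature genes, i.e.
*s* = (Σ<sub>up</sub> x − Σ<sub>down</sub> x) / |genes|.

**Networks.**  Signatures (their up and down halves separately) form
a graph whose edges connect gene sets sharing significantly many genes
(one-sided hypergeometric test, BH across all pairs, *q* ≤ 0.05; edge
weight = shared-gene count), clustered with an in-house Markov Cluster
(MCL) implementation (expansion/inflation on the column-stochastic
flow matrix).

**Association battery.**  Kruskal–Wallis tests of scores across
subtypes; Mann–Whitney contrasts of scores by mutation status (PIK3CA
also by exon class: 9, 20, all others); tertile Kaplan–Meier curves
with log-rank tests; and uni-/multivariable Cox proportional-hazards
models of recurrence-free survival (HR per 1 SD of score; covariates
age, tumor size, grade, nodal status), pooled patient-level across
rescaled datasets into a forest table with strata for all-luminal,
luminal A, luminal B and endocrine-only-treated patients.

**Synthetic cohorts.**  `simulate_cohort()` generates matched
expression/RPPA/clinical data with a known planted structure (latent
activation per marker driving RPPA values, planted signature genes,
subtype, mutation flags and proportional-hazards survival), so every
stage of the pipeline has a ground-truth recovery test.

## Worked example

```r
library(rppasig)

cohort <- simulate_cohort(sim_config(n_samples = 80, n_genes = 300,
                                     planted_up = 15, planted_down = 15,
                                     effect_size = 2, seed = 7))
fit <- rppa_signature(cohort$expr, cohort$rppa, marker = "pAKT",
                      k = 5, seed = 7)
fit
#> RPPA-guided gene signature for marker 'pAKT'
#> Gene signature 'pAKT': 15 up, 15 down
#>   thresholds: FDR <= 0.05, |log2 FC| >= 1
#>   cross-validated AUC: 0.936 (p = 1.86e-11)
#>   thresholds chosen by nested 5-fold CV
```

The fit recovered all 30 planted genes; the outer-CV AUC of 0.936 says
a randomly chosen activated sample outscores an inactivated one 93.6%
of the time, on folds never used for threshold selection.  The fitted
signature then scores any cohort and feeds the survival battery:

```r
scores <- predict(fit, cohort$expr)
groups <- tertile_groups(scores)
km_logrank(groups, cohort$clinical$rfs_time,
           cohort$clinical$rfs_event)$test
#> log_rank: statistic = 3.301, p = 0.192 (n = 27/26/27)

cox_fit(scores, cohort$clinical, multivariable = TRUE)
#> signature | all | multivariable: HR 0.733 (95% CI 0.484-1.111),
#>   p = 0.144 (n = 80, events = 26)
```

The hazard ratio is per 1 SD of score; at n = 80 the protective trend
planted by the generator (pAKT log-HR < 0) is visible but not
significant — the pooled multi-dataset analysis
(`pooled_analysis()`) is where power comes from.

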