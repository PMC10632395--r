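# ktspmeta

Rank-based gene-pair survival classifiers evaluated across heterogeneous
cohorts by random-effects meta-analysis.

## The problem

Expression-based relapse predictors rarely survive the trip from the cohort
they were trained on to any other cohort: absolute expression depends on
the platform (microarray vs RNA-seq), the normalisation pipeline, and
batch. `ktspmeta` is built for the setting where that trip is the whole
point — predicting **early relapse** (disease-free survival of one year or
less) of ovarian carcinoma from tumour transcriptomes profiled on different
platforms in different hospitals, with one training cohort and several
independent validation cohorts.

The package is aimed at computational biologists who want a single-sample,
cross-platform prognostic model plus the full evaluation stack around it:
censored survival statistics, meta-analysis, permutation nulls,
clinicopathologic baselines, and a synthetic multi-cohort generator that
makes every stage testable offline.

## The model

The core predictor is an ensemble of **k top-scoring disjoint pairs
(k-TSP)** classifiers. For a gene pair (i, j), the score is

    Δ_ij = | P(X_i < X_j | high) − P(X_i < X_j | low) |

estimated by within-class counting of the per-sample ordering indicator
I(x_i < x_j). A model is k disjoint pairs (no shared genes) selected
greedily by (Δ desc, rank-gap γ desc, pair id asc) from a Wilcoxon
rank-sum-filtered gene set, with k chosen by stratified cross-validated
balanced accuracy; it votes by majority of its oriented pair rules.
Because every rule depends only on a within-sample ordering, predictions
are invariant to any strictly increasing per-sample transform — the
property that lets one model score microarray and RNA-seq profiles alike.
An ensemble of B such models on class-balanced resamples yields a
continuous risk score in [0, 1] (the fraction of members voting high).

Per validation cohort the score is evaluated by Mann–Whitney **AUROC**
(Hanley–McNeil se), Harrell's **C-index**, and the Royston–Sauerbrei
**D-index** (exponentiated Cox coefficient of the κ-scaled rankit of the
score, κ = √(8/π)); cohorts are pooled by **DerSimonian–Laird**
random-effects meta-analysis (D-index on the log scale), with
leave-one-out sensitivity and median-split Kaplan–Meier / log-rank
analyses. Two permutation tests — label shuffling with full retraining,
and random gene substitution at fixed architecture — check that neither
the labels nor the specific gene pairings are exchangeable with chance.

## Worked example

```r
library(ktspmeta)

study <- simulate_study(simulation_config(seed = 1))   # default synthetic study
ens <- train_ensemble(study$training, B = 25, m = 200,
                      k_grid = c(3, 5, 7, 9), cv_folds = 3, seed = 2)
ens
ev <- evaluate_ensemble(ens, study$validation)
ev$table[, c("cohort", "platform", "n", "auroc", "cindex", "dindex",
             "median_dfs_gap")]
pool_random_effects(ev$auroc)
pool_random_effects(ev$dindex)
```

```
<ktsp_ensemble> B = 25 models; 48 distinct pairs over 62 distinct genes
  cohort   platform  n auroc cindex dindex median_dfs_gap
1     V1 sequencing 40 0.831  0.716   3.84            590
2     V2 sequencing 50 0.768  0.639   1.78           1150
3     V3      array 60 0.809  0.709   3.43           1291
4     V4      array 70 0.791  0.656   2.56            696
5     V5      array 80 0.783  0.682   2.83           1525
meta-auroc over 5 cohorts: 0.7963 (95% CI 0.7454-0.8471, p = 3.51e-30, tau2 = 0)
meta-dindex over 5 cohorts: 2.7262 (95% CI 2.1373-3.4775, p = 6.67e-16, tau2 = 0.001575)
```

Reading this: the study plants five prognostic gene pairs (ordering-
probability difference 0.6) in a 500-gene universe, trains on 50 patients
profiled on two platforms, and validates on five cohorts that each apply a
different monotone platform transform and batch shift. The ensemble's 25
members together use 48 distinct pairs over 62 distinct genes (members
overlap in their strongest pairs, so genes < 2 × pairs). Validation AUROCs
of 0.77–0.83 per cohort pool to 0.80 with no detectable heterogeneity
(τ² = 0); a pooled D-index of 2.7 means the risk score separates the DFS
distributions strongly, and the median-split gap shows high-risk groups
relapsing months-to-years earlier. Scores are bit-identical if a cohort's
expression is re-expressed in log2, affine or rank units.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study end-to-end,
writing tables under `results/` (bulky simulated cohorts go to
`scratch/`, which is disposable):

1. `01_simulate.R` — generate and write the default study, report realized
   labels, censoring and planted effects.
2. `02_train.R` — reload the cohorts from disk, train the ensemble, write
   `results/model.json`.
3. `03_evaluate.R` — per-cohort AUROC/BAC, C-index, D-index, median-split
   KM and log-rank.
4. `04_meta.R` — random-effects pooling, forest tables, leave-one-out.
5. `05_nulls.R` — label-shuffle and random-gene permutation tests.
6. `06_comparators.R` — clinicopathologic logistic baseline and
   superiority test, weighted-signature comparator, pair-budget reduction
   sweep, hypergeometric enrichment demo.

`run_all()` performs stages 2–6 as one call on in-memory cohorts.

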