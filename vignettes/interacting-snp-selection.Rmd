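---
title: "Selecting interacting SNPs for case-control risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting interacting SNPs for case-control risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Polygenic risk scores (PRS) model disease risk as a weighted sum of
risk-allele dosages, `PRS_i = sum_s beta_s * g_si`, with `g_si` in
{0, 1, 2} and `beta_s` the per-allele log odds ratio. The additivity
assumption is exactly what a PRS cannot escape: variants whose effect is
only visible jointly — epistatic SNP pairs, and XOR-type pairs in
particular, which carry (near) no marginal signal at all — contribute
nothing to a linear score. `episnp` implements a non-linear alternative
for case-control genotype panels:

1. **Module 1 — gain ranking.** A gradient-boosted tree ensemble
   (binary logistic objective) is fitted on all SNPs; each SNP is scored
   by its share of the ensemble's total split gain. SNPs never used in a
   split are discarded; the rest form the candidate list, sorted by gain.
2. **Module 2 — adaptive iterative search.** A top window (first `M`
   candidates) and bottom window (last `M`) are each re-ranked by an
   independent boosting model trained on that window's SNPs only; the top
   window's lowest-ranked SNP and the bottom window's highest-ranked SNP
   are exchanged; both windows grow by `W`; the cycle repeats until the
   windows overlap. Because a window model sees only a small SNP block,
   SNPs that matter jointly can out-gain marginally stronger singletons
   and climb out of the bottom of the list.
3. **Back-end.** A linear-kernel support vector machine
   (`k(x_i, x_j) = x_i' x_j`) on the selected dosages ranks samples by
   decision value; ranking quality is summarized by average precision
   (AP), i.e. `sum_i (recall_i - recall_{i-1}) * precision_i` over all
   score thresholds, and by its mean over cross-validation splits (mAP,
   reported x100).

## Evaluation protocol

`repeated_nested_cv()` implements the repeated stratified nested scheme:
per repetition a stratified 5-fold outer split (4:1 training fold :
test); the training fold is split into 5 stratified inner folds, of
which fold 1 is the *validation data* and folds 2–5 merge into the
*training set*. Module 1 fits on the training set; module 2 evaluates
every `(M, W)` pair of the configured grids and, for each group size `k`
in a grid, the validation AP of the SVM on the top-`k` of the re-ranked
list; the `(M, W, k)` triple with the best validation AP defines the
split's selected group (ties break toward smaller `k`, then `M`, then
`W`). The SVM is refitted on the whole training fold and scored on the
untouched test fold. Ten repetitions of five folds give 50 splits;
`mean_average_precision()` aggregates them. The same individual never
appears on both sides of any fit/score pair — an assertion the test
suite checks on every split.

Per-split argmax frequently lands on small `k`: on a small validation
set the AP curve over `k` is noisy and short lists often win. The
cohort-level set of identified risk-predictive SNPs is therefore the
*aggregate* of the per-split groups, `identified_snps()`: the union over
splits, ordered by how many splits selected each SNP. That aggregate is
what the downstream analyses (ER-subtype classification, cross-cohort
transfer) consume; on the real-scale analyses this construction yields
identified sets of hundreds of SNPs even though single splits may select
a handful.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_trees` | 500 | boosting rounds; an explicit grid axis, no early stopping |
| `tree_depth` | 2 | maximum tree depth; 2 was the reported optimum for this protocol — one interaction per tree, strong overfitting control |
| `learning_rate` | 0.01 | shrinkage; slow learning was consistently optimal |
| `subsample` | 0.5 | per-tree row subsampling without replacement; aggressive (40–60%) subsampling helps at these sample sizes |
| `window_sizes` (M) | 2, 4, 6, 8, 20, 30 | initial top/bottom window sizes swept by the search |
| `window_increments` (W) | 1–5 | per-pass window growth |
| `max_group_size` | 600 | cap on the selected group |
| `C` (penalized baselines) | 0.7 | inverse regularization strength, the protocol's fixed setting; elastic-net L1 ratio 0.4 |
| `svm_cost` | 1 | SVM soft-margin cost; the back-end's only free parameter |

`tune_boosting()` reproduces the two-stage protocol: a grid over
(`n_trees`, `tree_depth`, `learning_rate`) scored by stratified 5-fold
validation log-loss (one booster per (depth, rate, fold) covers the whole
`n_trees` axis through the per-round evaluation log), then the
subsampling rate with the winning triple fixed. `repeated_nested_cv()`
does **not** re-tune per training fold by default: the shipped defaults
are the protocol's reported optima, and the original study likewise
tuned on one cohort and reused the optima elsewhere; pass `tune = TRUE`
to re-tune per outer fold.

## Design choices on under-determined points

The published description of the iterative search leaves two details
open; the package fixes them as follows and documents them here rather
than silently. (a) *Swap count*: exactly one SNP is exchanged per
direction per pass — the description speaks of "the" highest-/lowest-
ranked SNP, singular; `W` controls window growth only. (b) *Re-rank
frequency*: both windows are re-ranked every pass, so a swapped-in SNP
competes immediately. Overlap is declared when the two window spans
cover the candidate list (`top + bottom >= N`); the never-windowed
middle retains its original relative order between the two re-ranked
blocks. Validation AP is computed on the final list only, not monitored
per pass.

Other fixed readings: missing-genotype exclusion is column-wise (a SNP
with any missing call is dropped; both study cohorts ended with one
common SNP count, which implies a per-SNP rule) with sample-wise
exclusion available behind `by = "sample"`; PRS weights default to
`log(OR)` with `beta = "or"` available, since the PRS description
states odds ratios but log-odds weighting is the field convention; the
validation fold is inner fold 1 (no rotation) unless
`rotate_inner = TRUE`; `l2` selection has no natural size, so its
`k_target` defaults to the proposed method's mean group size when both
run in `run_pipeline()`.

## The synthetic-data generator

Real case-control cohort genotypes are generally not redistributable, so every
stage is exercised on synthetic data built to reproduce the two
population-genetic features the method is sensitive to:

- **Population structure** between cohorts: Balding–Nichols — ancestral
  frequency `p ~ U(maf_range)` per SNP, cohort frequency
  `~ Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`.
- **Local LD**: a first-order Markov copying chain along adjacent SNPs
  (copy probability `ld_decay`, default 0.2).
- **Phenotype**: logistic in marginal dosage terms plus `product`
  (`beta * g_i * g_j`) or `xor` (`beta * 1[(g_i>0) != (g_j>0)]`)
  interaction terms. XOR pairs are included deliberately: their marginal
  signal vanishes as the carrier frequency approaches 1/2
  (`maf ~ 0.293`), which is precisely the regime where non-linear
  selection should beat a PRS. `target_prevalence` solves the intercept
  on the realized genotypes.
- **ER status**: among cases only,
  `P(ER+) = plogis(sum of er_effects)`.

What the generator does *not* emulate: coalescent-accurate LD blocks,
recombination maps, genotyping error, imputation uncertainty, rare
variants, or covariates such as age. Passing tests therefore demonstrate
the machinery's correctness and its qualitative behaviour (interaction
recovery, PRS comparison, structure-driven transfer loss) — not
performance claims about real cohorts.

The standard fixture (`make_toy_fixture()`) is 400 samples x 300 SNPs
with two marginal causal SNPs (log-odds 0.8) and one XOR pair (log-odds
2.0) at 50% prevalence — small enough for seeded replication studies,
large enough for the boosting ranker to be meaningfully better than
chance.

## Problem sizes used by the shipped studies

The test suite and the acceptance script run scaled-down studies chosen
as the package's own desk-scale conditions: the 400 x 300 fixture; one
repetition of the 5-fold outer scheme per seed (five splits per study,
ten seeded studies per claim); the window grid subset `M in {2, 20}`,
`W = 5` with a group-size grid dense for small `k`; module-1 boosting at
the shipped defaults; and window re-ranking models at
`n_trees = 100–150, learning_rate = 0.1` — window models see only a
small SNP block, so a shorter ensemble with a proportionally larger rate
(comparable total shrinkage) ranks a block as well as the full-length
setting at a fraction of the cost. Structural properties of the search
(termination, permutation conservation, the 30-run sweep) are checked on
the full `M`/`W` grids. The full-scale defaults remain the documented
ones; nothing in the package switches behaviour based on problem size.

## Numerical notes and degenerate inputs

- PR curves enumerate one threshold per distinct score; tied scores
  enter together (this matters for AP with discrete scores — a constant
  score yields AP = prevalence, the correct single-threshold value).
- SVM decision values are oriented from libsvm's class-pair label so
  that larger always means more case-like, independent of class order
  in the training data.
- Penalized fits map the stated inverse strength `C` to
  `lambda = 1/(C n)` (both objectives are mean deviance plus penalty);
  dosages are not standardized — they share a scale by construction.
- Degenerate cases error loudly rather than guess: single-class labels,
  empty candidate lists, all-zero gain, empty SNP intersections, classes
  too small to stratify. `2M >= |candidates|` at entry is the one
  sanctioned degenerate: the search returns the input ranking with zero
  iterations.
- Determinism: every stochastic step (fold draws, simulator, booster
  subsampling) derives from explicit integer seeds; boosters run single
  threaded. Identical configs produce byte-identical serialized reports.

## Limitations

- The adaptive search is a heuristic: it has no optimality guarantee,
  and on small validation sets the selected `(M, W, k)` is noisy — the
  per-split group should be read as one draw, the cross-split aggregate
  as the estimate.
- A linear SVM back-end can only exploit an interaction through its
  marginal leakage; the selection can find a pure XOR pair, but the
  back-end's AP gain then comes from carrier-frequency asymmetry.
- Boosting gain is biased toward SNPs with more split opportunities
  (higher MAF); no bias correction is attempted, matching the method
  being reproduced.
- The tuner's stage 1 fixes `subsample = 1`, so interactions between
  subsampling and the tree-count axis are only explored in stage 2.
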