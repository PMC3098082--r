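---
title: "Model selection for gene-selection procedures with the .632+ bootstrap"
author: "gsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model selection for gene-selection procedures with the .632+ bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsbench)
```

## The problem

Given a preprocessed two-class expression matrix (genes in rows, samples
in columns), which combination of ranking statistic, gene subset size and
classifier yields the most accurate diagnostic signature? No single
recipe dominates across datasets: parametric statistics suit large,
well-behaved cohorts; rank and entropy statistics tolerate outliers and
distributional surprises; restricting candidates to up- or down-regulated
genes, discretizing features, or summing a same-direction panel into one
composite feature each help on some datasets and hurt on others. gsbench
treats this as an empirical model-selection question: enumerate the whole
grid of candidate *procedures*, estimate each one's generalization error
honestly, and report the winners with their gene panels.

A *procedure* here is one complete prediction rule:

1. rank all genes by a statistic — Welch t, Wilcoxon rank-sum, or
   information gain under MDL discretization;
2. optionally restrict candidates to up- or down-regulated genes
   (direction is called from the positive-class mean);
3. keep the top k;
4. optionally discretize the classifier's features and/or sum the k
   same-direction genes into a single composite feature
   ("feature-vector addition");
5. train an SVM (RBF kernel) or a random forest.

With all options on and one k, the grid holds 60 procedures: the
`total` pattern contributes 3 statistics x 2 discretization x 2
classifiers = 12 (the composite needs same-direction genes, so it is
excluded there), and each of `up`/`down` contributes
3 x 2 x 2 x 2 = 24.

## The .632+ bootstrap, with selection inside the resample

Each procedure is scored by the .632+ bootstrap. Writing
$\bar{err}$ for the resubstitution error of the procedure fitted to all
n samples, and $err^{(1)}$ for the leave-one-out bootstrap error — each
sample's misclassification rate averaged over the bootstrap replicates
in which it was out-of-bag, then averaged over samples — the estimator
interpolates:

$$ err^{(1)\prime} = \min(err^{(1)}, \gamma), \qquad
   R = \frac{err^{(1)\prime} - \bar{err}}{\gamma - \bar{err}}, \qquad
   \hat w = \frac{0.632}{1 - 0.368\,R}, $$

$$ \widehat{Err}^{.632+} = (1 - \hat w)\,\bar{err} + \hat w\, err^{(1)\prime}, $$

where $\gamma = \sum_c p_c (1 - q_c)$ is the no-information rate computed
from the observed class proportions $p_c$ and the resubstitution model's
predicted-class proportions $q_c$. $R$ is defined as 0 unless
$err^{(1)\prime} > \bar{err}$ and $\gamma > \bar{err}$, and is clipped to
$[0,1]$; consequently $\hat w \in [0.632, 1]$ and the estimate always
lies between $\bar{err}$ and $err^{(1)\prime}$. $R = 0$ recovers the
plain .632 estimator; $R = 1$ (maximal overfitting, e.g. a memorizing
classifier on pure noise) gives the leave-one-out bootstrap error
unweighted.

The single most consequential design choice in the package is that the
**entire** procedure — ranking, direction filtering, top-k selection,
discretization, composite construction and classifier training — is
re-fitted from scratch on every bootstrap replicate's in-bag samples.
Selecting genes once on the full data and only refitting the classifier
would leak the held-out labels into the gene list and bias the error
estimate downward severely; the test suite includes a probe dataset
whose winning gene depends on the training subset to assert the
selection really is recomputed.

Other evaluation choices, fixed after deliberation:

* **B = 100 replicates** by default: standard for .632+ and enough for
  the per-sample averages to stabilize at the sample sizes the package
  targets; configurable in `bootstrap_plan()`.
* **Degenerate resamples**: an in-bag multiset with fewer than two
  samples of either class can neither compute a two-sample statistic
  (the Welch t needs a variance in each class) nor train a classifier,
  so the replicate is redrawn with the next derived seed (at most 50
  times, then an error names the class imbalance). Redrawing preserves
  the marginal bootstrap distribution better than stratified resampling
  would; with balanced cohorts of 30 + 30 the redraw is almost never
  triggered.
* **Seed discipline**: replicate r's seed is a pure function of
  (master seed, r) through a Lehmer-style integer mix, and each
  procedure in a grid derives its own master seed from (grid seed,
  canonical index). Results are therefore bit-identical whether the grid
  runs serially or on forked workers, in any schedule.
* **err1 aggregation** is per-sample first (each sample's error averaged
  over the replicates that held it out), then across samples; samples
  never out-of-bag are excluded and counted.

## Ranking statistics

* **Welch t** (unequal variances, two-sided, Welch–Satterthwaite
  degrees of freedom), the robust default for two-group expression
  comparisons. A gene constant in both classes with equal means scores
  t = 0, p = 1; constant with different means scores p = 0.
* **Wilcoxon rank-sum / Mann–Whitney U**, exact null distribution when
  min(n1, n2) <= 12 and the gene has no ties, otherwise the normal
  approximation with tie and continuity corrections. The implementation
  is vectorized across genes (one radix sort on (gene, value) keys gives
  all within-gene ranks and tie counts); the test suite checks it
  against `stats::wilcox.test` and against full enumeration of rank
  assignments at small n.
* **Information gain**: class-entropy reduction of the partition chosen
  by recursive minimum-description-length discretization (binary splits
  at midpoints between adjacent distinct values, each accepted only if
  its gain clears the MDL code-length penalty). Genes with no accepted
  cut score 0; for two classes 0 <= IG <= H(class) <= 1 bit. A
  `single_split` switch stops after the first accepted cut.

Ranking keys are explicit and total: (p ascending, |statistic − null
center| descending, gene file order) for the two tests, (gain
descending, file order) for information gain — so selected lists are
bit-reproducible. p-values are ranked rather than raw statistics because
class imbalance makes raw U values incomparable across directions. No
multiple-testing correction is applied: the statistics only order the
genes, and k caps the list.

Direction is `up` when the positive-class mean exceeds the other class's
mean, `down` otherwise, with exact ties called `down` — an arbitrary but
deterministic rule. The positive class defaults to the lexicographically
smaller label and is recorded in every report.

## Classifier-side transforms

Discretization re-learns MDL cuts per selected gene **on the training
samples only**; values map to 0-based half-open intervals
$(-\infty, c_1), [c_1, c_2), \ldots$ fed to the classifiers as ordinal
integers (interval order carries information a one-hot encoding would
discard). Feature-vector addition sums the raw expression vectors of the
k selected same-direction genes into one composite feature: for genes
shifted the same way the class gap grows k-fold while independent noise
grows only as sqrt(k), and sample-level outliers in single genes are
diluted. Three choices here were genuinely open and are fixed as
follows:

* the composite **replaces** the k gene features (the classifier sees
  exactly one feature) — the alternative, appending it, is weaker as a
  test of the mechanism and is not offered;
* genes are **not** standardized before summation; the transform is
  deliberately scale-sensitive and documented as such;
* when both options are on, the composite is formed from raw values
  first and then discretized — discretizing first would quantize away
  exactly the amplification the sum is meant to create.

Classifiers run untuned, mirroring their packages' defaults: SVM with
RBF kernel, cost 1, kernel width 1/#features, per-feature
standardization learned on the training block (e1071); random forest
with 500 trees and sqrt(p) candidate split variables (randomForest),
seeded deterministically. A training block whose features are all
constant — reachable when every discretized gene ends with zero cuts —
degenerates to a majority-class predictor with ties broken by class
order, a guard that also protects against pathological behavior of
tree training on zero-variance inputs.

## Ranking procedures and reporting

Completed procedures are ordered by (err632plus ascending, k ascending,
canonical grid order); `rank_results()` returns **all** procedures tied
at the minimal error and minimal k, since equally accurate, equally
parsimonious procedures are equally reportable. `write_report()` emits a
TSV of the full grid (best first, with the semicolon-joined gene panel
selected on the full data), the best subset, a machine-readable JSON
report, and a log of plan, seed and version. A failing procedure (e.g. a
pattern group with no genes) is recorded with its message and never
aborts the remaining grid.

## The synthetic generator

`simulation_config()` / `generate_dataset()` produce the two-class
matrices the test-suite and the acceptance script run on: values are
`base_level` (default 8, a log2-intensity scale) plus Gaussian noise
(`noise_sd` 1), with `n_up` and `n_down` informative genes shifted by
±`effect_size`·`noise_sd` in the positive class, and optionally a
fraction of samples spiked on 10% of genes to mimic outlier arrays. The
defaults — 2000 genes, 30 + 30 samples, 20 up + 20 down informative
genes, effect size 2 — represent a mid-sized two-class microarray study
with a clearly detectable but non-trivial signature. Gaussian noise was
chosen over heavy-tailed alternatives so analytic expectations (null
p-value uniformity, composite gap/noise arithmetic) stay checkable; the
outlier knob exists separately to exercise the composite's
outlier-offsetting behavior.

What the generator does **not** emulate: probe-level artifacts, batch
effects, dye bias, intensity-dependent variance, correlated gene blocks.
Passing tests therefore demonstrate the machinery is correct and honest
(no leakage, calibrated nulls), not that any particular procedure will
win on a given real dataset — on real data the whole point of the
workbench is to let the grid decide.

## Problem sizes used in the checks

The test-suite and `scripts/acceptance.R` run at sizes chosen to be
informative on a single desktop core: null calibration at the full
defaults (2000 genes, 30 + 30 samples, B = 100) over the 12-procedure
total-pattern grid; signal recovery on 500 genes with 40 planted genes
(effect size 3, k = 40, B = 100) over the 30-procedure non-discretized
grid; determinism on a miniature grid at three worker counts;
out-of-bag calibration with 1000 replicates at n = 100. Recall in the
signal check is assessed across the tied-best procedures because
up/down-restricted members of the tie can, by construction, select only
their own direction's half of the planted panel.

## Known limitations

* Two classes only; no multi-class generalization of direction calls or
  of γ.
* The feature-composite's scale sensitivity means mixing genes measured
  on wildly different scales into one sum is the user's responsibility.
* Hyperparameters are fixed, not searched; the grid compares procedures,
  not tuning regimes.
* Exact Wilcoxon p-values switch to the tie-corrected normal
  approximation in the presence of any tie, even at small n where a
  tie-aware exact enumeration would be feasible.
* Bootstrap redraws slightly perturb the resample distribution for
  severely imbalanced cohorts (e.g. 2 vs 98), where the redraw path is
  exercised constantly; the grid report records the plan so this is
  visible.
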