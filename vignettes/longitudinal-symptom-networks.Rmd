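---
title: "Longitudinal symptom-network analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal symptom-network analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` analyses multi-wave panels of 16 ordinal symptom items — the
nine PHQ-9 depression items and the seven GAD-7 anxiety items, each scored
0–3 — as *Gaussian graphical models* (GGMs). A GGM is an undirected
network whose edge weights are partial correlations: the association
between two symptoms after conditioning on all other symptoms. An absent
edge means conditional independence.

The precision matrix \(K\) is estimated by the graphical lasso, the
maximizer of the \(\ell_1\)-penalized Gaussian log-likelihood

\[
\log\det K \;-\; \operatorname{tr}(RK) \;-\; \lambda \sum_{i \ne j} |K_{ij}|,
\]

where \(R\) is the item correlation matrix. Only off-diagonal entries are
penalized. Edge weights are then
\(w_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}\). The penalty \(\lambda\) is chosen
on a 100-point log-spaced grid from \(\lambda_{\max}\) (the largest
absolute off-diagonal correlation, at which the graph is empty) down to
\(0.01\,\lambda_{\max}\) by minimizing the extended Bayesian information
criterion

\[
\mathrm{EBIC} = -2\ell(K) + E\log n + 4E\gamma\log p ,
\]

with \(E\) the number of edges and \(\gamma = 0.5\) by default — the
conservative standard for psychometric networks. \(\gamma = 0\) recovers
the ordinary BIC and yields denser networks. The likelihood convention
omits the additive constant \(-(n/2)\,p\log 2\pi\); it cancels in model
selection, and the `ebic()` examples in the documentation use this
convention.

Each wave is estimated on that wave's complete cases only (listwise
deletion; no imputation), so the estimation `n` differs by wave.

## Tunable parameters that matter

* `gamma` (default 0.5, unitless): sparsity/sensitivity trade-off of the
  EBIC. The default follows the convention of regularized psychometric
  network estimation; lower values admit weaker edges.
* `n_lambda` (100) and `lambda_min_ratio` (0.01): the penalty grid.
* `tolerance` (1e-4): glasso convergence threshold relative to the mean
  absolute off-diagonal of `R`, the reference convention for this
  algorithm family.
* `stop_after` (30 grid points): the descent down the penalty grid stops
  once the EBIC has not improved for this many consecutive points. The
  EBIC along a lasso path is near-unimodal, so this is an exact
  computation saver, not an approximation of the selection; `stop_after =
  0` forces the full grid and, in every case we test, the same selected
  model.
* Correlation `method`: `"pearson"` (default) or `"polychoric"`. Pearson
  on skewed 0–3 items is attenuated relative to the latent scale but is
  deterministic and robust to near-empty top categories; the two-step
  polychoric estimator de-attenuates under the latent-Gaussian model at
  the cost of boundary estimates on degenerate pairs (clamped to ±0.999
  and flagged). Both are exposed; network results in this package default
  to Pearson.

## Bridge centrality conventions

Strength centrality is \(s_i = \sum_j |w_{ij}|\); summed over nodes it
equals twice the global strength \(\sum_{i<j}|w_{ij}|\), an identity the
test suite asserts exactly on every estimated network. Bridge indices use
the fixed two-community partition (depression vs anxiety items):

* *bridge strength*: absolute edge mass to the other community;
* *bridge betweenness*: shortest-path counts restricted to
  cross-community endpoint pairs, with edge lengths \(1/|w_{ij}|\); tied
  shortest paths are counted fractionally (standard betweenness
  semantics); an integer per-pair count is available via
  `fractional = FALSE` for parity with tooling that counts one path per
  pair;
* *bridge closeness*: reciprocal mean distance to the other community,
  zero (and flagged) for nodes with no cross-community path.

Negative edges enter distances through absolute weights; their sign is
preserved in the weight matrix and in difference tests.

## Comparing waves: the paired permutation test

Two statistics compare networks estimated on the same participants at two
waves: structure invariance \(M = \max_{i<j}|w^A_{ij}-w^B_{ij}|\) and
global-strength invariance \(S\), the absolute difference of the two
global strengths. The null distribution swaps each participant's pair of
response vectors between conditions independently with probability 1/2 —
the exchangeability-preserving scheme for dependent samples — and
re-estimates both networks per permutation. p-values use the add-one
estimator \((1+\#\{\text{null} \ge \text{obs}\})/(1+n_{\mathrm{perm}})\),
which cannot return zero. Edge-level differences reuse the same draws and
are Holm-corrected across the edges present in at least one observed
network; across wave pairs (all six by default) a Bonferroni correction
divides the family \(\alpha\).

The test suite checks calibration directly: 200 null replicates of 300
paired observations, 200 permutations each, must reject at close to the
nominal 5% level. That check runs the estimator at \(\gamma = 0\):
at \(\gamma = 0.5\) and these sample sizes both estimated networks are
frequently *empty*, \(M\) degenerates to exactly zero and every p-value
is 1 — the rejection rate then says nothing about calibration. The
permutation scheme itself is identical at any \(\gamma\).

## Stability

Edge accuracy uses a nonparametric bootstrap (row resampling, full
re-estimation, 2.5/97.5 percentile intervals; B = 1000 by default).
Centrality stability uses the case-dropping bootstrap over drop
proportions 0.05–0.75 in steps of 0.05, recording Spearman correlations
with the full-sample centralities. The CS coefficient is the largest drop
proportion at which at least 95% of correlations stay ≥ 0.7; values
above 0.25 are conventionally read as minimally stable. Estimator
failures inside resamples (possible with polychoric boundary cases) are
dropped and counted, and more than 10% of failures aborts the report.

## Change-trajectory network

For each participant observed at all four waves, the OLS slope of each
item on the wave code (0,1,2,3) is computed in closed form; the GGM
estimated on these slope scores links symptoms whose *changes* co-occur.
Time codes are equally spaced integers even though real assessment
occasions are not equally spaced in calendar time: an affine re-coding of
time rescales all slopes by a common factor and leaves the slope
correlation matrix — hence the network — unchanged, so the coding is
immaterial for the result. Slopes are Pearson-correlated (they are
continuous; the polychoric option does not apply). An item that never
changes for anyone is dropped with a warning and kept as an isolated
node.

## The synthetic cohort generator

No participant-level data ship with the package; every stage is validated
against a generator with known ground truth. Its defaults emulate a
4-wave treatment cohort:

* 343 participants at baseline with per-wave complete-case counts
  343/269/261/212 and exactly 210 completing all four waves;
* age ~ N(30.68, 4.10) years, and a dropout log-odds of +0.1 per year of
  age between consecutive waves, so leavers are older on average;
* a sparse ground-truth network on 16 nodes at edge density 0.2: random
  support with uniform raw precision weights in [0.5, 1], 90% positive
  partial correlations, diagonal set to 1.5 × the absolute row sum
  (positive definite by diagonal dominance, with a uniform-shrinkage
  safety net on the minimum eigenvalue), standardized to partial
  correlations — the standard construction for simulating psychometric
  GGMs;
* ordinal items from thresholding the implied latent Gaussian at
  quantiles 0.55/0.80/0.93, mimicking the right-skewed response
  frequencies of low-prevalence symptoms such as suicidal ideation;
* small latent mean drifts across waves (+0.08 per wave on sadness and
  guilt, −0.08 on the anxiety items), emulating the typical shift of
  depressive versus anxious symptom prominence over a treatment course.

Exact per-wave counts are achieved by random trimming/re-retention after
the logistic dropout draw, because the downstream tests need
deterministic sample sizes. Dropout is monotone except for a configurable
number of "intermittent" participants (default 2) who skip the second
wave and return — the only way a cohort can simultaneously show 212
present at the last wave and 210 all-wave completers, as real cohorts do.
Setting `n_completers = retention["T4"]` restores strict monotonicity.

What the generator does **not** emulate: item-level missingness within an
observed wave, time-varying network structure (edge weights are constant
across waves; only means drift), floor/ceiling measurement artifacts, and
informative dropout driven by symptom severity. Passing tests therefore
demonstrate correctness of the estimators and test procedures under a
latent-Gaussian ordinal model — not that any specific real-data finding
is right.

## Sample-size analysis

`recommend_sample_size()` answers: how many participants are needed so
that, with probability `assurance`, an EBIC-glasso network recovers at
least a `sensitivity` fraction of the true edges? Per candidate `n` a
fresh ground-truth network is generated per replicate (100 replicates by
default) at the stated node count and density, `n` ordinal observations
are sampled, the network is re-estimated, and the replicate fraction
reaching the target is smoothed by an isotonic fit; the recommendation is
the smallest candidate whose fitted probability reaches `assurance`. A
10-point coarse grid over 50–1000 is refined once around the crossing
(1,800 replicates in total) — desk-scale, about a minute of CPU.

This quantity is extremely regime-dependent, and users should treat the
estimator configuration as part of the question. At the default
\(\gamma = 0.5\) with the generator's skewed ordinal items, the
recommendation for 16 nodes at density 0.2 (sensitivity 0.6, assurance
0.8) comes out around 530. Lowering \(\gamma\) toward BIC-like selection,
or measuring on less coarsely discretized data, lowers the crossing point
by a factor of two or more — at \(\gamma = 0\) the same question is
answered below 211. Published recommendations from other tools are only
comparable if their selection and data-generation conventions match.

## Numerical choices and degenerate inputs

* Partial correlations below 1e-8 in absolute value are zeroed; edge
  counts are counts of strictly nonzero upper-triangle weights.
* Correlation matrices are repaired to the nearest unit-diagonal PSD
  matrix by eigenvalue clipping when needed (polychoric assembly can be
  indefinite); the repair is idempotent on PSD input.
* `lambda = 0` (no penalty) requires a positive-definite input and
  reproduces the matrix-inverse partial correlations to solver precision.
* The Fruchterman–Reingold layout is computed on the element-wise mean of
  the absolute weight matrices of all supplied networks, so all waves
  share one placement. Initialization is a circle in sorted-label order
  with a seed-derived rotation; the algorithm is therefore deterministic
  given the seed and equivariant under node reordering — properties the
  usual RNG-initialized implementations do not guarantee.
* All bootstrap, permutation and simulation functions take explicit
  seeds, and `run_study()` records every seed, sample size and selected
  penalty in its manifest, so a bundle is regenerable from the config
  alone.

## Problem sizes used by the test suite

The suite validates edge recovery at n = 2000 over 20 generator seeds
(mean sensitivity and specificity ≥ 0.8), permutation-test calibration
over 200 null replicates of 300 pairs with 200 permutations, bridge
indices against exhaustive path enumeration on 50 random networks of up
to 7 nodes, slope closed forms against `lm()` on all 256 possible 4-point
0–3 series, and the cohort generator's counts exactly. These sizes were
chosen to make Monte-Carlo margins small relative to the asserted
thresholds while keeping a full run in minutes on one core.

## Known limitations

* Pairwise wave comparisons on common completers, not a joint
  longitudinal model; no temporal (VAR) networks.
* The polychoric estimator is two-step and pairwise; no polyserial or
  tetrachoric variants, and no pairwise-deletion correlations.
* Bridge centrality assumes the fixed instrument-defined two-community
  partition; no community detection.
* The sample-size analysis measures edge-recovery sensitivity only, not
  specificity or weight accuracy.
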