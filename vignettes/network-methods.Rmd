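---
title: "Methods: regularized partial-correlation networks for ordinal symptom surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized partial-correlation networks for ordinal symptom surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the model and its assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical conventions, and the design decisions taken where the methodology
leaves room.

## The model

`symptomnet` treats a respondent-by-item table of ordinal survey responses
as a sample from a latent Gaussian graphical model (GGM). The precision
matrix $K = \Sigma^{-1}$ encodes conditional independence: items $i$ and
$j$ are conditionally independent given all others exactly when
$\kappa_{ij} = 0$. Edge weights are partial correlations
$\rho_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$.

Estimation proceeds in three steps:

1. **Association.** Spearman rank correlations (midrank tie handling) over
   complete cases. Rank correlations are invariant to monotone transforms
   and considerably more stable than Pearson correlations on skewed
   Likert items. If the resulting matrix is not positive definite it is
   projected to the nearest correlation matrix (Higham alternating
   projections) and, if necessary, blended minimally with the identity so
   the smallest eigenvalue reaches a floor of $10^{-8}$.
2. **Graphical lasso.** For each penalty $\lambda$ on a 100-point
   log-spaced grid from $\lambda_{\max} = \max_{i \ne j} |S_{ij}|$ down to
   $0.01\,\lambda_{\max}$, the blockwise coordinate-descent graphical lasso
   maximizes $\log\det K - \mathrm{tr}(SK) - \lambda \sum_{i\ne j}
   |\kappa_{ij}|$ with the diagonal unpenalized. Shrunk entries are exact
   zeros by construction (soft thresholding), so the sparsity pattern needs
   no post-hoc cutoff.
3. **EBIC selection.** Each path member is scored by
   $\mathrm{EBIC} = -2L + E\log n + 4E\gamma\log p$ with
   $L = (n/2)(\log\det K - \mathrm{tr}(SK))$ and $E$ the number of nonzero
   upper-triangle off-diagonals of the regularized precision (numerical
   zero $10^{-10}$; no refit of the selected model). The minimizing
   $\lambda$ is selected. $\gamma = 0.5$ is the default everywhere: it
   suppresses false-positive edges at some cost in sensitivity, the usual
   compromise in psychopathology networks.

The assumptions worth keeping in mind: monotone latent-to-observed
relations (Spearman recovers latent ordering, not the latent correlations
themselves — ordinal discretization attenuates them), a single
homogeneous population per fitted network, and enough respondents relative
to nodes for the penalized likelihood to be informative.

## Inference on the fitted network

- **Expected influence** is the one-step signed sum of a node's edge
  weights. Betweenness and closeness are deliberately not offered — they
  are unreliable on psychometric networks — and plain strength is
  misleading when negative (protective) edges exist.
- **Bridge expected influence** restricts the sum to edges that leave the
  node's community; it flags symptoms that transmit activation between
  communities. The one-step variants are used for both statistics.
- **Predictability** is the in-sample $R^2$ of an ordinary least-squares
  regression of each node on its estimated neighbours; isolated nodes get
  0. The mixed-graphical-model nodewise approach used elsewhere in the
  literature treats each ordinal item by its conditional family; since the
  whole pipeline here already treats items as ordinal-continuous (the
  Spearman choice), the package stays within the Gaussian view. The
  population cross-check is available in closed form: for unit-variance
  variables $R^2_j = 1 - 1/\kappa_{jj}$ (`implied_predictability()`), and
  the test suite verifies the sample statistic approaches it on latent
  (continuous) draws. On discretized items the observed predictability is
  systematically lower — attenuation, not error.
- **Global strength** is the sum of absolute edge weights.

## Stability and accuracy

The nonparametric bootstrap resamples respondents with replacement and
re-runs the *entire* pipeline per replicate with identical settings; edge
CIs use the percentile rule. Difference tests declare two edges (or two
nodes' expected influence) different when the bootstrap interval of their
difference excludes zero. Case-dropping re-estimates on subsets of
$(1-q)\,n$ respondents over the grid $q \in \{0.05, 0.10, \dots, 0.75\}$
and records the Spearman correlation between subset and full-sample
expected influence (rank stability is what the CS statistic certifies; a
Pearson option exists). The CS coefficient is the largest tested $q$ at
which at least 95% of subsamples retain correlation $\ge 0.7$; above 0.5
is conventionally "good stability". Replicates whose estimation fails
(e.g. a resample with a constant or perfectly collinear column) are
excluded and counted rather than retried, keeping the resampling
distribution honest.

## Two-group comparison

The permutation network comparison test re-estimates both group networks
under random relabelings that preserve group sizes — each permutation runs
the full EBIC-glasso selection, not a fixed-$\lambda$ shortcut — and
computes, in a single pass, the maximum absolute edge difference $M$
(structure invariance), the absolute global-strength difference $S$, and
per-edge absolute differences. P-values use the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{\text{perm}})$, which is
never zero and valid under exchangeability. The per-edge family is the set
of edges present in at least one observed group network, and raw p-values
are Holm-adjusted; this keeps the family interpretable while controlling
the family-wise error rate. The permutation seed defaults to 123, the
conventional seed for this test. The centrality-invariance variant is not
implemented in this version.

## Communities

Walktrap community detection runs on absolute edge weights — negative
partial correlations cannot be random-walk transition probabilities, and
taking magnitudes is standard exploratory-graph-analysis practice; signs
remain available to bridge expected influence. Walk length is 4 (the
conventional default), the dendrogram cut maximizes weighted modularity,
and the algorithm is deterministic given the weight matrix. Isolated nodes
become flagged singleton communities. Community ids are contiguous
integers starting at 1, the R convention for membership vectors.

## The synthetic-data generator

Because raw survey data of this kind are typically not deposited, the
generator is a first-class module: every downstream stage is validated
against data with known truth.

A `ggm_spec` holds a sparse partial-correlation matrix (optionally
organized into communities), per-node thresholds and a seed. Sampling
draws latent scores from the implied correlation-scale covariance and
discretizes by thresholds; by default thresholds are equal-probability cut
points for the declared number of categories, which maximizes the
information available to rank-based recovery. Positive definiteness is
enforced by one deterministic symmetric rescaling of the off-diagonals
(eigenvalue arithmetic gives the exact factor), preserving the sparsity
pattern — not by rejection sampling.

The two-group variant multiplies one group's nonzero partials by a
strength multiplier (applied on the partial-correlation scale, before any
PD repair, which is also how the comparison test measures differences) and
adds planted per-edge deltas. A multiplier is only meaningful if the base
network leaves eigenvalue headroom: the specs used for comparison
benchmarks are built with a smallest precision eigenvalue of 0.3 so that a
1.3x multiplier still yields a valid model; without that headroom the PD
repair would silently undo the planted difference.

The 28-node `study_fixture()` mirrors a pandemic-era student survey
layout: three scale-aligned symptom communities (9 depression, 7 anxiety,
6 acute-stress items, four ordinal categories each), four recoded stressor
nodes (three levels), and two 7-point social-support nodes with negative
(protective) edges into suicidality and related symptoms, plus planted
group differences echoing the kinds of edges reported to differ by
infection history. Default size is 1,000 respondents per group with a
1.3x group-1 multiplier. Item marginals are a modelling choice
(equal-probability categories), not calibrated to any published marginal
distributions.

What passing tests on these data do **not** show about real surveys:
robustness to non-monotone item functioning, missingness beyond
complete-case analysis, sampling designs (snowball recruitment,
self-selection), measurement non-invariance between groups, or marginal
skew heavier than the generator produces.

## Preprocessing conventions

Scale totals are item sums; "probable case" means total $\ge 10$ on a
9/7/6-item scale. Correlated stressor domains are merged by the mean of
the two 0–4 ratings and every stressor node is collapsed to three levels.
The published anchors fix 0 and the "2 or more" boundary but leave
fractional merged means unassigned; the package maps 0 to 0, values in
(0, 2) to 1, and [2, 4] to 2, preserving the "2 or more is stressful"
anchor. Odds ratios use the Wald log-scale interval and a
continuity-corrected chi-square test (adequate at survey sample sizes;
Fisher's exact test is available as an option), with the Haldane 0.5
correction flagged when a cell is zero.

## Numerical choices

- Coordinate-descent convergence: mean-absolute-offdiagonal-scaled
  tolerance, $10^{-4}$ for routine path fits (the conventional level),
  tightened to $10^{-12}$ in oracle-comparison tests; correctness against
  an independent proximal-gradient (FISTA) solver is part of the test
  suite at objective tolerance $10^{-6}$.
- $\lambda = 0$ short-circuits to the closed-form inverse; penalties at or
  above $\lambda_{\max}$ provably give the empty network, and the solver
  returns it exactly.
- An all-zero correlation off-diagonal collapses the path to a single
  $\lambda = 0$ with a warning. Perfectly correlated columns abort
  estimation with an informative error (a duplicated item cannot enter a
  partial-correlation model).
- Ties in the walktrap merge sequence are resolved by igraph's
  deterministic ordering, so partitions are byte-reproducible.
- One global seed spawns independent per-stage streams (fixture sampling,
  bootstrap, case-dropping, permutations), so toggling one stage never
  changes another stage's draws.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own benchmark scales: oracle equivalence on 100
random 4-node problems; support recovery at $p = 15$, density 0.2,
$n = 3000$, 20 seeds; comparison-test calibration with two groups of 300
at $p = 8$ over 100 replicates of 200 permutations; community recovery on
three planted blocks of five at $n = 3000$ over 20 seeds; stability on a
10-node, $n = 2000$ network with 200 bootstrap replicates; and the full
pipeline on the 28-node fixture at 1,000 per group with 1,000 bootstrap
replicates and 1,000 permutations in `scripts/acceptance.R`.

## Known limitations

EBIC selection with $\gamma = 0.5$ is often described as conservative, but
its specificity is not monotone in $n$: when strong edges meet large
samples the likelihood rewards de-biasing those edges, the selected
$\lambda$ moves down the path, and small spurious edges (here on the order
of $|w| \le 0.03$) enter the model — an effect visible even when the exact
latent correlation matrix is supplied, and amplified on ordinal data
because the Spearman matrix of discretized Gaussians is an elementwise
distortion of the latent correlations whose inverse is not exactly sparse.
The support-recovery benchmark in the test suite reports both sensitivity
and specificity at $n = 3000$ so this behaviour is measured rather than
hidden.

Polychoric correlations are not offered in this version (raw Spearman
only, matching the estimation convention the pipeline follows); no
nonparanormal transforms, Bayesian GGMs, thresholded/refit variants, BCa
intervals, bridge-centrality stability, covariate adjustment, or
more-than-two-group comparisons. Confirmatory factor analysis of the
recovered communities is out of scope. Predictability from the Gaussian
nodewise view is not numerically identical to mixed-graphical-model
predictability on the same data, and no such equality is claimed.
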