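# symptomnet

Regularized partial-correlation network analysis for ordinal symptom
surveys — the network-psychometrics workflow used to study how
psychopathology items, stressors and protective factors interact, built as a
single tested R package with a synthetic-data generator so that every stage
can be benchmarked against a known ground truth.

It is aimed at researchers analysing Likert-type mental-health surveys
(e.g. PHQ-9 depression, GAD-7 anxiety, IES-6 acute stress items alongside
stressor ratings and social-support items), who want the full chain:
estimation, centrality, stability, two-group comparison and community
detection, with reproducible seeds throughout.

## The model

Item responses are modelled through a Gaussian graphical model: a
multivariate Gaussian whose precision matrix K encodes conditional
independence. Edges are partial correlations

    rho_ij = -kappa_ij / sqrt(kappa_ii * kappa_jj),

the association between two items controlling for all others. On a Spearman
correlation matrix S (robust for ordinal items; repaired to positive
definiteness when needed) the package maximizes the L1-penalized
log-likelihood

    log det K - tr(S K) - lambda * sum_{i != j} |kappa_ij|

over a decreasing 100-point penalty path (graphical lasso, diagonal
unpenalized) and selects lambda by the extended Bayesian information
criterion

    EBIC = -2 L + E log n + 4 E gamma log p,    gamma = 0.5,

where E is the number of estimated edges. On top of the fitted network it
computes:

- **expected influence** `EI_i = sum_j w_ij` and **bridge expected
  influence** (the same sum restricted to edges leaving a node's community);
- **predictability**: per-node R² from OLS on network neighbours;
- **global strength**: sum of absolute edge weights;
- **bootstrap accuracy** (percentile edge CIs, difference tests) and
  **case-dropping stability** summarized by the CS coefficient — the largest
  fraction of cases droppable while, with 95% certainty, subset centrality
  still correlates ≥ 0.7 with the full-sample centrality;
- the **network comparison test**: permutation p-values for the maximum edge
  difference M, the global-strength difference S, and Holm-corrected
  per-edge differences between two groups;
- **walktrap communities** (exploratory graph analysis) on absolute weights.

The synthetic-data module samples ordinal items from known sparse graphical
models (latent Gaussian + thresholds), including a 28-node two-group fixture
shaped like a pandemic-era student mental-health survey, so recovery,
calibration and power can be verified.

## Worked example

```r
library(symptomnet)

spec <- random_sparse_ggm(p = 10, edge_density = 0.2, seed = 3,
                          n_respondents = 2000)   # known truth: 8 edges
tab  <- sample_ordinal_responses(spec)            # 2000 x 10 ordinal table
fit  <- ebic_glasso(tab$values)                   # the central fit
fit
#> Regularized partial correlation network (EBIC graphical lasso)
#>   nodes: 10   edges: 11 / 45 possible   n = 2000
#>   gamma = 0.50   selected lambda = 0.04375 (path index 46/100)
#>   global strength = 1.318

head(centrality_table(fit, data = tab$values), 4)
#>   node expected_influence predictability
#> 1   V1          0.3148782     0.07613862
#> 2   V2          0.2434662     0.05546438
#> 3   V3          0.5650810     0.18521569
#> 4   V4          0.0000000     0.00000000

unlist(recovery_scores(fit, spec))[1:4]
#>       sensitivity       specificity      n_true_edges n_estimated_edges
#>         1.0000000         0.9189189         8.0000000        11.0000000
```

Every true edge was recovered (sensitivity 1.00) with 3 spurious weak edges
among 37 true non-edges (specificity 0.92); the EBIC-selected penalty and
the resulting global strength are printed by the fit. `summary()`, `coef()`,
`plot()`, `predict()` and `simulate()` methods expose the fitted model; the
two-group pipeline is one call:

```r
fx  <- study_fixture(seed = 1)            # 28-node, two-group ordinal data
out <- run_full_analysis(fx$table, analysis_config(out_dir = "run1"))
out$comparison                            # permutation network comparison
```

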