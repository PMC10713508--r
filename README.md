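# shsnet

Psychometric network analysis for the 25-item Suboptimal Health Status
Questionnaire (SHSQ-25) and similar ordinal instruments. The package is
aimed at researchers who want to move beyond sum scores and ask how
*symptoms relate to each other directly*: which complaints co-occur after
conditioning on all the others, how central each symptom is, how stable
those conclusions are under resampling, and whether two populations (here:
optimal vs suboptimal health status, split at the median total score)
differ in network structure.

## The model

Item responses are treated as discretised views of a latent multivariate
normal vector, so item--item association is measured by polychoric
correlation. The network itself is a Gaussian graphical model: the zeros of
the precision matrix Θ = Σ⁻¹ encode conditional independence, and edge
weights are regularised partial correlations
ρᵢⱼ = −θᵢⱼ / √(θᵢᵢ θⱼⱼ). Sparsity comes from the graphical lasso,

  maximise  log det Θ − tr(SΘ) − λ Σᵢ≠ⱼ |θᵢⱼ|,

with λ chosen on a 100-value log-spaced path by minimising the extended
BIC, EBIC_γ = −2ℓ + E log n + 4γE log p, at the conventional γ = 0.5.
Around that core the package provides scoring and median-split
stratification, group comparisons with pooled-SD Cohen's d, centrality
(strength / closeness / betweenness) and node predictability
(1 − 1/θⱼⱼ), nonparametric bootstrap edge intervals and bootstrapped
difference tests, the case-dropping bootstrap with CS-coefficients,
a permutation-based two-group network comparison test, ordinal
(non-metric) MDS with Shepard output, and a seeded Fruchterman–Reingold
layout. A synthetic-cohort generator with a known sparse latent structure
(calibrated to the published per-item means of the two study populations)
makes the whole pipeline testable end to end.

## A worked example

```r
library(shsnet)

truth  <- shs_truth(p = 25, density = 0.19, seed = 2026)   # known structure
cohort <- generate_cohort(truth, cohort_preset("suboptimal_like"), seed = 1)
net    <- shs_network(cohort, method = "polychoric")
net
#> Regularised partial-correlation network (polychoric, EBIC gamma = 0.5)
#>   25 nodes, 89/300 edges (density 0.297), lambda = 0.1664, n = 111

summary(net)
#> edges: 89 / 300  density: 0.297
#> mean |weight| over edges: 0.100  global strength: 8.884
#> lambda: 0.1664  EBIC: 2743.87  n: 111

cent <- centrality_indices(net)
head(cent[order(-cent$strength), c("node", "strength", "strength_z")], 3)
#>    node strength strength_z
#> 2   CS2 1.606690  2.4122787
#> 6   DS3 1.531733  2.2104645
#> 25  MH7 1.065424  0.9549729

recovery_metrics(net, truth)
#> $sensitivity   0.8245614
#> $specificity   0.8271605
#> $weight_correlation   0.853842
```

At n = 111 the estimator recovers 82% of the true edges while keeping 83%
of the true non-edges at zero, and the recovered weights correlate 0.85
with the truth — with more respondents sensitivity reaches 1 (specificity
behaves more subtly; see the methods vignette). Published group summaries
ship with the package, so printed effect sizes recompute directly:

```r
d <- cohens_d(53.09, 7.57, 106, 57.02, 10.43, 111)   # age, by status group
round(as.numeric(d), 2)
#> [1] 0.43
```

A complete analysis — scoring, median split, per-group networks,
bootstrap accuracy, stability, embeddings and the two-group comparison,
all written to disk with a checksummed manifest — is one call:

```r
run_pipeline(pipeline_config(method = "polychoric", seed = 2026), "shs-run")
```

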