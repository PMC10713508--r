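---
title: "Psychometric network analysis of suboptimal health: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Psychometric network analysis of suboptimal health: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific setting

The SHSQ-25 is a 25-item screening questionnaire for *suboptimal health
status* — the intermediate state between health and diagnosable disease.
Respondents rate how often they experienced each complaint in the preceding
three months on a five-point scale (0 = never, 4 = always). Items group into
five domains: cardiovascular (CS, 3 items), digestive (DS, 3), fatigue
(FT, 9), immune (IS, 3) and mental health (MH, 7). A respondent's total
score is the sum of the 25 ratings; the sample median of the total splits a
cohort into an *optimal* (at or below) and a *suboptimal* (above) group.

`shsnet` treats the items of each group as nodes of a **Gaussian graphical
model** (GGM). In a GGM the joint distribution is multivariate normal and
the zeros of the precision matrix $\Theta = \Sigma^{-1}$ encode conditional
independence: item $i$ and item $j$ are connected exactly when
$\theta_{ij} \neq 0$, and the edge weight is the partial correlation
$\rho_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$ — the association
between two symptoms after conditioning on all other symptoms. These
networks are read as hypotheses about symptom interplay: which complaints
hang together directly rather than through shared neighbours.

# The estimator

With $p = 25$ items and around a hundred respondents per group, the
unpenalised precision estimate is hopeless; `shs_network()` therefore uses
the graphical lasso,
$$\hat\Theta(\lambda) = \arg\max_{\Theta \succ 0}\;
  \log\det\Theta - \mathrm{tr}(S\Theta) -
  \lambda \sum_{i \neq j} |\theta_{ij}|,$$
with the diagonal unpenalised (so $\lambda = 0$ reproduces $S^{-1}$
exactly). The solver is a C++ block coordinate descent with warm starts
along a penalty path of `n_lambdas = 100` values log-spaced from
$\lambda_{\max}$ (the largest absolute off-diagonal of $S$, where the graph
is empty) down to $0.01\,\lambda_{\max}$. A detail that matters in
practice: the inner lasso solves are iterated to a tolerance one order
tighter than the sweep-level threshold, otherwise the outer loop chases
coefficient noise and never settles on ill-conditioned inputs.

The penalty is selected by minimising the **extended BIC**
$$\mathrm{EBIC}_\gamma = -2\ell(\hat\Theta) + E\log n + 4\gamma E \log p,$$
where $\ell = (n/2)(\log\det\Theta - \mathrm{tr}(S\Theta))$ up to constants
and $E$ is the number of nonzero off-diagonal pairs. The default
$\gamma = 0.5$ is the conventional EBICglasso setting for psychometric
networks; ties are broken toward the larger penalty, i.e. the sparser
model. We read the phrase "tuning parameter set to 0.5" in this literature
as the EBIC hyperparameter $\gamma$, not a fixed $\lambda$ — the penalty
itself is always chosen by the criterion.

## The association matrix

Items are 5-point ordinal variables, so the default zero-order association
is the **polychoric correlation**: item pairs are modelled as discretised
bivariate normals, thresholds are estimated from the marginal cumulative
proportions by the inverse normal CDF, and the latent correlation maximises
the bivariate-normal cell-probability likelihood of the contingency table
(two-step estimator; the bivariate normal CDF is a C++ implementation of
the Drezner–Wesolowsky/Genz Gauss–Legendre scheme, exact to machine
precision against independent quadrature). Pearson and Spearman matrices
are available as sensitivity analyses; both are attenuated by the
discretisation, and the attenuation is uneven across pairs, so they distort
the latent partial-correlation structure in ways the polychoric estimator
avoids. Correlations are capped at $|r| \le 0.999$ to keep log-determinants
finite, and a non-positive-definite matrix (common for polychoric) is
repaired by eigenvalue clipping with a floor of $10^{-4}$ and rescaling to
unit diagonal — the floor is deliberately far above machine tolerance so
that repaired matrices remain numerically workable for the solver.

## Node-level descriptors

Centrality uses the standard psychometric-network conventions: strength
$\sum_j |w_{ij}|$; distances $d_{ij} = 1/|w_{ij}|$ on present edges;
closeness as the reciprocal of a node's total shortest-path distance within
its connected component (cross-component distances are excluded rather than
set to infinity, and component sizes are reported — the published networks
are connected, so this only matters for degenerate fits); betweenness as
shortest-path counts. Absolute weights are used throughout so that negative
edges still contribute to connectivity.

Node **predictability** — the share of a node's variance its neighbours
explain — is computed analytically from the selected precision matrix: on
the correlation scale the residual variance of node $j$ given the rest is
$1/\theta_{jj}$, so predictability is $1 - 1/\theta_{jj}$, which equals the
nodewise regression $R^2$ when no penalty is applied. An empirical refit
variant (`method = "refit"`: OLS of each standardised item on its selected
neighbours) is provided as a cross-check. Published predictability values
for ordinal data were likely computed by a nodewise procedure that the
source literature does not fully specify; exact numerical reproduction is
not possible without the raw data, so the analytic Gaussian definition is
the package's documented choice.

## Resampling diagnostics

*Accuracy*: `bootstrap_edges()` resamples respondents with replacement
(default $B = 500$) and re-runs the entire pipeline per resample —
correlation matrix, penalty path, EBIC selection — yielding per-edge 95%
quantile intervals (quantile rather than BCa, matching common practice in
this literature). `difference_tests()` flags pairs of edges (or node
strengths) whose bootstrapped difference interval excludes zero.

*Stability*: `case_drop_stability()` implements the case-dropping
(subsetting) bootstrap: for each drop proportion $q$ in a grid (default
0.05–0.75 in steps of 0.05, 50 subsamples per level) it re-estimates the
network on a random subset of $\lfloor(1-q)n\rfloor$ respondents and
correlates the subset centralities with the full-sample ones. The
CS-coefficient is the largest $q$ at which the empirical 5th percentile of
those correlations still reaches 0.7; values above 0.25 (preferably 0.5)
are conventionally read as stable. The source literature does not print its
drop grid; the default grid is an implementation choice recorded in the
output metadata.

## Two-group comparison

`network_comparison_test()` compares the optimal and suboptimal networks by
permutation: respondents are pooled, group labels reshuffled with the group
sizes preserved exactly, and both networks re-estimated per permutation.
Because the phrase "global variance test" is ambiguous in this literature,
two connectivity statistics are computed side by side: the absolute
difference in global strength ($\sum |w_{ij}|$ over pairs) and the maximum
absolute edge difference. P-values use the add-one estimator
$p = (1 + \#\{T_{perm} \ge T_{obs}\})/(1 + n_{perm})$, which can never be
zero and is conservative under the null. The permutation draw reshuffles
one pooled index vector, which makes the result exactly invariant to which
group is labelled A. The weighted-adjacency correlation (Pearson, over
vectorised lower triangles, zeros included) quantifies structural
similarity alongside the test.

## Embeddings

`ordinal_mds()` is a SMACOF implementation of non-metric MDS:
disparities are fitted to configuration distances each cycle by isotonic
regression on the rank order of the input dissimilarities (ties pooled),
rescaled to the distance norm, and the configuration is updated by the
Guttman transform; Kruskal stress-1 is reported together with the Shepard
triples (dissimilarity, distance, disparity). The initial configuration is
the classical-scaling solution, so the result is deterministic; a seed only
perturbs degenerate starts. Dissimilarities default to
$d_{ij} = \sqrt{1 - |r_{ij}|}$ so that strong associations of either sign
place items near each other (the signed variant $\sqrt{1 - r}$ is
available by flag; the source literature does not state its transform).
`fr_layout()` provides the seeded Fruchterman–Reingold force-directed
layout with $|w|$ as attraction strength.

# The synthetic cohort generator

The study's respondent-level data are not deposited, so validation runs on
synthetic cohorts with a **known** sparse structure. `shs_truth()` draws a
random symmetric edge pattern of the requested density (default 0.19, the
published item-network density), assigns partial correlations with
magnitudes in `weight_range = c(0.15, 0.4)` and a 15% chance of a negative
sign (questionnaire networks are predominantly positive), and repairs the
implied precision matrix to positive definiteness by a uniform eigenvalue
shift followed by re-standardisation — simple, reproducible, and recorded
in the realised weights.

`generate_cohort()` is a Gaussian copula: a latent multivariate normal
sample with the truth's correlation matrix, discretised item by item
through four thresholds. The packaged presets carry the published per-item
means and SDs of the two study populations; for each item the thresholds
are the normal quantiles of the category probabilities of a
$N(\mu^*, \mathrm{sd}_{target})$ binned at half-integers, with $\mu^*$
tuned by deterministic 1-D root finding so the discretised mean equals the
published mean exactly. Means are the calibration target; SDs are emergent
(the source tables give only means and SDs, not category frequencies, so
exact response-profile replication is impossible and not attempted).
Everything is reproducible from the seed and the configuration alone.

What the generator does *not* emulate: item-specific skew beyond what the
mean/SD targets induce, respondent-level covariates other than the group
label, local dependence violating the latent-normal assumption, and
careless-response artefacts. Passing recovery tests on these cohorts
therefore show that the estimator works when its model assumptions hold —
they cannot certify performance on real survey data.

# Validation design and known limits

Every stage is tested against an independent oracle where one exists: the
solver against a Nelder-Mead-plus-polish numeric optimiser of the penalised
objective ($p \le 3$, agreement within $10^{-4}$, typically $10^{-6}$); the
polychoric estimator against a brute-force likelihood grid with independent
quadrature; betweenness against exhaustive path enumeration ($p \le 7$);
predictability against nodewise regression $R^2$; MDS against
generate-then-recover with Procrustes comparison; the permutation test
against its nominal type-I error (200 null repeats of 200 permutations at
$n = 200 + 200$; the null model is a $p = 6$, density 0.25 truth with
Pearson correlations and a 30-value path — sizes chosen so the calibration
study completes on a desk machine).

Two behaviours deserve explicit mention.

**Specificity of EBIC-glasso is not monotone in $n$.** Sensitivity rises
to 1 quickly, but as $n$ grows the selected penalty shrinks and tiny
spurious edges ($|w| \approx 0.01$) enter the model: mean specificity in
the recovery study drifts from about 0.92 at $n = 250$ to about 0.89 at
$n = 2000$ before recovering very slowly at much larger $n$. This occurs
even on raw latent Gaussian data with Pearson correlations, and the solver
matches the numeric optimum, so it is a property of EBIC penalty selection
(which is not support-consistent), not an implementation artefact. Analyses
should read the estimated graphs as weight estimates with controlled false
discovery at moderate $n$, not as exact support recovery.

**Median-split groups can yield empty networks.** Conditioning on the
total score restricts its components' variance and attenuates their
correlations; at $n \approx 110$ an optimal-status group simulated from the
low-mean preset can genuinely select the empty model. Downstream stages
degrade gracefully: stability returns `NA` CS-coefficients with a warning,
and the comparison test reports an undefined adjacency correlation rather
than aborting.

Other numerical choices, collected: correlation cap 0.999; PD-repair
eigenvalue floor $10^{-4}$ for correlation matrices (the standalone
`nearest_pd()` defaults to $10^{-8}$); solver tolerance $10^{-6}$ relative
to the mean absolute off-diagonal with a 10,000-sweep cap; EBIC ties to the
sparser model; "mean edge weight" defaults to the mean of absolute values
over nonzero edges (signed and all-pairs variants are options, since the
convention is not fixed in the literature); strict missing-data policy
(refuse to score incomplete rows; lenient mode drops them with a warning;
never impute); median-split ties to the optimal group, configurable;
effect-size bands negligible/small/medium/large at 0.2/0.5/0.8 (note that
a published table labels $d = 0.43$ "medium"; the package applies the
standard bands to new data and ships the printed table verbatim for
reproduction); pooled-variance t-tests so that $t$ and Cohen's $d$ share
one pooled SD.

# Reproducing a full analysis

```{r pipeline}
library(shsnet)
cfg <- pipeline_config(method = "polychoric", seed = 2026)
manifest <- run_pipeline(cfg, output_dir = "shs-run")
```

The pipeline scores the cohort (simulating both presets when no input CSV
is given), splits at the median, and per group estimates the network and
writes summaries, centralities, predictabilities, bootstrap edge intervals,
drop-curves with CS-coefficients and the MDS embedding, then the two-group
comparison; `manifest.json` lists every artefact with its MD5 checksum. One
master seed spawns fixed per-stage seeds, so re-running any stage in
isolation reproduces the full run's outputs bit for bit.
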