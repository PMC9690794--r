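---
title: "Estimating psychological networks from ordinal questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating psychological networks from ordinal questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ordnet` estimates and analyses Gaussian Graphical Models (GGMs) for
ordinal questionnaire items — the workhorse of network psychometrics.  In a
GGM the nodes are items and the edges are partial correlations: the
association between two items after conditioning on every other item in the
set.  If $K = \Sigma^{-1}$ is the precision matrix of the latent item
scores, the edge weights are

$$ w_{ij} = -\frac{K_{ij}}{\sqrt{K_{ii} K_{jj}}}, $$

so a zero precision entry means conditional independence and no edge.
Because partial correlations estimated from finite samples are never
exactly zero, the precision matrix is estimated by the graphical lasso:
penalised maximum likelihood

$$ \hat K_\lambda = \arg\max_{K \succ 0} \; \log\det K - \mathrm{tr}(RK)
   - \lambda \sum_{i \neq j} |K_{ij}|, $$

which sets small entries to exact zeros and yields a sparse, interpretable
network.  The penalty $\lambda$ is chosen by minimising the Extended
Bayesian Information Criterion,

$$ \mathrm{EBIC}_\gamma = -n\left(\log\det K - \mathrm{tr}(RK)\right)
   + E \log n + 4 E \gamma \log p, $$

with $E$ the number of nonzero upper-triangle entries.  The likelihood term
uses the penalised estimate itself (no refit), matching the convention of
the EBIC-glasso procedure widely used in this literature.

### Ordinal items and polychoric correlations

Likert-type items (here: five categories) are treated as discretisations of
latent standard-normal variables.  The input matrix $R$ is therefore the
polychoric correlation matrix, estimated pair by pair with the two-step
estimator: thresholds are fixed at the normal quantiles of the marginal
cumulative proportions, then the latent correlation maximises the
bivariate-normal likelihood of the two-way contingency table by
one-dimensional search on $(-0.999, 0.999)$.  Cell probabilities come from
a numerically stable bivariate-normal CDF (Genz's algorithm) and are
floored at $10^{-12}$ so sparse cells cannot produce infinite
log-likelihoods.  Estimates that hit the search boundary signal
near-duplicate items and are reported with a warning.

Missing responses are handled by pairwise deletion — each correlation uses
the rows complete for that pair, and the per-pair counts are retained.
Pairwise deletion can produce an indefinite matrix; if so, negative
eigenvalues are clipped to $10^{-6}$, the matrix is rescaled to unit
diagonal, and the repair is flagged.  Under pairwise deletion there is no
single $n$ for the EBIC; the package uses the mean of the off-diagonal
complete-pair counts (configurable), which at the low missingness rates
this design targets (about 1%) differs negligibly from any other
convention.

## Downstream analyses

* **Communities.**  The walktrap algorithm (short random walks, merged
  agglomeratively, cut at maximum weighted modularity) on the absolute
  weight matrix, with `steps = 4`.  Uncertainty in the *number* of
  communities is quantified by a parametric bootstrap: the correlation
  matrix implied by the fitted network is resampled, discretised with the
  item thresholds, and the full pipeline — polychorics, EBIC-glasso,
  walktrap — is re-run per replicate, so all estimation noise propagates.
  Two 95% intervals are reported: the percentile interval of the counts
  (wide by construction on integers) and a normal-approximation interval
  around the mean count, $\bar c \pm 1.96\,\mathrm{sd}(c)/\sqrt{B}$.  On a
  well-separated three-community instrument the latter is an interval like
  $[2.99, 3.01]$ — the natural way to obtain sub-integer bounds on an
  integer statistic.
* **Block connectivity.**  For every community pair (including each
  community with itself) the root mean squared edge weight
  $\mathrm{RMSEW} = \sqrt{\mathrm{mean}(w^2)}$ over *all* node pairs of the
  block, zero-weight pairs included, plus the mean and SD of $|w|$.
  Including the zeros is deliberate: block summaries should reflect how
  densely, not only how strongly, two communities connect, and it explains
  SDs exceeding means in sparse blocks.
* **Centrality.**  Strength $s_i = \sum_j |w_{ij}|$, eigencentrality (the
  Perron vector of $|W|$ on the largest component, scaled to maximum 1),
  and bridge strength (the part of $s_i$ going to other communities).
  Absolute weights are used throughout — strength is defined on absolute
  weights, and extending that convention to eigencentrality and the
  walktrap input is standard for signed psychological networks.
  Betweenness and closeness are deliberately absent: conditional
  associations are not distances, so path-length centralities have no
  meaningful interpretation here.  Z-standardised columns use the sample
  (n−1) SD.
* **Clustering.**  The weighted global clustering coefficient is the
  Zhang–Horvath variant on max-normalised absolute weights (mean over
  nodes with at least two neighbours); Onnela and Barrat variants are
  available behind a switch for sensitivity analyses.  Zhang–Horvath is
  the default because it is the variant implemented in the psychometric
  network software family this package parallels.
* **Backbone.**  The minimum spanning tree of the Gower distance
  $d_{ij} = \sqrt{2(1 - w_{ij})}$, computed with Kruskal's algorithm and
  union-find.  The signed weight is used by default — a negative partial
  correlation is *farther* than a zero one under the similarity-to-distance
  transform; an absolute-weight switch is provided.  Zero-weight pairs get
  $d = \sqrt 2$, so the distance graph is complete and a tree always
  exists.  Ties are broken by lexicographic node-pair order, making trees
  reproducible on tied inputs; since the MST depends on distances only
  through their order, the choice between $\sqrt{2(1-w)}$ and $1-w$ is
  immaterial to the topology (and tested to be).
* **Stability.**  Edge-weight precision by nonparametric bootstrap
  (respondents resampled with replacement, full re-estimation per
  replicate, percentile CIs); stability by the case-dropping bootstrap CS
  coefficient — the largest proportion of cases that can be dropped such
  that with 95% probability the subsample statistic still correlates at
  least 0.7 (Pearson) with the full-sample statistic.  Values of 0.25 are
  considered the minimum and 0.50 preferable.  The default drop grid is
  0.05 to 0.75 in steps of 0.05 with 250 subsamples per level; the
  correlation for edge weights is computed over the entries nonzero in the
  original network.  Whether the cited methodology uses Pearson or
  Spearman here is not documented; Pearson is the default because the
  statistic vectors are continuous and approximately linearly related
  under case dropping.

## The synthetic-data generator

Real questionnaire data of this kind are typically confidential, so the
package ships a generator that every downstream stage is tested against.
`generate_true_ggm()` builds a ground-truth precision matrix with planted
blocks:

1. exactly `round(density * p(p-1)/2)` edges are placed, allocated across
   block pairs and sampled uniformly without replacement within them;
2. off-diagonal magnitudes are uniform on [0.1, 0.4] (before repair),
   yielding realised partial correlations of roughly 0.05–0.25 — the range
   reported for psychological networks;
3. edge signs follow a block pattern; the default three-block instrument
   (7 stress + 6 coping + 4 support items) uses positive within-block
   edges, negative stress–coping and stress–support edges, and positive
   coping–support edges, the sign structure stress/coping/support theory
   predicts;
4. positive definiteness is guaranteed by diagonal dominance (diagonal =
   row sum of absolute off-diagonals + 0.1) followed by re-standardisation
   — simple and always successful, the standard device in GGM simulation.

Data are sampled by drawing latent Gaussians with the model-implied
correlation matrix and cutting them at per-item thresholds (default
symmetric: −1.5, −0.5, 0.5, 1.5 for five categories), which is exactly the
generative model the polychoric estimator assumes.  Missingness is MCAR
only, consistent with the pairwise-deletion analysis; non-MCAR mechanisms
are out of scope.

Two edge-allocation schemes are provided because they answer different
questions.  `"proportional"` (the default) gives every block pair edges in
proportion to its number of node pairs: within- and between-block
*densities* are equal, and any community signal lives in the weights alone.
This is the neutral choice for recovery benchmarks such as the sample-size
simulation.  `"within_first"` saturates within-block pairs before spending
the remainder between blocks, producing the topologically dense subscales
seen in real instruments — a validated questionnaire's subscale items are
densely interconnected, which is precisely why walktrap recovers subscales
as communities in real data.  `synthetic_study_data()` bundles the
study-emulating configuration: 17 items in blocks of 7/6/4, density 0.5,
`within_first` allocation, within-block magnitudes 0.2–0.4 versus
between-block 0.05–0.15 (realised partials about 0.19 within and 0.06
between, reproducing the within/between connectivity contrast reported for
such instruments), n = 367, and 1.1% MCAR missingness.  What passing tests
on these data do *not* show: robustness to non-normal latent variables,
informative missingness, or items violating the ordinal-thresholds model —
real data can deviate in all three ways.

## Sample-size estimation

`estimate_sample_size()` answers "how many respondents are needed before
the estimated network recovers the truth?" by Monte Carlo: for each
candidate $n$, generate a fresh true network (17 nodes, density 0.4 by
default), simulate data, re-estimate, and score edge-recovery sensitivity
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$ — the fraction of true edges
recovered; false positives are deliberately not part of this criterion.
The selected size is the smallest candidate whose fraction of replications
reaching the sensitivity target (default 0.6) is at least the power target
(default 0.8), after isotonic smoothing across the grid (monotone by
construction, deterministic, no spline machinery).  The default fast mode
simulates continuous latent Gaussian data and estimates from Pearson
correlations; an `"ordinal"` mode runs the full polychoric pipeline at
higher cost.  A criterion unattained on the grid is flagged rather than
extrapolated.

It deserves emphasis that the answer depends strongly on the true-weight
distribution: with this generator's defaults the sensitivity criterion is
already met at a few hundred respondents, because uniform 0.1–0.4
magnitudes leave few edges near the detection floor.  Published
requirements in the thousands correspond to generators that place
substantial mass on very weak edges.  The generator's defaults are part of
the package's stated study conditions and are not adjusted per analysis;
anyone matching a specific published figure must match that figure's
generator.

## Numerical choices

* Glasso convergence: outer tolerance $10^{-4}$ relative to the mean
  absolute off-diagonal of $R$ (tightenable per call), inner lasso sweeps
  to $10^{-7}$; warm starts along the 100-point log-spaced path from
  $\lambda_{\max} = \max_{i<j} |R_{ij}|$ down to $0.01\,\lambda_{\max}$.
  Exact zeros are preserved from the lasso soft-thresholding, and entries
  below $10^{-8}$ are treated as zero — a numeric noise floor, not a
  substantive threshold.
* EBIC $\gamma = 0.5$, the standard default where the hyperparameter is
  not reported.
* Eigencentrality of a disconnected network is the Perron vector of the
  largest component with zeros elsewhere; the empty network has no
  defined eigencentrality and errors.
* Walktrap on an empty network returns $p$ singletons with modularity 0.
* All bootstrap stages derive per-replicate seeds from one master seed
  with a counter scheme, so every report is exactly reproducible; failed
  replicates are skipped and more than 5% failures abort with an error.

## Problem sizes in the shipped tests

The test-suite simulations are sized for a desktop run: community
bootstraps use 50–200 replicates (the methodology's 2500 remains the
pipeline default), case-dropping uses 40–60 subsamples per level on 8-item
fixtures, and the sample-size curve uses 100 replications per grid point
in the fast Gaussian mode.  The statistical claims these runs check are
scale-free; the defaults in `pipeline_config()` keep the full published
budgets.

## Known limitations

* Gaussian copula only: no item-response-theory generation, no
  nonparanormal transform, no mixed variable types.
* Cross-sectional conditional associations: nothing here supports causal
  interpretation, and betweenness/closeness are excluded by design.
* The CS coefficient's correlation convention (Pearson) and the EBIC
  sample-size convention under pairwise deletion (mean pairwise n) are
  defensible defaults for under-documented corners of the methodology;
  both are configurable.
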