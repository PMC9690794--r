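# ordnet

Regularised partial-correlation networks for ordinal questionnaire data.

Surveys in psychology and epidemiology score behaviours, cognitions and
emotions on Likert-type items (e.g. perceived stress, coping and social
support on 5-point scales).  Network psychometrics treats the items as
nodes of a **Gaussian Graphical Model (GGM)**: edges are partial
correlations

&nbsp;&nbsp;&nbsp;&nbsp;*w<sub>ij</sub> = −K<sub>ij</sub> / √(K<sub>ii</sub> K<sub>jj</sub>)*,&nbsp;&nbsp;&nbsp;&nbsp;*K = Σ<sup>−1</sup>*,

so an edge means two items remain associated after conditioning on every
other item.  `ordnet` implements the full analysis such studies report,
for researchers who need it reproducible and testable:

* **polychoric correlations** (two-step ML, pairwise deletion,
  positive-definiteness repair) for ordinal items;
* **EBIC-glasso estimation**: graphical lasso over a 100-point penalty
  path with Extended-BIC selection (γ = 0.5 default), authored in
  C++/RcppArmadillo;
* **communities**: walktrap detection, parametric-bootstrap CI for the
  number of communities, within/between-community RMSEW connectivity;
* **centrality**: strength, eigencentrality, bridge strength (raw and
  z-standardised), weighted global clustering (Zhang–Horvath);
* **backbone**: minimum spanning tree of the Gower distance
  √(2(1 − w)) via Kruskal's algorithm;
* **stability**: nonparametric edge bootstrap and case-dropping
  correlation-stability (CS) coefficients;
* **sample-size planning**: Monte-Carlo estimation of the smallest n at
  which the network is recovered at a target edge sensitivity;
* **synthetic data**: ground-truth sparse GGMs with planted communities
  and Likert-type samples from them, so everything above is testable
  without access to confidential survey data.

## Worked example

Simulate a study-like dataset (17 items in three planted communities —
7 stress, 6 coping, 4 support — n = 367, 1.1% missingness), estimate the
network and inspect it:

```r
library(ordnet)

sim <- synthetic_study_data(seed = 1)
sim$data
#> Ordinal dataset: 367 respondents x 17 items, 5 categories; 69 missing cells

R <- polychoric_matrix(sim$data)
net <- select_network(R)
net
#> GGM network: 17 nodes, 81 edges (density 0.596 ); lambda = 0.04806 (EBIC gamma = 0.5)

comm <- walktrap_communities(net)
comm
#> Community assignment: 3 communities; modularity 0.4588

head(centrality_table(net, comm), 3)
#>   variable  strength eigencentrality bridge_strength strength_z eigencentrality_z bridge_strength_z
#> 1  stress1 0.9976866       0.9321675      0.20722223  0.8001086         1.1672672         0.3596897
#> 2  stress2 0.8566920       0.8369486      0.12297544 -0.6438509         0.4253272        -0.4602716
#> 3  stress3 1.0619702       0.9984917      0.08808809  1.4584519         1.6840613        -0.7998249
```

The three detected communities coincide with the planted stress / coping /
support blocks, mirroring how walktrap recovers questionnaire subscales in
real data.  An estimated density of 0.60 (81 of 136 possible edges at
n = 367) with modularity 0.46 says the network is connected but clearly
modular.  The full pipeline —
including the community-count bootstrap, the MST backbone and the
stability bootstraps — runs with one call and writes every table plus a
JSON report:

```r
report <- run_pipeline(sim$data, pipeline_config(), outdir = "out/", seed = 1)
```

`estimate_sample_size()` answers the planning question "how many
respondents before a 17-node, density-0.4 network is recovered with
sensitivity ≥ 0.6 in ≥ 80% of replications?" by simulation over a grid of
candidate sizes.

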