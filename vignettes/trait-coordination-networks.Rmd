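---
title: "Trait coordination as a correlation network: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait coordination as a correlation network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitnet)
```

## The question and the method

Plant organs do not evolve independently: leaf, stem and root traits are
correlated across species, and the pattern of those correlations — which
traits move together, which act as hubs — is itself a biological signal.
`traitnet` treats a species-mean trait table as the raw material for a
*trait correlation network*: traits are nodes, significant pairwise Pearson
correlations are edges, and network statistics (modularity, centrality)
summarise how coordinated the phenotype is and which traits organise it.
Two sites (for instance a seasonally dry and a moist tropical forest) can
then be compared trait pair by trait pair and hub by hub.

The pipeline has a fixed stage order:

1. **Trait derivation** (`derive_traits()`): per-seedling organ
   measurements become the ten standard traits (SLA, MPU, LTh, LWC, WD,
   SWC, SRL, MRD, RTh, RD), then species means.
2. **Transform** (`log_transform()`): a configured subset of traits is
   log10-transformed. The Shapiro–Wilk report is advisory only — the
   transform list is a per-site configuration choice, because which traits
   need the transform is an empirical property of each data set and is
   typically hand-picked per site.
3. **Size correction** (`size_correct()`): each trait is regressed on
   log10(total biomass); where the slope is significant (default
   `alpha = 0.05`) the column is replaced by its residuals, removing
   allometric size effects from all downstream correlation structure.
4. **Branch A — tip-level analysis**: pairwise-complete Pearson
   correlations (`pearson_pairwise()`), the `p < 0.05` network
   (`build_network()`), spin-glass modules (`spinglass_partition()`),
   centralities (`centrality_table()`) and PC1 importance
   (`importance_scores()`).
5. **Branch B — phylogenetic analysis**: independent contrasts
   (`prepare_tree()`, `pic_matrix()`) feeding the same correlation and PCA
   machinery.
6. **Two-site comparison** (`compare_sites()`): Fisher r-to-z tests per
   shared trait pair, plus the cross-site correlation of PC1 importance
   scores.

## Statistical machinery

**Pairwise-complete correlations.** Each unordered trait pair uses every
species where both traits are observed, so each pair carries its own `n`.
This matters for designs where a block of species lacks a block of traits
(root traits measured for 28 of 52 species, say): leaf–stem pairs keep the
full sample while root–root pairs drop to the measured subset. Listwise
deletion would discard most of the data. Significance uses the exact
transform `t = r sqrt(n-2)/sqrt(1-r^2)` on `n - 2` degrees of freedom,
two-sided; no multiple-testing correction is applied by default (edges are
thresholded on raw `p < 0.05`, the convention of this literature), with a
Holm option available via `pearson_pairwise(adjust = "holm")`.

**Fisher r-to-z.** Two sites' correlations for the same pair are compared
with `Z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
normal. It requires `n >= 4` per site and `|r| < 1`; it is antisymmetric
under swapping sites.

**Network statistics.** Degree is normalised by `n - 1` (the possible
direct partners); betweenness by `(n-1)(n-2)/2`; closeness is
`(n_c - 1) / sum_j d(i, j)` within each connected component of size `n_c`
(undefined for isolates). Shortest paths are *unweighted*: correlation
magnitudes are similarities, and we take no stance on converting them into
path costs. A `-log|r|` cost transform would be the natural weighted
alternative and is deliberately not the default, since published trait
networks are generally read topologically.

**Modules.** `modularity_score()` is Newman–Girvan
`Q = sum_c (e_cc - a_c^2)`, unweighted by default so that small-graph
brute-force enumeration is an exact check (a weighted variant is a flag).
`spinglass_partition()` minimises the Reichardt–Bornholdt spin-glass
Hamiltonian (configuration null model, resolution `gamma = 1`) by
simulated annealing — 25 spins, start temperature 1, stop 0.01, cooling
0.99 — run best-of-10 with seeded restarts. Selection among runs is by the
modularity of the induced labels (equivalent to energy ranking at
`gamma = 1`); the per-run modularities are kept as diagnostics since the
annealer backend does not expose its energy trajectory. Disconnected
graphs are partitioned per component with distinct label blocks and a
warning. Negative-correlation edges enter with weight `|r|` under the
standard Hamiltonian; `implementation = "neg"` switches to the signed
Hamiltonian for users who want negative edges to repel.

**Importance.** The three centralities are summarised by PC1 of their
correlation-matrix PCA (`standardize = TRUE` is the only defensible
setting for metrics on different scales). Eigenvector signs are arbitrary,
so components are oriented deterministically: the degree loading is made
positive for the importance PCA, and the alphabetically first variable
loads positively in the generic `pca()`. High PC1 = hub trait. Cross-site
comparison reports both `r` and `r^2`, because the orientation convention
can flip the sign of `r` but never `r^2`.

**Independent contrasts.** `prepare_tree()` follows the common
comparative-ecology convention for community phylogenies without reliable
divergence times: resolve polytomies at random (seeded), then set every
branch length to 1 — in that order, so the zero-length branches created by
the resolution are overwritten. Contrasts are Felsenstein's pruning
recursion (via `ape::pic`): a binary tree with S tips yields S − 1
contrasts, iid Normal(0, σ²) under Brownian motion. Contrast correlations
and PCA treat contrasts as ordinary observations by default because they
feed a standard PCA; `pic_correlations(through_origin = TRUE)` provides
the origin-constrained form (contrasts have zero expectation, so the
strict version estimates no intercept). Complete-case pruning is done per
analysis, since different trait subsets can have different missing
species.

## The synthetic-data generator

`simulate_traits()` draws species-mean traits as

x_st = beta_t * log10(B_s) + BM_t(s; sigma_BM) + lambda_t * f_m(t),s + eps_st

with log-normal biomass `B` (median 1, log10-sd `sigma_logb`), an
independent Brownian realisation per trait on the supplied phylogeny
(recursive normal increments, variance `sigma_BM^2 * b` per branch, root
state 0), shared standard-normal module factors `f`, and iid noise. Within
a module the population correlation is
`lambda^2 / (lambda^2 + sigma_eps^2)` when the Brownian and allometric
terms are off, which is the closed form the tests check by Monte Carlo.

The two presets encode the study designs the package targets:
`spec_moist_forest()` (43 species, 10 complete traits) and
`spec_dry_forest()` (52 species, root traits `SRL`, `MRD`, `RTh`, `RD`
blanked for a block of 24 species, leaving 28 root-measured). Default
parameters were fixed once, on field realism grounds: `lambda = 1.25`
(within-module r ≈ 0.6, the strength of the clearer published trait
correlations), `sigma_eps = 1`, `sigma_BM = 0.3` (moderate phylogenetic
signal), `beta = 0.3` (mild allometry on every trait so the size
correction has something to find), `sigma_logb = 0.5`. Missingness is
block-structured — a species subset times a root-trait subset — not random,
because that is the structure greenhouse/field designs actually produce,
and it is what exercises pairwise-complete machinery.

What the generator does *not* emulate: the actual trait distributions of
any real forest (units, skew, multi-modality), correlated measurement
error within organs, more than one factor per module, or non-Brownian
evolution. Passing recovery tests on synthetic data therefore shows the
machinery is correct and well-calibrated, not that any particular field
data set has two modules.

`make_planted_network()` plants a partition directly at the graph level
(within-module edge probability `p_in`, between `p_out`), which is the
cleaner benchmark for the community-detection stage in isolation; spin-glass
recovery is scored with the Adjusted Rand Index against the planted labels.

## Numerical and design choices

- **Biomass regressor**: the allometric literature regresses on log size,
  so `size_correct()` defaults to log10(biomass); `regressor = "raw"` is
  available because the convention is not universal.
- **Order of operations**: transform, then residualize. Species means are
  taken before any transform (measurements are per seedling; analysis is
  across species).
- **State flags**: every column carries `raw`/`log10`/`residual`; both
  preprocessing stages refuse to run twice on the same column rather than
  silently double-transforming.
- **Degenerate inputs**: empty networks are legal (isolated traits are
  kept as nodes); an uninformative network makes the importance stage
  return `NULL` with an "insufficient network" note instead of failing the
  run; pairs with `n < 3` or zero variance are undefined rather than
  errors.
- **Determinism**: every stochastic stage takes a seed; the pipeline
  derives per-stage seeds from one master seed via named sub-streams
  (`sub_seed()`), and a run manifest records them, so identical
  config + seed reproduces byte-identical artifacts.
- **Ties and signs**: annealer ties are broken by the seeded restarts;
  PCA signs by the loading conventions above. Nothing depends on BLAS
  sign conventions or hash ordering.

## Problem sizes used in the tests

The test suite validates against brute-force oracles at sizes where
enumeration is exact: betweenness/closeness against path enumeration on
200 random connected graphs of 4–8 nodes; spin-glass against the exhaustive
maximum-modularity partition (all set partitions, up to Bell(8) = 4140) on
20 graphs; planted-partition recovery at 3 modules × 8 nodes over 40
seeds; the Fisher z null at n = 50 with 2000 replicates; contrast
normality over 200 replicate 50-tip simulations; and full-pipeline module
recovery on the 43-species preset over 10 seeds. These sizes were chosen
as the smallest at which the statistical assertions have adequate power.

## Known limitations

- The spin-glass annealer is stochastic; best-of-10 makes small-network
  partitions reproducible in practice, but global optimality is only
  guaranteed where the exhaustive check runs (≤ 8 nodes).
- Centrality normalisations assume an undirected simple graph; multigraphs
  and directed relations are out of scope.
- No imputation and no outlier handling: missing cells propagate by
  pairwise/complete-case rules, which is a policy, not a reconstruction.
- The Fisher z comparison assumes independent samples at the two sites;
  shared species between sites would violate it.
- Unit branch lengths and random polytomy resolution are conventions, not
  inferences; contrasts computed on such trees remove shared-ancestry
  covariance only to the extent the topology is right.
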