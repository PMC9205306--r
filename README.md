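# traitnet

Correlation-network analysis of plant functional trait coordination.

## The problem

Across species, plant traits do not vary independently: leaf, stem and
root properties are correlated through shared construction costs,
allometry and selection, and the *pattern* of those correlations tells you
whether a flora behaves as a coordinated whole-plant strategy or as
loosely coupled organ-level strategies. `traitnet` implements the standard
network formulation of that question for species-mean trait tables, and a
two-site comparison designed for contrasts such as a seasonally dry versus
a moist tropical forest:

- **traits → network**: pairwise-complete Pearson correlations (each
  unordered trait pair keeps its own sample size *n*; p from
  *t* = *r*·√(*n*−2)/√(1−*r*²)); traits are nodes, correlations with
  *p* < 0.05 are edges weighted |*r*| with sign.
- **modules**: Newman–Girvan modularity *Q* = Σ(*e*ᵢᵢ − *a*ᵢ²) optimised
  by Reichardt–Bornholdt spin-glass simulated annealing (25 spins, γ = 1,
  best-of-10 seeded runs).
- **hub traits**: degree *k*/(*n*−1), betweenness (normalised by
  (*n*−1)(*n*−2)/2) and within-component closeness, summarised per trait
  by PC1 of their correlation-matrix PCA ("trait importance").
- **site comparison**: Fisher r-to-z tests
  *Z* = (atanh *r*₁ − atanh *r*₂)/√(1/(*n*₁−3) + 1/(*n*₂−3)) per shared
  trait pair, and the cross-site correlation of PC1 importance scores.
- **phylogenetic control**: Felsenstein's independent contrasts on a
  community phylogeny prepared by seeded random polytomy resolution
  followed by unit branch lengths.
- **preprocessing**: trait derivation from organ measurements (SLA, MPU,
  LTh, LWC, WD, SWC, SRL, MRD, RTh, RD), configured log10 transforms, and
  size correction by residualising traits on log10(total biomass) where
  the slope is significant.

A synthetic-data generator (`simulate_tree()`, `simulate_traits()`,
`make_planted_network()`) plants known module structure, Brownian
phylogenetic signal, allometry and block-structured missingness (e.g. root
traits for only 28 of 52 species) so every stage is benchmarked against
ground truth without any external data.

## Worked example

The desk-scale re-analysis of the published two-forest centrality table
(shipped in `inst/extdata/published_centralities.csv`):

```r
library(traitnet)
pub <- published_centralities()
imps <- lapply(split(pub, pub$forest), importance_scores)
```

Running `Rscript analysis/06_published_reanalysis.R` prints:

```
dry forest: PC1 = 85.9% of variance; ranking: LWC > SWC > RTh > LTh > MPU > WD > MRD > RD > SLA > SRL
moist forest: PC1 = 93.4% of variance; ranking: LWC > SRL > WD > SWC > RD > SLA > LTh > MPU > RTh > MRD
cross-forest importance: r = 0.55, r2 = 0.31, p = 0.097
```

Read: in both forests one principal axis captures nearly all centrality
variation, so "importance" is a meaningful single score per trait. Leaf
water content (LWC) is the top hub in both forests; the rest of the
ranking reorders — root thickness rises in the dry forest while specific
root length and wood density matter in the moist one — and the cross-forest
importance correlation (r = 0.55, p ≈ 0.1 over the 10 shared traits) is
too weak to call the two rankings the same.

The synthetic two-site pipeline is `analysis/01_simulate.R` through
`analysis/05_importance.R`: simulate both communities, preprocess,
correlate, build networks and score the recovered modules against the
planted truth (Adjusted Rand Index), then compare importance across sites.
Each script prints a one-line summary and writes its tables under
`results/synthetic/`.

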