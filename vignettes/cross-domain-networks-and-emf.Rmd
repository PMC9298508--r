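---
title: "Cross-domain co-occurrence networks and ecosystem multifunctionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-domain co-occurrence networks and ecosystem multifunctionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emfnet)
```

## The analysis problem

Herbivore disturbance — burrowing pikas, grazing livestock, or both —
reshapes alpine meadow soil along a surface-type succession: grassland
(G), new mound (N), old mound (O) and eventually bare land (B), with
inside-mound (I) soil as a fifth habitat. Amplicon surveys of such systems
yield three OTU count tables (bacteria, fungi, archaea), sample metadata
(disturbance C/P/PL, surface, block, site), and a table of soil and
vegetation measurements. `emfnet` covers the downstream analysis: how
diverse each domain is, how taxa co-occur within and across domains, how
much ecosystem function each sample supports, and which factors drive the
community structure.

## Rarefaction, diversity, similarity

All diversity and network computation starts from tables rarefied to even
depth, because library size differences otherwise masquerade as biology.
`rarefy()` draws without replacement (multivariate hypergeometric), so a
retained sample's row sum equals the target depth *exactly*; samples below
the depth are dropped with a warning naming them. Repeating a rarefaction
with the same seed is bit-identical.

Alpha diversity uses the classic estimators. Chao1 is
`S_obs + F1^2 / (2 F2)` with singletons `F1` and doubletons `F2`,
switching to the bias-corrected `S_obs + F1(F1 - 1) / (2(F2 + 1))` when
`F2 = 0` — the convention of the QIIME-era tooling this pipeline mirrors;
variants disagree at that boundary, which is why the branch rule is
documented and tested. Shannon entropy uses the natural logarithm by
default (a `base` flag exists; only relative comparisons matter
downstream), and Simpson is reported as Gini-Simpson `1 - D` with a flag
for raw `D`. Bray-Curtis dissimilarity comes from `vegan::vegdist()`, and
community similarity is its complement `1 - d`. Because a per-group
similarity summary can be formed in more than one way, `group_similarity()`
reports the within-group pairwise mean and SD explicitly.

## Co-occurrence networks

Networks are built per sample group from *dominant* OTUs, those with mean
relative abundance strictly above 0.01% across the samples being
networked. The filter is applied per group (networks are per-group
objects); a global-filter alternative simply means calling
`filter_dominant()` before subsetting, and both orders are supported
because the source convention is ambiguous.

`spearman_all_pairs()` computes Spearman's rho as Pearson correlation of
average-ranked data — the tie-handling used throughout the field — with
two-sided p-values from the t approximation. Rank correlations are
invariant to the per-sample total, so feeding counts or relative
abundances is equivalent after rarefaction. Edges require `|rho| > 0.7`
and `p < 0.05`, both strict inequalities; raw p-values are the default to
match common practice in this literature, with Benjamini-Hochberg
available by flag. Nodes left without edges are dropped by default
(matching Gephi-style node counts, where reported nodes are connected
OTUs); `keep_isolated = TRUE` retains all dominant OTUs, since published
node counts may follow either convention.

Cross-domain networks are formed by deleting every intra-domain edge from
the merged-table network. Domain membership travels in the OTU id itself
(`bac|`, `fun|`, `arc|` prefixes), so exported edge lists are
self-describing. `domain_pair_summary()` then accounts edges and sign
proportions per domain pair; counts always partition the cross-domain
edge total.

Topology summaries follow Gephi's definitions: density `2E/(N(N-1))`,
average degree `2E/N`, mean local clustering with degree-<2 nodes
contributing 0, path length and diameter over connected pairs only, and
Newman modularity of a Louvain partition (Gephi's algorithm) on the
unweighted simple graph at resolution 1 with a fixed seed — community
detection is stochastic, so the seed is part of the result's provenance.

## Ecosystem multifunctionality

The EMF index is the per-sample mean of Z-scores of seven
support/regulation variables: total vegetation coverage, dry weight, wet
weight, NH~4~-N, NO~3~-N, SOC and TN. Standardization is computed jointly
over **all** samples (not per group): group EMF means are only comparable
on a common scale, and joint standardization is what makes the
sample-size-weighted group means sum to zero. The SD uses the `n - 1`
denominator; both conventions appear in the multifunctionality literature,
so the choice is stated and tested. Missing function values are refused
rather than silently imputed. The index is invariant to affine rescaling
of any input variable — it is unit-free by construction — and symmetric in
the seven functions.

## Permutation inference

All permutation tests use the add-one convention
`p = (1 + #{T* >= T}) / (1 + n_perm)`, so p-values never fall below
`1/(n_perm + 1)`. For small designs (`n <= 8`) PERMANOVA and the Mantel
test can enumerate every ordering exhaustively, in which case the p-value
is the exact proportion `#{T* >= T}/n!` with the identity included.

* **PERMANOVA** partitions `SS_total = sum(d^2)/n` over all pairs into
  within- and between-group parts and permutes raw labels. Unrestricted
  permutation is the default; the block structure of a split-plot design
  can be honored by subsetting, and the observed pseudo-F and R² agree
  with `vegan::adonis2` to numerical precision (a cross-check in the test
  suite).
* **Mantel** correlates upper triangles (Pearson by default — the classic
  test — with a Spearman flag) and permutes one matrix's rows/columns
  jointly, one-sided.
* **MRM** regresses the response matrix's upper triangle on the
  predictors' (intercept always included, no weighting) and permutes the
  response for per-coefficient p-values; collinear predictors are flagged
  and rank-deficient coefficients returned as `NA`.

Enrichment ratios compare each OTU's relative abundance between a focal
group and the control by one-way ANOVA; an OTU counts as *enriched* only
when significant **and** higher in the focal group — enrichment is a
directional claim, and plain ANOVA is direction-blind. No multiplicity
correction is applied by default (matching the "all P < 0.05" convention
these ratios come from); a BH flag exists. OTUs absent from both groups
leave the denominator.

## The synthetic community model

`generate_counts()` draws per-sample log abundances from a Gaussian copula:
fixed per-OTU base abundances (log-normal spread `base_abundance_shape`),
plus multivariate-normal sample deviations with sd `noise_sd` and an
equicorrelation block for each planted OTU set (feasibility requires
`rho > -1/(k-1)` for a block of k OTUs, which the constructor enforces).
Enrichment adds `log2fc * log(2)` to target OTUs in the target group
before the softmax to composition; counts are multinomial at
negative-binomial library sizes. This gives independent control of
correlation, enrichment and depth. Defaults — `noise_sd = 0.6`,
`base_abundance_shape = 1`, depth mean 10,000 (dispersion 20), per-domain
richness 500/150/60 mirroring the bacteria ≫ fungi ≈ archaea richness
ordering of soil surveys — describe a moderately variable soil community
in which a planted latent correlation of 0.9 remains detectable above the
0.7 Spearman threshold at 50 samples, and a +2 log2 fold-change is
detectable at 20 samples per group.

The default design reproduces the field layout: 2 control blocks × 5
sites sampling only natural meadow (surface recorded as G so that
surface-level contrasts can include them), plus 2 blocks × 5 sites × 5
surfaces for each of P and PL — 110 samples. Group sizes entering each
network are free parameters of the design configuration, since pooling
conventions vary between studies.

One property of the model deserves emphasis: **compositional closure
induces weak dependence among "null" OTU pairs.** Because relative
abundances share a denominator, pairs with zero latent correlation still
show empirical |rho| around 0.1, and at n = 100 samples roughly 18% of
null pairs reach p < 0.05 — far above the nominal 5% that truly
independent vectors give (and which the Spearman p-value attains in the
test suite's calibration check). This is a property of compositional data,
not an artifact of the generator, and it is precisely why the network
construction leans on the |r| > 0.7 magnitude threshold: across the test
suite's null simulations the false-positive *edge* rate stays at zero,
well under 1%. Conclusions drawn from p-values alone on compositional
tables would need SparCC-style corrections, which are intentionally out of
scope here because the analysis this package mirrors used plain Spearman.

The gradient generator plants monotone surface effects (nutrients and
vegetation declining G → N → O → B, with inside-mound intermediate and pH
drifting slightly upward) with Gaussian residuals; magnitudes are free
parameters with defaults in realistic field ranges. It emulates mean
structure only — no spatial autocorrelation within blocks, no
heteroscedasticity, no measurement censoring — so passing recovery tests
demonstrates that the *estimators* work, not that real soils are this
well behaved.

## Numerical choices and scaling

Problem sizes in the tests and the acceptance script are chosen for quick,
reproducible runs on a single CPU: calibration uses 500 null simulations at
999 permutations (binomial ±2 SE on a 5% rate is about ±2 percentage
points, matching the [0.03, 0.07] acceptance band), edge recovery uses 20
seeds of 80-OTU/50-sample communities, and the default pipeline
configuration uses 120/80/50 OTUs per domain at rarefaction depth 2,000.
Zero-variance OTUs are excluded from correlation (their ranks are
undefined) with a logged report; degenerate networks (fewer than 2 nodes)
report density as missing with a warning rather than erroring, so pipeline
runs survive sparse groups. Per-stage RNG streams are derived from the
master seed by a stable integer map, so adding a stage never perturbs
earlier stages' draws, and every writer/reader pair round-trips
bit-identically.

## Known limitations

- Spearman on compositional tables (see above) — magnitude thresholds
  mitigate, not remove, closure effects.
- UniFrac, ordination and LEfSe are out of scope (tree-dependent or
  off-the-shelf elsewhere).
- PERMANOVA R² values from field studies depend on pooling and strata
  conventions that are rarely stated; the implementation makes its own
  conventions explicit instead of chasing any particular published value.
- The exact-enumeration paths are limited to 8 samples (40,320 orderings);
  beyond that, sampled permutations with the add-one convention apply.
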