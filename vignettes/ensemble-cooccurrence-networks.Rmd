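---
title: "Ensemble co-occurrence networks for soil microbiota: models, calibration and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble co-occurrence networks for soil microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

rhizonet implements the statistical core of a soil-microbiota survey of a
factorial nitrogen-fertilization experiment: OTU-table preprocessing,
diversity and differential-abundance testing, ensemble co-occurrence network
inference with a compositional permutation null, and screening of OTU
abundances against qPCR-derived nitrogen-cycle marker genes. This vignette
explains the statistical models behind each stage, the tunable parameters
and their defaults, the synthetic-data generator used to validate the
pipeline, and the numerical choices and limitations a user should know
about.

## The data model

The central object is a non-negative integer count matrix, OTUs by samples,
with a SILVA-style taxonomy string per OTU and per-sample metadata (habitat:
rhizosphere vs bulk soil; nitrogen treatment: none `0`, mineral `N`, manure
`M`, both `NM`; replicate block). Counts are compositional: each sample's
library size is an artifact of sequencing, so inference operates either on
relative abundances (correlations, diversity) or on rarefied counts
(count-based tests).

Preprocessing follows the conventions of amplicon surveys:

* `remove_contaminants_and_singletons()` drops plastidic, mitochondrial and
  unidentified OTUs (case-insensitive keyword match on the taxonomy string)
  and OTUs with at most one read.
* `filter_min_total()` has two named presets: `"more_than_10"` keeps OTUs
  with more than 10 reads (totals >= 11), the rule used for diversity
  analyses; `"network"` keeps totals >= 1000, the stricter rule for network
  inference. The two published phrasings of the network rule disagree at
  exactly 1000 reads; the preset keeps a total of exactly 1000, following
  the explicit deletion rule ("fewer than 1000 are deleted").
* `filter_min_relative()` keeps OTUs strictly above a share of total reads
  (e.g. 0.075%). The share is evaluated on the grand total of the table as
  passed in, i.e. before removal, so the filter is order-invariant and
  idempotent.
* `rarefy_table()` subsamples each sample without replacement to a fixed
  depth (classically 4310 reads in this design); shallower samples are
  dropped and reported. Subsampling without replacement matches the QIIME
  behaviour and makes every column sum exactly equal to the depth.

## Diversity and differential abundance

Alpha diversity uses the Shannon index in bits (`-sum(p log2 p)`), observed
richness, and the Chao1 estimator `S + F1^2/(2 F2)` with the bias-corrected
form `S + F1(F1-1)/2` when no doubletons exist. Beta diversity is
Bray-Curtis on relative abundances, with PERMANOVA (pseudo-F) and ANOSIM
(rank R) permutation tests delegated to vegan; p-values use the add-one
convention `p = (1 + #{perm >= obs})/(1 + n_perm)` and never return zero.
Phylogeny-dependent metrics (UniFrac, phylogenetic diversity, PCoA) are out
of scope, as no tree is consumed.

Differential abundance across treatments uses the G-test of independence:
replicate samples are pooled per treatment and each OTU is tested on the
2 x k table of (OTU reads, all other reads) per treatment, with
`G = 2 sum O ln(O/E)`, k - 1 degrees of freedom and Benjamini-Hochberg
correction across OTUs. The Williams small-sample correction is available
as a flag but off by default. Pooling means the test assumes multinomial
sampling within treatment; on overdispersed data (sample-to-sample
composition noise beyond counting noise) the G-test is anticonservative,
which is why the generator's null for count-test calibration is
multinomial-only (below). The summary (`glance()`) reports the number of
affected OTUs and their percent of total reads, mirroring how such results
are tabulated.

## The ensemble network

`build_ensemble_network()` implements a CoNet-style ensemble over four
pairwise association measures between OTU abundance profiles: Pearson and
Spearman correlations (similarity orientation, computed on relative
abundances) and Bray-Curtis and symmetrised Kullback-Leibler divergence
(dissimilarity orientation; KL normalises each profile to a probability
vector after adding a pseudocount, default 1e-6). The pipeline is:

1. **Screening.** Per measure, the `edges_top` most copresence-like and
   `edges_bottom` most exclusion-like pairs are admitted (defaults 1000
   each; boundary ties included). The union over measures is the candidate
   set; the direction of each (pair, measure) is fixed by the list that
   admitted it.
2. **ReBoot permutation null.** Per edge and measure, the two profiles are
   independently permuted across samples. For correlation measures the
   sample is re-closed around the permuted pair (the rest of the
   composition held fixed), so the null retains the pair's closure
   coupling; this renormalisation is done on the proportion scale, because
   the observed statistic is computed on closed columns and a count-scale
   renormalisation would leak library-size variation into the null.
   Dissimilarities are scored on the permuted profiles directly. All four
   measures share the same permutations of each edge, which is what makes
   the dependence between their p-values estimable.
3. **Null calibration.** The pair-conditional permutation null cannot see
   two table-wide features: the common mode of closed compositions (many
   small OTUs jointly anti-correlate with the large ones, shifting
   random-pair correlations slightly positive) and depth-heterogeneous
   counting noise (which shifts the dissimilarity scores against their
   pairing null). Following the empirical-null idea of large-scale
   inference, `measure_null_calibration()` scores a few hundred random
   pairs against their own nulls; the median standardised offset recentres
   parametric z-values, and the ensemble of add-one empirical p-values is
   the reference distribution for the dissimilarity measures. The scale is
   deliberately left at 1: the z-values are already t-standardised per
   pair, and an estimated scale would multiply extreme-tail p-values by
   its own sampling noise.
4. **Per-measure p-values.** Correlations use a parametric tail: the
   recentred standardised score referred to a t distribution with
   `n_permutations - 1` degrees of freedom (the t correction keeps the
   extrapolated tail honest at modest permutation counts). Dissimilarities
   use the add-one empirical p ranked against the calibration ensemble —
   their permutation nulls are collision-driven mixtures on spiky
   profiles, for which a normal approximation badly misstates the tail; a
   `gaussian_dissimilarity` flag restores the parametric tail if wanted.
5. **Bootstrap stability.** Samples are resampled with replacement
   (default 100 times); an edge is stable for a measure iff its observed
   score lies inside the closed 2.5–97.5 empirical percentile interval of
   its bootstrap distribution. Unstable (and unselected) measures drop out
   of the edge.
6. **Brown's merge.** The surviving measures' one-tailed p-values are
   combined with Brown's method, the dependent-test extension of Fisher's:
   `X = -2 sum log p` is referred to a scaled chi-square whose variance
   uses the Kost-McDermott covariance polynomial
   `3.263 r + 0.710 r^2 + 0.027 r^3`. The correlation `r` between two
   measures is estimated from their null scores across the shared
   permutations, oriented towards each measure's rejection tail (so that,
   e.g., high Pearson and low KL count as the same evidence) and clamped
   to ±0.99. At independence the merge is exactly Fisher's method; at
   perfect correlation with equal p-values it returns that p-value.
7. **FDR and support.** Merged p-values receive Benjamini-Hochberg
   correction over the *full family of scorable OTU pairs*, not just the
   screened candidates. The screen examines every pair, so correcting only
   over the survivors would re-discover the screen's own order statistics:
   on null communities the top candidates are always "significant" against
   their per-pair nulls, and a candidate-family BH retains several false
   edges per run. With the full family the null network is empty, at the
   cost of thinner margins for true edges. Edges are retained when
   `q < alpha` (default 0.05) and at least `min_support` (default 3 of 4)
   merging measures agree on the consensus direction; conflicted minority
   measures do not count towards support. The order of the FDR and support
   filters is switchable (`fdr_order`); the default corrects first. A
   `positive_only` flag restricts the final graph to copresence edges, the
   convention for published co-occurrence figures.

Determinism: one integer seed drives the calibration, permutations and
bootstraps, and a fixed-seed run is reproducible edge-for-edge.
`refilter_network()` re-applies the retention filters (tighter alpha,
higher support, positive only) without redoing any permutation work, and
is guaranteed monotone.

## Network description

Clusters are the connected components of the positive-edge subgraph
(`find_clusters()`); nodes with no positive edge are labelled
"uncorrelated". Node centralities (degree; betweenness normalised by
`(n-1)(n-2)/2`; closeness as inverse mean geodesic; local clustering) are
computed within components via igraph. Per-cluster statistics mirror the
usual network-parameter tables: density `2E/(n(n-1))`, average neighbours
`2E/n`, mean local clustering (isolated/degree-1 nodes counted as zero, the
Cytoscape convention), and degree centralization in the Cytoscape form
`(n/(n-2)) (max_deg/(n-1) - density)` — 1 for a star, 0 for any regular
graph, undefined below three nodes. Density and mean degree are linked by
`density = mean_degree/(n-1)` exactly, which is also how published
per-cluster tables can be checked for internal consistency
(`density_from_mean_degree()`).

Hubs are, per cluster, the nodes in the top `top_fraction` (default 10%) by
*all three* of degree, betweenness and closeness, with ties at the cutoff
included — so a fully regular cluster returns all of its nodes or none.
Habitat preference tags each OTU with the habitat of greater mean relative
abundance (ties give "none"), recording the margin and a Mann-Whitney
p-value; the mean-abundance rule is a stated assumption, as published
figures do not define "enriched" formally.

## Gene-abundance screening

`correlate_genes()` computes Spearman correlations between each OTU's
relative abundance and each nitrogen-cycle marker gene's qPCR abundance
(amoA bacterial/archaeal, nirK, nirS, nosZ-I, nosZ-II), by default on bulk
soil samples only, where functional-gene quantification is typically
performed. Being rank-based, the screen is invariant to monotone transforms
of the gene values, so absolute copy numbers per gram and percent-of-16S
values give identical results. BH correction is applied over all gene x OTU
pairs jointly (a per-gene family is available as a flag), and the per-gene
summary counts positively and negatively correlated OTUs among the
significant set — these counts partition the significant set exactly.

## The synthetic-data generator

`generate_otu_table()` emulates the survey design: 4 treatments x 2
habitats x 4 replicate blocks = 32 samples, ~300 OTUs at desk scale,
library sizes uniform on 5,000–20,000 (so rarefaction to 4310 is always
feasible), baseline log-abundances N(0, 1.5) per OTU, multinomial closure
per sample. Three kinds of structure can be planted, and every planting is
recorded in a machine-readable ground-truth object:

* **Correlated blocks.** Within the tagged habitat's samples, each member's
  per-sample log-noise is `member_sd (sqrt(rho) f + sqrt(1-rho) eps)` with
  `f` shared — latent pairwise correlation `rho` at unchanged marginal
  variance. Members are `habitat_fold` (default 4) times more abundant in
  the tagged habitat, planting their habitat preference, and their baseline
  is pinned at the median of the baseline distribution so that recovery
  tests the method rather than the abundance lottery — and so that a block
  stays a modest share of the community (a dominant block would correlate
  all bystanders through closure). An optional hub member gets a boosted
  factor loading and a higher baseline: hub taxa are abundant, and the
  deeper coverage reduces sampling attenuation, making the hub's edges the
  strongest in the block.
* **Treatment effects.** Multiplicative fold-changes on chosen OTUs in one
  treatment's samples.
* **Gene links.** Signed latent correlations between a gene and an OTU's
  log relative abundance, with log-normal noise sized so the latent
  correlation matches the planted target (the observed Spearman is
  attenuated a few percent by the rank transform and counting noise).

Overdispersion (per-sample log-normal noise on all OTUs, `noise_sd`) is
**off by default**: under the default the only sample-to-sample variation
outside planted structure is the multinomial closure itself, so the pooled
G-test and the Spearman screen are exactly calibrated on null data. Network
studies use `noise_sd = 0.7`: a noise-free community is degenerate for
association analysis, because closure common-mode would then be the only
source of bystander variation and all bystanders would correlate near one.

What the generator does **not** emulate: amplicon error and chimeras,
taxonomy assignment noise, Dirichlet-multinomial overdispersion of the
counting stage, genuinely sparse zero-inflated taxa, and ecological
interaction structure beyond pairwise latent correlation. Passing tests
therefore show that the pipeline recovers the statistical structure it
models, not that it is robust to every artefact of real amplicon data.

## Study scales and reference results

The packaged validation studies (the test suite and
`scripts/acceptance.R`) use these scales, chosen to exercise the full
pipeline in minutes on one CPU:

* Null calibration: 20 independent null communities, 100 OTUs x 32
  samples, screening 50 edges per list, 50 permutations/bootstraps. The
  ensemble retains zero edges in all runs, and per-measure p-values on
  random pairs are uniform (dissimilarity measures assessed through the
  randomized permutation p, the exactly-uniform equivalent of their
  discrete add-one p).
* Planted recovery: two habitat-tagged blocks (rho 0.85, 10 OTUs each, a
  hub in the rhizosphere block) in a 100-OTU community with
  `noise_sd = 0.7`, generator seed 7; inference with 100/100 screening,
  200 permutations, 100 bootstraps, 400 calibration pairs, positive edges
  only. Components match blocks (ARI 1 at the study seed), the hub is
  detected, habitat preference is 20/20, and edge recall/precision are
  both near 1. At these sample sizes the planted signal sits close to the
  family-wide FDR boundary: across generator seeds roughly one realization
  in four fails to clear it — a power limitation of 32-sample designs, not
  a tuning target.
* G-test calibration and power: 500-OTU bulk-soil null (type-I error
  0.050 at p < 0.05) and 4-fold changes on 20 abundant OTUs (recall 1.0;
  note that large planted changes also shift every other OTU's relative
  abundance through closure, so the significant set legitimately exceeds
  the planted set).
* Gene screening: four planted negative links at latent rho 0.95 on 16
  bulk samples, all recovered with the correct sign at q < 0.05.

## Numerical choices and limitations

* Shannon entropy is reported in bits; the base affects no comparison.
* Spearman uses average ranks for ties; constant profiles have undefined
  correlation and are excluded from candidacy.
* Empirical percentiles use linear interpolation (R's default type 7);
  the stability interval is closed at both ends.
* Permutation p-values never return zero (add-one convention); merged
  p-values of exactly zero are clamped to the machine floor and reported.
* A KL score at exactly the null center is classed as exclusion (logged
  tie rule); a correlation of exactly zero likewise.
* The Kost-McDermott polynomial is an approximation for the covariance of
  dependent `-2 log p` terms; with estimated correlations clamped to
  ±0.99 the merged p-value is accurate to a few percent, which is far
  below the decision noise of the permutation stage.
* The inference run on the unfiltered table is supported but not
  recommended: the 1000-read preset exists because rare OTUs' correlation
  estimates at 32 samples are dominated by counting noise.
* Whether the G-test should run on the rarefied or the raw table is not
  settled; the package default follows the rarefied (normalised) branch,
  with the raw table available by simply passing it.
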