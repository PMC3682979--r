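---
title: "Methods: cross-species TF expression comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species TF expression comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devotf)
```

`devotf` compares transcription-factor (TF) expression between two
species' developmental time courses. This vignette documents the model
behind each stage, the parameters that matter, the numerical decisions,
and what the bundled simulation does and does not establish about real
data.

## Data model and preprocessing

Expression enters as a genes-by-time-points matrix of log2 values
(`expr_timecourse`), one per species, with a companion boolean
presence/absence table. Two presence-calling rules are supported:

* **Detection flags** (microarray): a gene is present at a condition only
  if *every* probe mapped to it, in *every* replicate of the condition,
  carries a positive detection flag. This conservative conjunction means
  one doubtful probe silences the gene at that time point.
* **FPKM threshold** (RNA-seq): present iff FPKM is *strictly* greater
  than 1. A value of exactly 1 is absent.

Probe intensities are quantile-normalized between arrays (via limma; ties
receive the mean of the reference distribution over their rank span) and
averaged — over probes of a gene and replicates of a time point, plain
arithmetic means, whose order does not matter. RNA-seq FPKM is
transformed as `log2(FPKM + pseudocount)` with a default pseudocount of
0.01. The pseudocount is a deliberate policy choice: `log2(0)` is
undefined, and 0.01 keeps never-expressed genes around −6.6, far below
any plausible expression floor, while shifting a gene at FPKM 1 by only
0.014. It is recorded on the returned object so downstream analyses can
report it.

Before clustering, two filters run in a fixed order: (1) genes never
called present at any time point are removed; (2) among the remainder,
genes whose log2 range (max − min) is *strictly below* 1 — less than a
two-fold change — are removed as near-constant. A range of exactly 1 is
retained. Surviving profiles are Z-normalized per gene (mean 0, sd 1
across time points) so clustering responds to the *shape* of the
temporal profile, not its level or amplitude. We use the population
standard deviation (denominator T). The choice is immaterial for
c-means geometry, which is scale-invariant under a common rescaling, but
we pin it for bit-reproducibility.

## Soft clustering

Profiles are clustered by fuzzy c-means: minimize
$J = \sum_{i}\sum_{k} u_{ik}^m\, \lVert x_k - v_i\rVert^2$ by alternating
the membership update
$u_{ik} = 1 / \sum_j (d_{ik}/d_{jk})^{2/(m-1)}$
with the center update (the $u^m$-weighted mean). Defaults are `c = 7`
clusters and fuzzifier `m = 1.25`. Seven clusters comfortably cover the
recurring embryonic shapes (several maternal-decay variants, sustained
activation, transient pulses, late rise); `m = 1.25` is crisp enough
that well-supported genes reach memberships near 1 while genes between
shapes stay ambiguous. Genes join their argmax cluster only when that
membership strictly exceeds 0.8; the rest remain unassigned and are
excluded from all cluster-level statistics, including the enrichment
background.

Numerical decisions:

* **Initialization.** Centers are seeded k-means++-style from the data
  (first center uniform, subsequent ones with probability proportional
  to squared distance from the chosen set), with the best of 5 seeded
  restarts kept by final objective. We tried the simpler option of
  uniform random memberships and discarded it: with a crisp fuzzifier,
  every row-normalized random membership matrix yields initial centers
  in a tight ball around the grand centroid, all restarts converge into
  the same local optimum, and distinct but nearby temporal shapes get
  merged while a well-separated shape is split. Spreading the seeds over
  the data removes that failure mode entirely.
* **Convergence.** Iteration stops when the largest membership change
  falls below `tol = 1e-6`, or at `max_iter = 1000`. The objective trace
  is stored and is non-increasing by construction (each half-step is an
  exact minimizer); tests assert this on random instances.
* **Singularity.** A profile coinciding with a center (squared distance
  below 1e−12) takes membership 1 there, 0 elsewhere.
* **Determinism.** All randomness flows from the `seed` argument; the
  caller's RNG state is saved and restored.

Per cluster and TF family, over- and under-representation are tested with
the two one-sided hypergeometric tails (`p_over = P(X >= k)`,
`p_under = P(X <= k)`), each at a fixed `alpha = 0.0025`. The low fixed
threshold stands in for an explicit multiplicity correction across the
roughly ten cluster tests a family undergoes; we inherit it as a fixed
constant rather than recomputing a correction, so reported flags are
comparable across runs with different cluster counts. The background is
the *assigned* genes of the species — representation is judged within the
clustered universe, not the whole catalog; genes with several family
labels count once per family.

## Cross-species comparison

Comparing clusters across species requires a time-point alignment — an
ordered, strictly monotone list of comparable time-point pairs, supplied
as data (automatic alignment inference is out of scope). Cluster centers
restricted to the aligned columns are compared by Euclidean distance. A
cluster pair (i, j) forms when d(i, j) is strictly smaller than the
distance from i *or* j to any other cluster of either species — the
strictest reading of mutual nearest neighbours, which also guards against
a cluster pairing across species while being closer to a sibling within
its own species. A `"cross-only"` rule (mutual row/column minima of the
cross-species matrix) is available for comparison. Exact distance ties
disqualify the clusters involved rather than being broken arbitrarily:
ties are logged and the clusters stay unpaired, which is conservative and
reproducible. An average-linkage dendrogram over the combined 2c centers
accompanies the pairing for display; average linkage is the conventional
default for profile centroids and is recorded in the output.

Family composition across species is compared per family with Fisher's
exact test on the 2 × (number of pairs) table of assigned members per
paired cluster — exact enumeration up to a table total of 200, a
Monte-Carlo null with fixed margins beyond. Pooled pair enrichment
re-runs the hypergeometric family test on the union of each pair's
members against the pooled assigned background of both species.

## Ortholog conservation statistics

Only ortholog pairs with both genes hard-assigned are *eligible*; a pair
is *concordant* when its two clusters are paired across species. The
observed concordant count is compared against 1,000 null sets, each
formed by sampling (uniformly, with replacement) an assigned gene from
each species, pair by pair, to the observed eligible count. We report
`Z = (obs − mean(null)) / sd(null)` and the add-one empirical p-value
`(1 + #{null >= obs}) / (1 + n_sets)`, which is never zero and bottoms
out at 1/1001 for 1,000 sets. When the null has zero spread (e.g. an
empty pairing forces every draw to zero) Z is reported as undefined
while the empirical p remains valid.

Per-pair expression conservation is the Pearson correlation over the
aligned common time points, with a two-sided t-test on T′ − 2 degrees of
freedom; the method is recorded and switchable to Spearman. Pairs with a
constant profile inside the common window are skipped (correlation
undefined) and counted. The correlation null repeats the count of
significant pairs on random gene pairs drawn from the same matrices and
the same time grid. Null pairs are sampled with replacement and
independently per set; the sampling scheme is a package decision, made
symmetric with the concordance null.

## Hourglass analysis

For every pair of time points (s, t) — the full grid, not only aligned
points — we compute the Euclidean distance between the two species'
ortholog expression vectors, each gene Z-normalized over its *own*
species' complete time course. The gene universe is ortholog pairs in
which both genes survive the clustering filters, so never-expressed and
near-constant genes cannot inject noise; this mirrors the normalization
used for clustering. The minimum-distance profile along either axis
(minimum over the other species' time points) localizes the stage of
maximal transcriptome similarity; strict interior local minima are
reported separately from boundary minima so a monotone profile is not
mistaken for a convergence peak.

## Ontology enrichment

Term enrichment over a DAG first propagates annotations by the true-path
rule (a term inherits the genes of all descendants). The classic test is
the one-sided hypergeometric tail per term, default `alpha = 0.01`,
skipping terms with fewer than 3 annotated background genes (the floor is
configurable). Because parent terms inherit their children's genes,
classic p-values are strongly correlated along the hierarchy; the `elim`
variant processes terms bottom-up (deepest first by longest path from a
root, ties in term-id order for determinism) and removes the study genes
of significant terms from all ancestors before testing them. `elim` is a
fully specified, well-understood decorrelation procedure; more elaborate
hybrid weighting schemes exist, and the output carries an `algorithm`
column so results are never ambiguous about which test produced them.

## The synthetic data generator

`simulate_species_pair()` builds both species from k shared temporal
archetypes — unit-variance curves on normalized developmental time
including monotone maternal decay, delayed maternal decay, sigmoidal
activation, transient pulses and a late rise, mutually separated by at
least 1.0 in Euclidean distance (typically 2.5–6). Species B's clock is
warped onto species A's by piecewise-linear interpolation through the
alignment pairs; the default grids are 12 evenly spaced hours (0–22) for
A against 12 insect-style unevenly spaced hours (2–49) for B with a
complete point-by-point alignment. A gene's profile is
`baseline + amplitude × archetype + noise`, with baseline ~ N(6, 1),
amplitude uniform on [1.5, 2.5] and i.i.d. Gaussian noise of sd 0.3 on
the log2 scale — a deliberately simple error model consistent with
Z-normalized clustering of log-scale intensities.

Planted structure, all recorded in a `truth` object:

* 5% never-expressed genes at level −2 (every value below the presence
  floor of 1), and 10% "constant" genes: flat baseline with noise sd
  `min(noise_sd/3, 0.15)`. The reduced sd is the generator's definition
  of constant expression — across 12 time points, i.i.d. noise at sd 0.3
  alone would often exceed a 1.0 range, and a "constant" gene that the
  range filter cannot recognize would make filter-recovery ill-posed.
* 300 ortholog pairs among clustered genes; a configurable fraction
  (default 0.5) share their archetype across species, the rest draw
  independently (and may coincide by chance, ~1/k of the time).
* One family (default zf-C2H2, base frequency 0.24 within a realistic
  frequency table over the six canonical families plus "other") with
  5-fold sampling odds inside archetype 1; ~10% of genes carry a second
  family label so many-to-many catalogs are exercised.
* Optional hourglass convergence windows in normalized time: away from a
  window, each species' genes receive independent extra noise whose sd
  ramps linearly (over 0.15 normalized time units) up to `divergence_sd`
  (default 1). Inside a window the species agree up to the base noise, so
  the stage-distance matrix dips there. Two windows produce the
  two-trough geometry seen when a phylotypic period splits.

What the generator does *not* emulate: count-level RNA-seq noise
(negative binomial overdispersion), probe-level artefacts, partially
overlapping time grids, gene losses/duplications in the ortholog map, and
archetype shapes that drift between species. Passing recovery tests
therefore shows the pipeline's statistics are correct and well calibrated
under their own assumptions — not that 7 clusters or any specific
threshold is right for a given real data set.

## Validation suite and problem sizes

The acceptance tests run the generator's study conditions — 700 TFs per
species, 7 archetypes, 12 time points, noise sd 0.3, 10% constant, 5%
never-expressed, 300 orthologs: filter recovery is exact and fuzzy
c-means reaches ARI ≥ 0.9 on ≥ 90% of 25 seeds; cluster pairing recovers
at least 6 of 7 archetype correspondences on ≥ 90% of 25 seeds (all 7
with zero distances at sigma = 0); the concordance null gives |Z| < 3 on
≥ 95% of 50 chance-level seeds with uniform-ish empirical p, and the
saturated p = 1/1001 on every seed at planted concordance 0.5; the
correlation test holds its 5% level within the binomial 99% envelope
over 1,000 independent pairs; the hourglass argmin lands inside a
planted window in ≥ 90% of 25 seeds and a two-window construction yields
exactly two interior minima; planted family enrichment is detected at
p < 0.0025 in ≥ 90% of 50 seeds while the null flag rate stays at level;
and the whole pipeline is byte-identical across reruns at a fixed seed.
The hypergeometric and Fisher primitives are checked exactly against
enumeration oracles (all feasible instances up to N = 20, and margin
enumeration for 2×2 tables).

## Limitations

Time-point alignment is an input, not an inference; the pairing rule is
geometric and has no uncertainty attached; the enrichment background
(assigned TFs) is one of two defensible choices — using all TFs with data
would shift p-values for clusters that absorb most of a family; `elim`
approximates, but is not identical to, hybrid hierarchy-weighting
schemes; and all calibration statements are with respect to the
generator's Gaussian, shape-sharing model.
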