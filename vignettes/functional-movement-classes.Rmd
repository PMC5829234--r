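---
title: "Classifying functional movement classes from acoustic telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional movement classes from acoustic telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Passive acoustic telemetry observes aquatic animals only when a tagged
individual swims within range of a moored receiver. A national-scale network
of receiver *installations* (groups of receivers deployed in one region)
produces, for each tagged animal, an irregular sequence of timestamped,
georeferenced detections. `moveclass` classifies individuals into
*functional movement classes* (FMCs) from those sequences alone — without
species identity — and asks how much of that classification, and of the
between-installation connectivity structure, survives when only part of the
receiver network is used.

The workflow is:

1. ingest quality-controlled detection logs (QC flags 1 and 2 retained);
2. compute seven per-individual movement covariates;
3. select the number of k-means classes with the gap statistic and name the
   classes a posteriori (Residents, Occasionals, Irruptors, Roamers);
4. characterize classes with a Euclidean-distance SIMPER decomposition;
5. build relative-movement networks over installations and compare the full
   array against its strategic (IMOS) and independent (non-IMOS) subsets.

A built-in agent-based simulator generates datasets with the statistical
structure this analysis assumes, so the whole pipeline runs and is tested at
desk scale.

## Movement covariates

For each individual with at least `min_detections` detections (default 2;
fewer detections leave the inter-detection quantities undefined, and
exclusions are reported, never silently dropped) we compute:

* `n_installations` — installations with at least one detection;
* `n_detections` — total detections;
* `mean_gap_min` — mean time between consecutive detections, minutes;
* `q25_km`, `q50_km`, `q75_km`, `q99_km` — quantiles of the great-circle
  distance (km, spherical Earth radius 6371 km) between the receiver
  positions of consecutive detections.

The 99% quantile, rather than the maximum, summarizes long-distance movement
without being a single-hop statistic. Two conventions are fixed explicitly
because dialects differ: quantiles interpolate linearly between order
statistics at positions $1 + (n-1)p$ (R's type-7 default), and distances use
*receiver* coordinates — the actual detection locations — so
within-installation receiver-to-receiver hops count as consecutive-detection
steps. Before clustering, each covariate is square-root transformed (to
reduce skew), centred, and scaled by the sample standard deviation
($n-1$ denominator), giving columns with mean 0 and sd 1.

```{r}
library(moveclass)
det <- read_detections("detections.csv")          # QC flags 1-2 kept
cv  <- covariate_table(det, min_detections = 2)
cm  <- build_covariate_matrix(cv$covariates)      # raw + transformed matrices
```

## Model selection with the gap statistic

`kmeans_fit()` runs Lloyd iterations from `n_init = 25` seeded random
restarts (initial centres are sampled data points; a cluster emptied during
iteration is reseeded deterministically at the point farthest from its
centroid) and keeps the lowest within-cluster sum of squares $W_k$.
`gap_statistic()` compares $\log W_k$ with its mean over $B = 50$ reference
datasets drawn uniformly over the observed range of each column — the simple
reference of the original gap-statistic proposal — and selects the smallest
$k$ with $\mathrm{gap}_k \ge \mathrm{gap}_{k+1} - s_{k+1}$, where
$s_k = \mathrm{sd}_b(\log W^*_{kb})\sqrt{1 + 1/B}$. If the rule never fires
the largest considered $k$ (`k_max`, default 10) is returned with a warning.
These defaults are package choices (the analysis they re-implement does not
state them) and are all configurable.

The implementation is cross-checked in the test suite against
`cluster::clusGap` (with `d.power = 2` and `spaceH0 = "original"`; `clusGap`
reports $W/2$, a constant offset that cancels in the gap values), against a
planted four-cluster Gaussian mixture, and against the single-blob null
case, where unstructured data must yield $k = 1$.

## Class naming and sensitivity

When four clusters are selected (or forced), classes are named from cluster
means of the *raw* covariates, operationalizing the a-posteriori
descriptions of the four movement syndromes: the cluster with the largest
mean `q99_km` is *Roamers*; of the rest, the largest `mean_gap_min` is
*Occasionals*; of the remaining two, the larger `n_detections` is
*Residents*; the last is *Irruptors*. Exact ties abort with a request for
manual naming; any other $k$ yields numeric class names. The heuristic is a
package construct and can be overridden by renaming the assignment table.

`sensitivity_analysis()` repeats the gap-statistic selection after removing
random subsets of 1, 10, and 100 tags (20 iterations each, by default) and
reports the per-iteration selections and their mean per removal size.

## SIMPER characterization

Which covariates drive between-class dissimilarity? Raw covariates are
first *dispersion weighted* — each covariate divided by the average over
classes of its within-class variance-to-mean index, so that erratically
over-dispersed covariates do not dominate — then `log(x + 1)` transformed.
Degenerate indices (a class mean of zero, zero variance, or a singleton
class) contribute index 1. The weighting averages class-level indices with
equal weights; this is a documented simplification of the permutation-tested
recipe used by commercial multivariate packages.

Euclidean distance does not decompose additively over variables, so
contributions are shares of *squared* distance: for individuals $i$ (class
$A$) and $j$ (class $B$), covariate $v$ contributes $(x_{iv} - x_{jv})^2$,
averaged over all cross pairs and expressed as a percentage of the total
(summing to 100 per comparison). Both pairwise tables and one-vs-rest
summaries are emitted, because single per-class percentages are commonly
reported but the underlying tables are pairwise. The implementation uses the
moment identity
$\overline{(a-b)^2} = \overline{a^2} + \overline{b^2} - 2\,\bar a\,\bar b$
and is tested against an explicit all-pairs loop at $10^{-10}$.

## Relative-movement networks

The edge weight from installation $a$ to $b$ is the number of times
individuals moved from $a$ to $b$ (consecutive detections at different
installations) divided by the total number of between-installation
movements. Pooling all individuals in that normalization is the default
(the literal reading of the definition); per-individual normalization
followed by averaging is available behind a flag. Subsetting to IMOS-only
or non-IMOS-only installations filters the detection stream *first*, so a
tag passing through an excluded installation contributes a skip transition
between its surviving neighbours (the alternative — dropping such
transitions — can be obtained by pre-filtering tags). Installations with no
retained transitions are dropped.

Metric conventions are fixed in `network_metrics()`: density is directed
edge count over $n(n-1)$; diameter and average path length use unweighted
directed shortest paths on the largest weakly connected component;
strength is the sum of in- and out-weights; eigenvector centrality is
computed on the symmetrized weighted graph (guaranteed convergence) and
scaled to a maximum of 1; betweenness is directed and unweighted;
communities come from greedy modularity maximization on the symmetrized
graph with nodes in lexicographic order (so membership is input-order
invariant), isolated installations forming singletons. The resulting 9
network-level plus 5 node-level metrics stand in for a metric list whose
original enumeration is not recoverable; the set is easy to extend through
`igraph`.

## The simulator

`generate_dataset()` emulates a linear coastal array: installation
centroids uniform along a 2,000 km meridian arc, 5 receivers scattered
within 1.5 km of each centroid, a third of installations labelled IMOS.
Individuals follow one of four archetypes in a daily loop: with probability
`p_move` the animal relocates to another installation drawn with weight
$e^{-d/\text{scale}}$ (a long-distance kernel with probability
`excursion_prob`; `return_home` forces the following relocation home), and
on each non-silent day it is detected a Poisson number of times at uniform
receivers of the occupied installation, at uniform times. Defaults (60
Residents, 120 Occasionals, 25 Irruptors, 45 Roamers for one year, seed 42)
keep the class imbalance of continental-scale data at roughly 1:10 scale
while staying under $10^6$–$10^7$ detections. Every individual runs on a
counter-based substream of the dataset seed, so output is byte-reproducible
and stable under reordering.

What the simulator does *not* emulate: detection-range decay, tides and
diel cycles, tag battery expiry, off-array habitat (movement is
installation-to-installation; off-array time is observationally identical
to silence), and the continuous geographic variety of a real national
array. Passing tests therefore demonstrate correctness of the computations
and qualitative behavior of the method, not field realism.

## What the synthetic conditions do and do not reproduce

On simulated data the class *signatures* hold (Residents detected most and
most locally; Occasionals sparsest in time; Roamers farthest-ranging across
the most installations), a forced four-class fit recovers the simulated
archetypes with accuracy around 0.83 under best bijective matching (the
acceptance script recomputes this), and the gap statistic is well calibrated
on unstructured data (selecting $k = 1$ essentially always on uniform
blobs).

The gap statistic does **not**, however, settle on four classes on the
simulated datasets: across seeds it selects either 1 or a value near
`k_max`. The cause is instructive. Each installation's five fixed receivers
give every site-attached individual *identical* within-installation step
quantiles, determined by its home installation's receiver layout — so the
lower distance quantiles carry tight, geographically quantized
micro-structure that a national array with hundreds of heterogeneous
installations does not produce at this resolution. The independent
`cluster::clusGap` implementation makes the same selections on the same
matrices, under both of its reference spaces. The simulated Irruptor class
is similarly hard to isolate: its rare excursions contribute only a couple
of long steps among thousands, leaving its 99% step quantile nearly
Resident-like, and at $k = 4$ it tends to merge with the site-attached
classes (its named cluster can have an Occasional majority). Cluster-number
instability under data removal is, notably, also a property of the original
continental analysis.

## Running everything

```{r}
sim <- run_simulation(simulation_config(), "data")   # detections/installations/truth CSVs
cfg <- pipeline_config(
  detections = "data/detections.csv",
  installations = "data/installations.csv",
  out_dir = "results", seed = 7
)
res <- run_full_analysis(cfg)
```

The run writes per-stage CSV artifacts (covariates, gap curve, assignment,
PCA coordinates, SIMPER table, network/node/community metrics, subset
effectiveness summaries, per-class network metrics) plus `manifest.json`
recording input hashes, the configuration, derived stage seeds, and the
selected $k$; re-running with the same seeds reproduces every artifact
bit-identically. The test suite and the acceptance script run the same
public functions at the scales given above (250 individuals for one
simulated year; 20 replicate datasets for the selection study; 500-point
blobs for null calibration).

## Known limitations

* The gap-selected $k$ on synthetic data reflects simulator geometry, not
  field structure (see above); analyses of real exports should treat the
  selected $k$ as exploratory, and the forced-$k$ path exists for exactly
  that reason.
* Dispersion weighting uses the simplified equal-weight index average, not
  a permutation-tested index.
* The QC flags are treated as opaque pass/fail values; no additional
  false-detection filtering is applied.
* Path-based network metrics are defined on the largest weakly connected
  component; comparing them across networks with very different component
  structure requires care.
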