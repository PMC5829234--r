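# moveclass

Functional movement classification of acoustic telemetry detections.

Passive acoustic telemetry records a tagged aquatic animal only when it
swims within range of a moored receiver, producing an irregular sequence of
timestamped, georeferenced detections per individual. Given such detection
logs from a network of receiver *installations* (groups of receivers
deployed in one region, labelled as strategic "IMOS" arrays or independent
"non-IMOS" project arrays), `moveclass`:

* computes seven per-individual movement covariates — number of
  installations with detections, number of detections, mean time between
  detections (min), and the 25/50/75/99% quantiles of great-circle distance
  (km) between consecutive detections — square-root transformed, centred and
  scaled for clustering;
* partitions individuals into **functional movement classes** with k-means,
  the number of classes selected by the **gap statistic**
  (gap<sub>k</sub> = E*[log W<sub>k</sub>] − log W<sub>k</sub>, one-standard-error rule),
  and names four-class solutions a posteriori: *Residents*, *Occasionals*,
  *Irruptors*, *Roamers*;
* characterizes the classes with **Euclidean-distance SIMPER** (per-covariate
  shares of mean squared between-class distance) after dispersion weighting
  and log(x+1) transformation;
* builds **relative-movement networks** over installations (edge weight =
  transitions between two installations ÷ total between-installation
  transitions), with 9 network-level and 5 installation-level metrics and
  modularity-based community detection, for the full array, its IMOS-only
  and non-IMOS-only subsets, and each movement class;
* ships an agent-based **detection simulator** with four movement
  archetypes (site-attached heavy-detection, site-attached sparse,
  home-based with rare excursions, wide-ranging nomadic) so the entire
  workflow runs reproducibly without database access.

Intended users are movement ecologists working with continental or
regional acoustic arrays who want a tested, scriptable re-implementation of
this classification-and-connectivity workflow.

## Worked example

Simulate the canonical desk-scale dataset (250 individuals, 12
installations over 2,000 km, one year) and run the full analysis:

```r
library(moveclass)

sim <- run_simulation(simulation_config(), "data")   # writes detections/installations/truth CSVs
cfg <- pipeline_config(
  detections    = "data/detections.csv",
  installations = "data/installations.csv",
  out_dir       = "results", seed = 7
)
res <- run_full_analysis(cfg)

head(as.data.frame(res$gap$curve), 5)
#>   k log_Wk    gap       s
#> 1 1  7.463 0.4859 0.02870
#> 2 2  7.072 0.5922 0.02282
#> 3 3  6.564 0.8984 0.02197
#> 4 4  6.270 1.0523 0.02332
#> 5 5  5.976 1.2741 0.02073
```

`log_Wk` is the log within-cluster dispersion of the data at each k, `gap`
its shortfall against uniform reference data, and `s` the reference
standard error used by the selection rule. On simulated data the gap curve
keeps rising (the simulator's fixed receiver geometry quantizes the lower
distance quantiles into geographic micro-clusters), so the selected k lands
at 1 or near `k_max` rather than at the four planted archetypes — see the
vignette for the full analysis of this behavior. The four-class structure
itself is recoverable by a forced fit:

```r
fit4 <- kmeans_fit(res$covmat$transformed, k = 4, seed = 101)
asn  <- name_clusters(fit4, res$covmat)
table(asn$class_name)
#>   Irruptors Occasionals   Residents     Roamers
#>          23         108          74          45
```

Matched against the simulator's truth table, this four-class assignment
recovers the archetypes with best-bijective-match accuracy **0.832**.
Roamers are characterized by the 99% distance quantile (SIMPER one-vs-rest
contribution 66.6% of squared between-class distance):

```r
w <- dispersion_weight(res$covmat$raw, asn$class_name)
s <- simper_euclidean(w, asn$class_name)
head(subset(s$contributions, comparison == "Roamers_vs_rest"), 3)
#>        comparison       covariate mean_sq_contribution percent cumulative_percent
#> 1 Roamers_vs_rest          q99_km                10.90   66.60               66.6
#> 2 Roamers_vs_rest n_installations                 2.44   14.90               81.5
#> 3 Roamers_vs_rest    mean_gap_min                 1.30    7.95               89.5
```

The full-array relative-movement network over the 12 simulated
installations:

```r
as.data.frame(res$networks$full$summary$network)
#>   n_nodes n_edges density diameter avg_path_length n_communities modularity reciprocity transitivity
#> 1      12     131   0.992        2            1.01             3       0.39       0.992            1
```

Every stage writes a CSV artifact under `out_dir` plus a `manifest.json`
(input hashes, configuration, derived seeds, selected k); re-running with
the same seeds reproduces all artifacts bit-identically.

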