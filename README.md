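# microAssembly

Diversity partitioning, assembly-process quantification and Bayesian
source tracking for host-associated microbial metacommunities.

Amplicon surveys of fish body habitats (skin, gill, stomach, hindgut)
and the surrounding water yield an OTU count table, per-sample metadata
(habitat, host body weight, site, month) and a phylogeny over the OTU
pool. `microAssembly` is for microbial ecologists who want to take such
data from raw counts to three answers:

* **Where the diversity lives** — Chao1 alpha diversity, Bray–Curtis
  beta diversity with PCoA / PERMANOVA / ANOSIM / (partial) Mantel, a
  distance-based regression of pairwise dissimilarity on body-weight
  difference |Δw| with a sample-permutation F-test, prevalence/abundance
  core-taxon calling, and the additive hierarchical Rao decomposition
  γ_Ecosystem = β_Inter-Habitats + β̄_Intra-Habitats + ᾱ_Local-Community
  (optionally on the Jost equivalent-numbers scale, where the identity
  holds exactly and every β is non-negative).
* **What assembles the communities** — per-pair βMNTD standardized into
  βNTI against a regional tip-shuffling null, Raup–Crick on Bray–Curtis
  (RC_Bray) against a richness- and occupancy-preserving null, and the
  five-way classification (βNTI > +2 heterogeneous selection, < −2
  homogeneous selection; otherwise RC < −0.95 homogenizing dispersal,
  RC > 0.95 dispersal limitation, |RC| ≤ 0.95 undominated) aggregated
  into per-habitat process profiles.
* **Who seeds whom** — leave-one-habitat-out Bayesian source tracking by
  collapsed Gibbs sampling (known sources plus an Unknown source), with
  posterior means and credible intervals.

A synthetic metacommunity generator (`simulateMetacommunity`) with
phylogenetically conserved habitat filtering, tunable dispersal and a
calibrated body-weight effect provides ground truth for validating every
stage; the whole chain is orchestrated by `runPipeline()` with one master
seed and bit-reproducible outputs. Data live in a `MetacomExperiment`
(a `SummarizedExperiment` plus a phylogeny slot).

## Worked example

Simulate a strongly habitat-selected metacommunity (3 habitats, 6 fish
each, 100-OTU pool, 1,000 reads per sample) and analyse it:

```r
library(microAssembly)

params <- simulationParams(n_habitats = 3, fish_per_habitat = 6,
                           pool_size = 100, reads_per_sample = 1000,
                           selection_strength = 50, dispersal_rate = 0,
                           seed = 1)
sim <- simulateMetacommunity(params)
mex <- sim$experiment
mex
#> MetacomExperiment: 100 OTUs x 18 samples
#>   habitats: gill (6), skin (6), stomach (6)
#>   total counts: 18,000 | tree with 100 tips

d <- brayCurtis(mex)
perm <- permanovaTest(d, habitats(mex), permutations = 999, seed = 1)
#> PERMANOVA pseudo-F = 385.24, R2 = 0.981, p = 0.001

part <- partitionDiversity(mex)   # equivalent-numbers Rao partition
#> % of gamma: alpha = 37.2, beta_intra = 1.4, beta_inter = 61.4

reg <- distanceRegressionByHabitat(mex, d, permutations = 999, seed = 1)
#> skin: slope = 0.00107 per g, F = 66.15, p = 0.034

assemblyProfile(mex, nNull = 199, seed = 1, includeBetween = TRUE)
#>     group n_pairs heterogeneous_selection ... dispersal_limitation
#> 1    skin      15                   0.000 ...                0.000
#> 2 between     108                   0.667 ...                0.333
#> 3    gill      15                   0.000 ...                0.000
#> 4 stomach      15                   0.000 ...                0.000
```

Read: habitats are almost perfectly separated (PERMANOVA R² = 0.98);
most diversity is between-habitat turnover (β_inter = 61% of γ);
within the skin, dissimilarity grows by ~0.0011 per gram of body-weight
difference (permutation p = 0.034); and two thirds of across-habitat
pairs are classified as heterogeneous selection — the generative regime
(`sim$truth$regime` is `"selection-dominated"`) is recovered. Within
habitats, communities are *more* similar than the occupancy null
expects, so within-pairs fall to homogenizing dispersal.

`runPipeline(config, experiment)` runs every stage (rarefaction,
diversity, weight regression, core taxa, Rao partition, assembly
processes, source tracking) and writes per-stage TSV/JSON outputs plus
an aggregated `report.json`; a YAML config plus
`inst/scripts/metacom-cli.R` exposes the same as `simulate` and `all`
shell subcommands.

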