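# aquassembly

Statistical analysis of aquatic bacterial communities along salinity and
nutrient gradients: diversity, constrained ordination, spatial variation
partitioning, permutation tests on distance matrices, functional
profiling, and a null-model analysis of community assembly — plus a
ground-truthed niche/neutral community simulator for validating the whole
pipeline.

## Who this is for

Microbial ecologists working with OTU tables from 16S amplicon surveys of
lakes and rivers who want, in one reproducible toolchain:

* preprocessing (low-abundance filtering, taxonomy exclusion, seeded
  rarefaction) and habitat-group assignment by ecosystem and salinity;
* α-diversity (bias-corrected Chao1, Shannon, inverse Simpson) with
  Kruskal–Wallis compact-letter comparisons, Bray–Curtis β-diversity,
  UPGMA dendrograms and group OTU-overlap summaries;
* redundancy analysis (RDA) on Hellinger-transformed tables with
  permutation-based forward selection and VIF pruning, PCNM spatial
  eigenfunctions, three-set variation partitioning by partial RDA, and
  distance–decay regression;
* Mantel, ANOSIM and PERMANOVA permutation tests, and a two-sided
  permutation test for differentially abundant functions with
  Benjamini–Hochberg FDR;
* an abundance-based null model and the **stochasticity ratio (SR)**.

## The core statistic

For each sample pair, observed Bray–Curtis similarity
`C_ij = 1 − d_ij` is compared with its expectation `E_ij` under a null
model that preserves each sample's richness and read total exactly while
drawing species by occupancy and filling reads by regional abundance
(mean over 1000 randomizations by default).  The per-pair stochasticity is
the folded ratio

    ST_ij = E_ij / C_ij   if C_ij ≥ E_ij
    ST_ij = C_ij / E_ij   otherwise

and a group's SR is `100 × mean(ST_ij)` over its within-group pairs.
SR near 100% means the observed structure is what the null already
produces (stochastic assembly); low SR means strong departure from the
null (deterministic assembly, e.g. environmental filtering by salinity).
Group structure is additionally tested by comparing the observed PERMANOVA
pseudo-F against the F distribution over randomized datasets.

## Worked example

Simulate a 40-sample, four-group salinity gradient under pure niche
assembly (`nu = 0`), then estimate group separation and the SR:

```r
library(aquassembly)
cfg <- sim_config(n_species = 300, reads_per_sample = 2000, nu = 0, seed = 101)
md  <- simulate_metadata(cfg)
cm  <- simulate_communities(cfg, md)$community
cm  <- rarefy_community(preprocess_community(cm), seed = 1)
bc  <- bray_curtis(cm)

anosim_test(bc, md$habitat_group, n_perm = 999, seed = 1)[c("statistic", "p")]
#> $statistic
#> [1] 0.9744203
#> $p
#> [1] 0.001

ens <- expected_similarity(cm, n_rand = 200, seed = 2)
stochasticity_ratio(dm_complement(bc), ens, md$habitat_group)
#> stochasticity ratio (SR, % of null expectation):
#>   Group I  Group II Group III  Group IV
#>      50.6      59.8      44.8      32.8
#> letters (alpha = 0.01 ): Group I=a  Group II=a  Group III=b  Group IV=c
#> overall SR = 44.0%
```

ANOSIM R ≈ 0.97 says the four habitat groups are almost completely
separated in composition.  The SR declines from the freshwater lake group
to the high-brackish group (59.8% → 32.8%): under pure niche assembly the
high-salinity communities sit far from the null expectation, i.e.
deterministic processes dominate — exactly the behaviour the generator was
told to produce.  Rerunning with `nu = 1` drives all groups' SR above 90%.

The full pipeline — diversity tables, ordination, variation partitioning,
distance decay, SR and a reproducibility manifest in one output
directory — runs with:

```r
run_pipeline(pipeline_config(sim = sim_config(nu = 0.5, seed = 1),
                             out_dir = "report"))
```

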