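# sedabench

Benchmarking beta-diversity workflows and transfer functions for
sedimentary ancient DNA (sedaDNA).

## What this is for

sedaDNA preserved in lake and marine sediments records past communities
beyond the fossil record, but DNA degradation turns the recovered count
matrices into noisy data: taxa become false negatives, alpha diversity
drops, and the sequencing depth "freed" by the missing taxa is spent on
the surviving, mostly abundant, taxa. Whether a community analysis
survives that noise depends on three method choices made in sequence —
the count transformation, the beta-diversity index, and the ordination —
and on whether a transfer function (a model calibrated on modern
community–environment pairs and applied to past assemblages) is trained
on the composition matrix itself or on ordination coordinates.

`sedabench` implements the whole benchmark for R users working on
paleoecology, paleoceanography or microbial community ecology:

* a seeded hierarchical negative-binomial community simulator
  (cluster and gradient settings, 100 samples × 400 taxa by default,
  with synthetic per-taxon sequences and a phylogeny so sequence- and
  tree-aware methods run out of the box);
* an ancient-DNA degradation model: ~25/50/75% of detected taxa per
  sample turned into false negatives (with ±3% jitter), the removed
  reads reallocated to the sample's top-decile taxa so sequencing depth
  is preserved exactly;
* 13 count transformations, 16 beta-diversity indices (including TINA,
  PINA and the weighted UniFrac family) and 4 ordinations
  (PCoA, NMDS, t-SNE, UMAP) behind uniform dispatch interfaces with a
  compatibility table;
* PERMANOVA pseudo-F scoring of every combination, at the distance level
  and on Euclidean distances between embedding coordinates, i.e.

  F = (SS_model / df_model) / (SS_residual / df_residual)

  computed from the Gower-centered matrix of −d²/2, with permutation
  p-values, plus betadispersion F across degradation levels;
* KNN and random-forest transfer functions (60–40 split, repeated
  10-fold CV tuning) trained on modern samples and applied to degraded
  samples, with top-5 aggregation and Tukey HSD comparisons of
  composition- versus ordination-based approaches.

## Worked example

```r
library(sedabench)

params <- draw_sim_params(seed = 42, mode = "cluster")
modern <- simulate_community(params)
modern
#> community_dataset: 100 samples x 400 taxa (cluster mode, seed 42)
#>   clusters: C1 C2 C3 C4 C5

plan    <- assign_effect_levels(modern, "cluster", seed = 42)
ancient <- degrade_counts(modern, plan)
identical(rowSums(ancient$counts), rowSums(modern$counts))
#> TRUE      # sequencing depth preserved exactly, per sample
```

The mean realized dropout among the level-0.50 samples is 50.6% — the
target fraction up to the ±3% jitter. Scoring one classical workflow
(Hellinger transformation + Bray–Curtis) on both versions:

```r
f_mod <- permanova_f(beta_distance(transform_counts(modern$counts, "hellinger"),
                                   "bray"), modern$metadata$cluster)
f_anc <- permanova_f(beta_distance(transform_counts(ancient$counts, "hellinger"),
                                   "bray"), ancient$metadata$cluster)
#> PERMANOVA pseudo-F: modern 19.6, ancient 3.1 (both p = 0.001)
```

The cluster signal survives degradation but the pseudo-F collapses by a
factor of ~6: the noise, not the biology, absorbs most of the
between-sample variance. A transfer function calibrated on a joint UMAP
embedding is far more robust on the same data:

```r
rec <- transfer_evaluate(modern, ancient,
                         list(feature_space = "embedding",
                              transform = "hellinger", index = "bray",
                              ordination = "umap"),
                         algorithm = "knn", seed = 1)
rec[, c("effect_level", "n", "transfer")]
#>  effect_level   n transfer
#>           all 100        1
#>             0  25        1
#>          0.25  25        1
#>           0.5  25        1
#>          0.75  25        1
```

Here the KNN transfer function recovers every degraded sample's cluster
of origin, even at 75% false-negative taxa.

## The analysis workflow

The numbered drivers under `analysis/` run the benchmark end to end at
desk scale and write their tables under `results/`:

1. `01_simulate.R` — seeded community matrices (+ sequences, phylogeny);
2. `02_degrade.R` — degraded copies + per-sample degradation plans;
3. `03_benchmark_distances.R` — transformation × index grid, PERMANOVA
   pseudo-F on distance matrices, median-F rank tables;
4. `04_benchmark_ordinations.R` — transformation × index × ordination
   grid scored on embedding distances, plus betadispersion by level;
5. `05_transfer.R` — KNN/RF transfer functions on composition matrices
   and joint embeddings, top-5 aggregation and Tukey HSD letters.

Each is a thin narrative script over the exported functions; rerun any
stage with the same seeds and you get bit-identical outputs.

On the default desk-scale run (three datasets per mode, seeds from
`study_design()`), the drivers print, among other things: TINA-based
combinations lead the modern-DNA distance ranking (median pseudo-F ~7700
for chi-square+TINA) but collapse on degraded data, where
chi-square+Pearson-type combinations take over (median F ~8.3–8.7);
every top-5 embedding-level combination for degraded data includes UMAP;
the median betadispersion F across effect levels is 0.94 for UMAP
embeddings against 138.9 for NMDS; and the Tukey comparison of transfer
approaches assigns the ordination-based approaches the top letter group
at the 75% effect size (mean transfer accuracy 0.99/0.93 for
embedding-RF/KNN versus 0.79/0.67 for the composition-based ones).

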