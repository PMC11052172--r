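# gutassembly

Tidyverse-native tools for the community ecology of gut microbiomes
profiled by 16S amplicon sequence variants (ASVs). The package covers the
full analysis arc of a wild-animal gut microbiome study:

1. **Preprocessing** — low-count ASV filtering (pooled total < 5),
   rarefaction to even depth, genus aggregation, relative abundances.
2. **Enterotype discovery** — partitioning around medoids (PAM) over
   genus-level Bray–Curtis dissimilarity, model selection by the
   Calinski–Harabasz pseudo-F
   `CH(k) = [B/(k-1)] / [W/(n-k)]`
   in PCoA space, with silhouette validation, ANOSIM, and Wilcoxon
   rank-sum contrasts of Shannon/Gini–Simpson diversity.
3. **Co-occurrence networks** — Spearman screening of all taxon pairs
   (|ρ| > 0.6, BH-adjusted p < 0.05), plus the six standard topology
   features (diameter, modularity, clustering coefficient, density,
   average degree, average path length).
4. **Sloan neutral community model** — occurrence frequency predicted as
   `1 − I_d(Nm·p, Nm·(1−p))` (regularized incomplete beta), `Nm` fit by
   bounded least squares, R², 95% Wilson occurrence bands, and the
   above/within/below partition of ASVs.
5. **Null-model assembly partitioning** — abundance-weighted βMNTD,
   βNTI from tip-shuffle nulls, Raup–Crick (RC_bray) from
   richness/abundance-preserving nulls, and the Stegen-style five-process
   partition: βNTI > +2 variable selection, βNTI < −2 homogeneous
   selection, then RC > +0.95 dispersal limitation, RC < −0.95
   homogenizing dispersal, |RC| ≤ 0.95 drift.
6. **Host factors** — Mantel tests of βNTI against altitude, body length,
   body weight and BMI distance matrices.

Every stage is exercised end to end by bundled synthetic-data generators
with known ground truth (enterotype mixtures, Sloan-neutral communities,
Brownian-trait habitat filtering on a Yule phylogeny), so the whole
pipeline is testable without any sequencing download. It is aimed at
microbial ecologists analyzing ASV tables from QIIME2/DADA2-style
pipelines.

## Worked example

Discover enterotypes in a simulated 94-sample community and fit the
neutral model:

```r
library(gutassembly)

sim <- simulate_enterotype_mixture(n_samples = 94, n_taxa = 200,
                                   depth = 20000, seed = 1)
genus_bc <- sim$table |> relative_abundance() |> bray_curtis()
fit <- select_k(genus_bc, k_min = 2, k_max = 6)
fit
#> Enterotype fit: k_best = 2
#> cluster sizes: 47/47
#> CH profile:
#>  k        ch silhouette
#>  2 104.62784  0.4969316
#>  3  55.00890  0.3596887
#>  4  37.97455  0.3562104
#>  5  29.55057  0.3550674
#>  6  24.89933  0.3575791

anosim(genus_bc, tidy(fit)$cluster, n_perm = 999, seed = 1)
#> # A tibble: 1 × 5
#>   method statistic p_value n_perm n_groups
#>   <chr>      <dbl>   <dbl>  <dbl>    <int>
#> 1 ANOSIM         1   0.001    999        2

nsim <- simulate_neutral(n_samples = 50, n_taxa = 1000, depth = 20000,
                         Nm = 2000, seed = 1)
ncm_fit(nsim$table)
#> Sloan neutral community model fit
#>   Nm = 1973.3  (m = 0.09867, N = 20000.0 reads/sample, d = 3.47e-05)
#>   R^2 = 0.987 over 815 taxa; 82.82% within the wilson 95% band
```

The CH profile peaks at k = 2 (the simulated number of types), ANOSIM
confirms the separation (R = 1 at its minimum attainable p of 0.001 with
999 permutations), and the neutral fit recovers the simulated dispersal
parameter Nm = 2000 within 1.5% with 83% of ASVs inside the 95%
occurrence band. Fitted objects have `tidy()`/`glance()` methods and
`autoplot()` figures (CH profile, occupancy–abundance curve with its
band, PCoA ordination).

`run_pipeline(pipeline_config(...))` orchestrates all stages from one
config (files in, TSV/JSON out, per-stage derived seeds, provenance
headers) and `summarize_run()` renders a plain-text report; a thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`.

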