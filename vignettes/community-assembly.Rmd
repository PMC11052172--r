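---
title: "Enterotypes and community assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterotypes and community assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutassembly)
```

gutassembly implements the analysis arc common to wild-animal gut microbiome
studies: discover discrete community types (enterotypes) in an ASV table,
contrast their diversity and composition, summarize their co-occurrence
structure, and ask which ecological processes — selection, dispersal, drift —
assembled them. This vignette is the package's account of those methods: the
models, the tunable parameters, the numerical choices, and what the bundled
synthetic-data generators do and do not establish.

## Data model and preprocessing

A community table is a tibble whose first column is `sample_id` and whose
remaining columns are per-taxon counts (or relative abundances); every
function takes it first, so stages chain with the pipe. Preprocessing
mirrors standard amplicon practice:

* `filter_low_abundance_asvs()` removes ASVs with a pooled count below 5
  (strict `< 5`, totals pooled across all samples). The filter precedes
  rarefaction in `run_pipeline()`'s canonical order; the reverse order is
  available via `filter_before_rarefy = FALSE` because published pipelines
  are split on this point and the choice should be explicit, not implicit.
* `rarefy()` subsamples each sample without replacement to the smallest
  sample total (one seeded draw, seed recorded in the result's attributes;
  averaging repeated rarefactions would shrink the very sampling variance
  the downstream null models rely on).
* `aggregate_by_genus()` sums ASVs within genus for enterotyping; ASV-level
  resolution is kept for networks and null models. Unassigned genera pool
  under an explicit `g__unassigned` sentinel so mass is never silently lost.
* Tree/table reconciliation (`reconcile_tree_table()`) is a separate,
  logged step: phylogenetic functions refuse mismatched taxa rather than
  pruning behind the user's back.

## Enterotype discovery

Genus-level Bray–Curtis dissimilarities are clustered by partitioning around
medoids (PAM, BUILD + SWAP; deterministic for a given matrix), scanning
k = 2..6. The Calinski–Harabasz pseudo-F selects k, computed in the full
positive-eigenvalue PCoA space of the distance matrix — the convention of
the standard enterotyping tutorials — rather than on raw distances, so that
between/within sums of squares are well defined; ties break toward smaller
k (parsimony). Mean silhouette width is reported alongside as validation.
Separation of the discovered types is tested by ANOSIM (rank-based, with
the `(1 + hits)/(1 + n_perm)` p estimator, so p is never exactly 0), and
alpha-diversity contrasts use two-sided Wilcoxon rank-sum tests (exact
enumeration when both groups have at most 8 untied values). Shannon
diversity is in nats and "Simpson" means Gini–Simpson `1 - sum(p^2)`, the
convention of common amplicon pipelines; inverse Simpson is a flag.

## Co-occurrence networks

Within each enterotype's sample subset (relative abundances renormalized
within the subset), taxa with mean relative abundance below 0.01% are
dropped, all remaining pairs are screened by Spearman correlation, and an
edge requires `|rho| > 0.6` (strict) together with Benjamini–Hochberg
adjusted `p < 0.05` over all screened pairs. Both signs are kept. Spearman
p values use the t approximation, which remains valid under the heavy ties
of sparse count data. Topology summaries follow the six standard
network-level features; two conventions matter on sparse graphs and are
fixed deliberately: diameter and average path length are computed on the
largest connected component (they are infinite otherwise), and modularity
is the best partition found by greedy (Clauset–Newman–Moore) agglomeration
on the unweighted graph — chosen over Louvain because it is deterministic,
which keeps network outputs bit-reproducible without a seed.

## Sloan neutral community model

For each taxon, `occurrence_stats()` computes its mean relative abundance
p and occurrence frequency (fraction of samples with a nonzero count). The
Sloan model predicts frequency as the upper tail of the taxon's local
abundance distribution, `1 - pbeta(d, Nm * p, Nm * (1 - p))`, where `Nm`
(metacommunity size x migration rate) is the single free parameter and `d`
is the detection limit. `ncm_fit()` estimates `Nm` by least squares on
untransformed frequencies with a bounded 1-D search over `log(Nm)` in
`[1, 1e7]`; `R^2 = 1 - SSE/SST` is reported as-is and may be negative.

One numerical choice deserves emphasis: the default detection limit is the
*half-detection abundance* `d = log(2)/N` rather than the classic `1/N`
(N = mean reads per sample). A taxon at local relative abundance x is seen
among N reads with probability `1 - (1 - x)^N`, which crosses 1/2 at
`x ≈ log(2)/N`; matching the model's step-function detection to that point
makes the least-squares estimator essentially unbiased under
Dirichlet-multinomial sampling, whereas `d = 1/N` overestimates `Nm` by
about 25% in the package's own parameter-recovery experiment (median
recovered ratio 0.99 vs 1.25 at Nm = 2000, 50 samples x 1000 taxa, depth
20 000). Pass `d = 1/N` explicitly for the literal Burns-style convention.
The 95% occurrence band is a Wilson score interval at the predicted
frequency with n = number of samples (`ci_method = "beta"` gives a
Clopper–Pearson-style beta-quantile band); each taxon is partitioned as
above/within/below, and the within fraction is the usual "percent neutral"
headline number.

## Phylogenetic and taxonomic null models

`beta_mntd()` is the abundance-weighted mean nearest-taxon distance between
communities: for each taxon in one community, the patristic distance to its
closest relative in the other, weighted by relative abundance, averaged in
both directions. A taxon present in both communities contributes zero (its
nearest relative is itself). `beta_nti()` standardizes the observed value
against a null built by shuffling taxon labels across the tree tips
(equivalently, permuting rows/columns of the patristic distance matrix over
the table's taxon pool — the most common published null; a per-pair-pool
variant was considered and rejected as the default because the whole-table
pool matches the metacommunity framing of the rest of the pipeline). With a
shared seed the z-score is exactly invariant to uniform branch-length
scaling. Degenerate pairs (null standard deviation 0, which arises when two
communities have identical support) are reported as 0 and flagged.

`raup_crick_bray()` compares observed Bray–Curtis against nulls that
preserve each sample's richness and total abundance, drawing species by
metacommunity occupancy and filling individuals by metacommunity relative
abundance; the null quantile is rescaled to [-1, 1]. Note a structural
property verified in the tests: samples that are plain multinomial draws
from one shared pool are *more* similar than this null expects (RC near
-1) — that is the homogenizing-dispersal signature, not a bug; RC centers
near 0 only when the data-generating process matches the null's own
two-step assembly scheme.

`partition_processes()` applies the Stegen-framework rules: betaNTI > +2
variable selection; betaNTI < -2 homogeneous selection; otherwise RC >
+0.95 dispersal limitation, RC < -0.95 homogenizing dispersal, |RC| <= 0.95
drift. The stochastic band uses `|betaNTI| <= 2` inclusive, so every pair
receives exactly one label and the five fractions sum to 1. Mantel tests
relate the betaNTI matrix (betaMNTD also supported) to absolute-difference
matrices of host factors (altitude, body length, weight, BMI); the package's
Mantel is two-sided on |r| with joint row/column permutation and reports
both r and r².

## The synthetic-data generators and what they establish

All generators are pure functions of their seed and return ground truth
alongside the table.

* `simulate_enterotype_mixture()` draws Dirichlet-multinomial samples
  around per-cluster mean compositions on a shared geometric background:
  cluster 1 boosts a single dominant taxon (a Lactobacillus-style
  dominance type) while other clusters boost an even block (a
  Muribaculaceae-style diverse type), so cluster 1 has lower expected
  Shannon diversity by construction. Defaults `effect_size = 4`,
  `concentration = 40` were chosen once to represent a strongly separated
  two-type gut community at a 94-sample study scale; `effect_size = 0`
  collapses the means for null-control experiments.
* `simulate_neutral()` draws each sample from `Dirichlet(Nm * p)` over a
  normalized geometric metacommunity (ratio `shape`), giving local
  relative abundances exactly the `Beta(Nm p, Nm (1 - p))` marginal the
  Sloan model assumes, then multinomial counts. Calibration experiments
  use 20 samples x 200 taxa at depth 2000 with `shape = 0.97` (mean
  occupancy ~0.6, as in rarefied gut data) because a fully saturated
  table makes betaMNTD degenerate — every taxon is its own nearest
  neighbor everywhere.
* `simulate_selected()` evolves a Brownian trait on a Yule tree and
  filters multinomial sampling weights by a Gaussian niche function of the
  sample's environment. The positive controls place the optimum at the
  *realized trait maximum* (an actual clade's niche): an optimum at the
  Brownian root state selects a polyphyletic set — every major clade
  retains near-ancestral lineages — and produces little phylogenetic
  clustering, an instructive failure mode discovered during design. The
  homogeneous-selection control uses a 1000-tip pool, 20 communities at
  depth 1000, selection strength 0.5, flat base abundances and Dirichlet
  concentration 100 (drift within the selected clade creates the
  close-relative turnover betaNTI detects); the variable-selection control
  splits samples between optima at the trait minimum and maximum.
* `simulate_metadata()` assigns samples to 7 sites with one uniform
  altitude each in 120–838 m (a realistic lowland elevation span),
  body length ~ N(95, 8) mm and BMI ~ N(0.0030, 0.0004) g/mm² for a
  ~30 g, ~95 mm rodent, with `bmi = weight/length²` exact.

Passing tests on these generators establish that each estimator recovers
the structure it targets under its own model assumptions at realistic
problem sizes. They do not establish robustness to features real 16S data
add on top — compositional correlation between dominant taxa, chimeric or
contaminant ASVs, uneven sequencing effort beyond what rarefaction removes,
phylogenetic signal in detection efficiency — and the acceptance thresholds
(e.g. Nm recovered within ±15%) are properties of these study conditions,
not guarantees for arbitrary data.

## Numerical conventions and degenerate inputs

* Randomized procedures (rarefaction, permutation tests, null models,
  generators) take explicit integer seeds; `run_pipeline()` derives
  per-stage seeds from one master seed keyed by stage name, so adding a
  stage never perturbs earlier stages' random streams.
* Permutation p values use `(1 + hits)/(1 + n_perm)` throughout.
* Calinski–Harabasz returns `Inf` when the within-cluster dispersion is
  numerically zero; silhouette scores singleton clusters 0.
* `R^2` of the neutral fit is never clamped; anti-neutral occupancy
  patterns legitimately fit worse than the mean.
* Problem sizes in the test and acceptance harnesses (e.g. 199
  randomizations for calibration runs, 999 for headline permutation tests;
  20-sample calibration communities) are the package's chosen study
  conditions, balancing the precision of a z-score built from its null
  sample against the number of independent replicates.

## Known limitations

* betaNTI on tables whose communities share nearly all taxa is
  uninformative (degenerate nulls); the package flags rather than hides
  this.
* The Raup–Crick null conditions on observed richness; it is not a test of
  richness differences themselves.
* PAM enterotyping inherits the general caveat that discreteness is
  imposed, not discovered: the null-effect guard (flat CH profile, ANOSIM
  R ≈ 0 under `effect_size = 0`) is the package's protection against
  over-reading gradient variation as clusters.
* Network modularity from greedy agglomeration can sit below the Louvain
  optimum on large graphs; determinism was preferred for reproducibility.
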