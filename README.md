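# mipror

Metaproteomic analysis of in vitro gut microbiome culture models:
peptide-level taxonomy, taxon-function coupled stability, and in
vitro–in vivo concordance of drug responses.

## What it does, and for whom

In vitro culture models (96-deep-well formats such as MiPro) promise
scalable drug–microbiome screening, but only if the cultured community
keeps the inoculum's taxonomic composition and taxon-specific functional
activity, and responds to drugs the way the host microbiome does.
`mipror` is for microbiome researchers who validate such models with
metaproteomics. It takes MetaLab-style post-search tables (peptides with
per-sample intensities, protein groups with LFQ intensities and
COG/KEGG/enzyme annotations, taxonomic lineages, sample metadata) and
provides the full analysis chain:

- **Peptide taxonomy** — lowest-common-ancestor assignment over seven
  ranks; biomass-contribution matrices at any rank from summed peptide
  intensities, with the ≥ 3-distinct-peptides filter.
- **Functional quantification** — Q25/Q50 presence filters, COG category
  rollups, KEGG pathway sums, within-pathway enzyme fractions.
- **Taxon-function coupling** — the per-sample (taxon, COG) → intensity
  profile; the stability statistic r (Pearson correlation of two
  samples' profiles over the union of their cells, zero-filled); a
  hypergeometric taxon-function enrichment ranking (top-30 links).
- **Ecology** — Bray-Curtis, PCoA, Shannon-Wiener diversity, PCA on COG
  matrices, and ANOSIM with an exact (exhaustively enumerated)
  permutation p-value for small designs,

  R = (mean between-group rank − mean within-group rank) / (n(n−1)/4).

- **Drug response** — NIPALS PLS-DA with VIP scores,
  VIP_j = sqrt(p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a),
  strict VIP > 1 / VIP > 2-on-all-components selection; paired in
  vitro/in vivo change tables (Δ relative abundance), per-subject
  Pearson r, quadrant agreement %, and two-sided rank-sum tests on
  enzyme fractions.
- **Synthetic data** — a ground-truthed generator of realistic
  metaproteomic studies (log-normal biomass, controlled peptide
  degeneracy, multiplicative noise, detection-limit missingness, planted
  treatment effects) so the whole pipeline is testable end to end.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, `autoplot()` for each result type.

## Worked example

Simulate a three-donor culture-stability study (timepoints 0/9/24 h, two
media, one of which drifts) and run the full stability analysis:

```r
library(mipror)

cfg <- sim_config(seed = 42)
com <- sim_community(cfg)
design <- design_stability(n_subjects = 3, timepoints = c(0, 9, 24),
                           media = c("MiPro", "BCM"), n_replicates = 3)
design$Treated <- design$Condition == "BCM"   # plant a drift in BCM
cfg$treatment_effects <- tibble::tibble(
  target = c("Phylum_01", "Phylum_02"), level = "phylum",
  effect = c(2.5, 0.4))
sim <- sim_dataset(com, design, cfg)

report <- run_stability(sim$dataset, seed = 1)
report
#> <stability_report>
#>   mean taxon-function r vs baseline: 0.970
#>   ANOSIM:
#> # A tibble: 4 × 5
#>   Condition grouping        R     p method
#>   <chr>     <chr>       <dbl> <dbl> <chr>
#> 1 MiPro     Timepoint -0.0795 0.977 permutation
#> 2 MiPro     Subject    1      0.001 permutation
#> 3 BCM       Timepoint  0.538  0.001 permutation
#> 4 BCM       Subject    0.334  0.001 permutation
```

Read: samples cultured in the maintaining medium stay indistinguishable
across timepoints (ANOSIM R ≈ −0.08, p = 0.98 — donors, not time,
structure the distances), while the drifted medium separates over time
(R = 0.54, p = 0.001). The taxon-function coupled profiles of cultured
samples correlate with their own donor's inoculum at r ≈ 0.97:

```r
glance(report$taxfunc)
#> # A tibble: 1 × 4
#>   mean_r   sd_r n_samples n_baseline
#>    <dbl>  <dbl>     <int>      <int>
#> 1  0.970 0.0191        45          9

report$pcoa
#> <mipro_ordination:pcoa> 45 samples; axis 1-2: 64.9% / 16.6% of variance
```

`autoplot(report$pcoa, sim$dataset$metadata)` draws the ordination;
`run_drug_response()` does the same for a paired two-arm study, and a
thin CLI (`inst/scripts/mipror`, verbs `simulate` / `stability` /
`drug-response`) drives both from YAML configs.

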