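---
title: "Methods: metaproteomic stability and drug-response analysis in mipror"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaproteomic stability and drug-response analysis in mipror}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipror)
```

## The analytical problem

In vitro culture models of the human gut microbiome (96-deep-well formats
such as MiPro) are only useful for drug screening if the cultured
community keeps the taxonomic composition and the taxon-specific
functional activity of the stool inoculum, and if its response to a drug
mirrors the host's. Metaproteomics measures both at once: peptide
intensities carry taxonomic information (through the peptides' possible
protein sources) and protein-group LFQ intensities carry functional
information (COG categories, KEGG pathways, enzymes). `mipror` implements
the full analysis chain on MetaLab-style post-search tables and couples
it to a ground-truthed synthetic-data generator so every stage can be
validated without raw mass-spectrometry data.

## Peptide taxonomy and biomass contributions

Each peptide is assigned the **lowest common ancestor** (LCA) of the
lineages of all proteins that contain it, comparing the seven ranks
superkingdom → species one rank at a time; the first rank at which the
candidate lineages disagree (or are unresolved) ends the assignment.
Peptides that resolve only to the root are treated as unassigned. The
**biomass contribution** of a taxon at a rank is the sum of the
intensities of the peptides whose lineage is resolved at least to that
rank and matches the taxon. Peptides resolved above the requested rank go
to an explicit *unassigned* bucket rather than being redistributed — we
prefer losing mass transparently over inventing an apportionment rule —
so at every rank

\[ \sum_{\text{taxa}} I_{t,s} + I_{\text{unassigned},s} =
   \sum_{\text{peptides}} I_{q,s} . \]

Taxa quantified by fewer than `min_distinct_peptides = 3` distinct
peptide identifiers are dropped, matching the usual "quantified with ≥ 3
peptides" convention. The count is dataset-wide, not per sample; whether
search engines apply it per sample is not documented, so the threshold
and its scope are arguments, not constants. Where a ratio or change
operator needs a nonzero denominator, zeros are replaced by a
pseudo-abundance of half the smallest nonzero value in the matrix.

## Functional rollups

Protein groups pass a presence filter first: nonzero LFQ in at least 25 %
of all samples (Q25) for single-cohort analyses, or at least 50 % within
*every* compared subgroup (Q50) for differential analyses; the comparison
is `>=`. COG category abundance is the sum of member protein LFQ, with an
explicit `unannotated` row so the rollup conserves each sample's total. A
protein annotated to several KEGG pathways contributes its full LFQ to
each of them — pathway sums are deliberately not a partition. Within one
pathway, enzyme abundances are normalized by the summed intensity of all
enzyme-annotated proteins of that pathway, giving per-sample fractions
that sum to one and are invariant to global rescaling of a sample.
Pathway "relative abundance" divides the pathway sum by the sample's
total protein LFQ; whether published figures used raw or normalized sums
is rarely stated, so this is switchable.

## The taxon-function coupled profile and its stability statistic

The central object is the per-sample sparse mapping
\((\text{taxon node}, \text{COG}) \mapsto\) (summed peptide intensity,
matched-protein count): peptides keep their own LCA node, so a protein
group is never attributed to taxa its peptides do not support. A
peptide's intensity is added once per distinct cell its protein
memberships support; adding it once per protein membership would
double-count peptides shared by proteins that agree on taxon and COG and
would break conservation. Cells require a lineage below superkingdom and
a COG annotation.

Stability between two samples is the Pearson correlation of the two
profiles vectorized over the **union** of their cells with zero fill, on
raw intensities (no log transform — this mirrors running `cor()` directly
on the exported intensity tables; a switch is provided). Against the
baseline, each sample is compared to the inoculum replicates of its *own
subject*: stability is a within-individual question, and averaging across
donors would conflate inter-individual variability with culture drift.

Taxon-function enrichment between two sample groups tests each cell's
matched-protein count against both margins (all protein-cell memberships
in the compared samples as the population) with one-sided hypergeometric
tests; cells significant on both margins are ranked by matched-protein
count (ties: summed intensity, then lexicographic id) and the top 30
links reported. The published analyses defer the exact test to a web
platform whose internals are not printed; the hypergeometric choice is
therefore an emulation and is documented as such.

## Ecology and ordination

Bray-Curtis dissimilarity (`vegan::vegdist`), PCoA by classical scaling
(Gower double-centering, negative eigenvalues dropped, variance
proportions over positive eigenvalues only, no Lingoes/Cailliez
correction), Shannon-Wiener diversity (natural log), and PCA of COG
matrices (mean-centered, not variance-scaled, because all categories
share one intensity unit). ANOSIM is implemented in the package because
its exact small-sample behaviour matters here: all pairwise distances are
ranked with average ties and

\[ R = \frac{\bar r_{\text{between}} - \bar r_{\text{within}}}{n(n-1)/4}, \]

with a permutation p-value that enumerates *every* distinct labeling when
there are at most 1024 of them (p is then the fraction of labelings with
\(R_{\text{perm}} \ge R_{\text{obs}}\), the observed one included) and
otherwise uses 999 random permutations with the add-one estimator, which
cannot return p = 0. The R statistic is cross-checked against
`vegan::anosim` in the test suite. Because the grouping factor behind
published ANOSIM values (time versus donor) is often ambiguous, the
pipeline runs every requested grouping factor.

## PLS-DA and VIP selection

Two-class PLS-DA uses the standard NIPALS deflation scheme on autoscaled
features (zero-variance features are kept, scaled to zero) with a
centered two-level dummy response. Variable importance in projection is

\[ \mathrm{VIP}_j = \sqrt{\, p \cdot
   \frac{\sum_a \mathrm{SSY}_a \, (w_{ja}/\lVert w_a\rVert)^2}
        {\sum_a \mathrm{SSY}_a}} , \]

which satisfies \(\operatorname{mean}(\mathrm{VIP}^2) = 1\) for every
fit — the suite asserts this identity to 1e-8 and checks the scores
against mixOmics to numerical precision. Selection is strict
(`VIP > threshold`): threshold 1 for differential proteins, and for the
stringent species selection a feature must exceed 2 on every cumulative
model A = 1..3 ("VIP > 2 for all components"). Requested components
beyond the data's rank are dropped with a warning.

## In vitro-in vivo concordance

For every subject present in both arms, the change of each feature
(taxon relative abundance, or pathway share of total protein LFQ) is
`mean(post) − mean(pre)` per arm, with one in vivo change per treated
timepoint; a log2 ratio with pseudo-abundance protection accompanies it
for heat-map-style displays. Whether published "changes" are differences
or ratios is not printed; the difference of relative abundances is the
primary metric here because the compared figures are labelled as changes
in relative abundance. Concordance is summarized by the per-subject
Pearson r across features (mean ± SD per in vivo timepoint; the
transpose, per-feature across subjects, is available from the change
table) and by quadrant agreement: the percentage of rows whose two
changes share a sign among rows where both are nonzero. Group
comparisons of enzyme fractions use a two-sided Wilcoxon rank-sum test —
the natural reading of a "two-sided non-parametric t-test" — exact for
tie-free groups of at most 8, otherwise normally approximated with tie
correction; constant pooled input returns p = 1.

## The synthetic-data generator

`sim_community()` draws a taxonomy (each species in exactly one genus,
each genus in one phylum; class/order/family auto-named), log-normal
species base abundances (σ = 1.5, normalized to sum 1), per-species COG
profiles (Dirichlet, α = 0.6 over 12 categories), a protein catalog
(log-normal expression weights; ~60 % of proteins carry one or two of 12
KEGG-style pathways and an enzyme id), and a peptide map in which chosen
fractions of peptides are shared within a genus (LCA resolves to genus)
or across phyla (LCA resolves to superkingdom). Peptide ionization
efficiencies (log-normal, σ = 0.5) are drawn once and frozen.

`sim_dataset()` then simulates, per sample: species abundance = base
abundance × a frozen per-subject log-normal effect (σ = 0.3, shared
between a subject's arms so paired designs pair properly) × planted
multiplicative treatment effects; protein intensity = abundance ×
catalog weight × exp(N(0, σ²)) with σ = `noise_sigma` (default 0.2);
peptide intensity = ionization × sum of parent protein intensities;
protein LFQ = sum of member peptide intensities; finally the lowest 5 %
(`detection_quantile`) of nonzero peptide intensities per sample are set
to zero, emulating a detection limit.

One calibration is built in: after drawing weights and ionizations, each
species' weights are rescaled so that the summed response of its
species-unique peptides is identical across species. This makes "summed
peptide intensity ∝ biomass" — the working assumption of intensity-based
biomass estimation — true by construction, so the noise-free planted
abundances are exactly recoverable and the estimator's degradation under
noise can be measured in isolation. Real data violate this assumption
(protein load per cell and ionization response differ systematically
between taxa), so passing recovery tests here says the *estimator* is
correct, not that real biomass estimates are unbiased. The generator
also does not emulate chimeric/misidentified peptides, shared peptides
between more than two proteins, compositional sequencing artifacts, or
rank-intermediate taxa beyond what the two sharing fractions induce.

## Problem sizes and reproducibility

The default community (4 phyla / 10 genera / 30 species, 20 proteins per
species, 5 peptides per protein) matches the species count of a typical
filtered stool metaproteome at desk scale; the drug-response scenario in
`scripts/acceptance.R` uses 79 species to match a typical quantified
species count for that design. Tests run on deliberately small
communities (12 species) so the full suite finishes in well under a
minute; the acceptance checks (planted-effect power over 50 seeds,
VIP recovery over 20 seeds, IVIVC over 10 seeds) use the sizes stated in
their test names and complete in about half a minute. Every stochastic
step is seeded through `sim_config()` or an explicit `seed` argument,
reports embed the parameter hash and seed, and reruns are byte-identical.
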