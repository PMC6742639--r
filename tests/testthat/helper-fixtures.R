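# Small simulation configuration used across tests; overrides via ...
small_config <- function(...) {
  sim_config(n_phyla = 3, n_genera = 6, n_species = 12,
             proteins_per_species = 6, peptides_per_protein = 3, ...)
}

# Hand-built four-species toy dataset: two phyla, two genera, peptides
# covering unique / genus-shared / cross-phylum cases.
toy_lineages <- function() {
  tibble::tribble(
    ~Taxon,  ~Superkingdom, ~Phylum, ~Class, ~Order, ~Family, ~Genus, ~Species,
    "SpA1",  "Bacteria", "P1", "C1", "O1", "F1", "G1", "SpA1",
    "SpA2",  "Bacteria", "P1", "C1", "O1", "F1", "G1", "SpA2",
    "SpB1",  "Bacteria", "P2", "C2", "O2", "F2", "G2", "SpB1",
    "SpB2",  "Bacteria", "P2", "C2", "O2", "F2", "G2", "SpB2")
}

toy_dataset <- function() {
  proteins <- tibble::tribble(
    ~ProteinGroup, ~Species, ~COG, ~KEGG_Pathway,       ~Enzyme,
    "PG_1",        "SpA1",   "C",  "ko00010",           "EC:1.1",
    "PG_2",        "SpA2",   "C",  "",                  "",
    "PG_3",        "SpB1",   "G",  "ko00010;ko00020",   "EC:1.2",
    "PG_4",        "SpB2",   "K",  "ko00020",           "EC:1.3")
  pep <- tibble::tribble(
    ~Peptide, ~ProteinGroups, ~`Intensity.S1`, ~`Intensity.S2`,
    "p1",     "PG_1",         10,  20,
    "p2",     "PG_1;PG_2",    6,   6,    # genus-shared within G1
    "p3",     "PG_1;PG_3",    4,   4,    # shared across phyla
    "p4",     "PG_3",         8,   2,
    "p5",     "PG_4",         3,   9,
    "p6",     "PG_2",         5,   5)
  lfq <- tibble::tibble(
    `LFQ.S1` = c(20, 11, 12, 3),
    `LFQ.S2` = c(30, 11, 6, 9))
  metadata <- tibble::tibble(
    Sample = c("S1", "S2"), Subject = "V1", Timepoint = c(0, 24),
    Arm = "in_vitro", Condition = c("baseline", "MiPro"), Replicate = 1)
  mipro_dataset(dplyr::bind_cols(pep),
                dplyr::bind_cols(proteins, lfq),
                toy_lineages(), metadata)
}

# Random truncated lineages drawn from a synthetic taxonomy, for LCA
# property tests.
random_lineages <- function(n, taxonomy, max_set = 4) {
  lapply(seq_len(n), function(i) {
    rows <- taxonomy[sample(nrow(taxonomy), sample(max_set, 1),
                            replace = TRUE), ]
    depth <- sample(7, nrow(rows), replace = TRUE)
    m <- as.matrix(rows[, TAXONOMIC_RANKS])
    for (k in seq_len(nrow(m))) if (depth[k] < 7) m[k, (depth[k] + 1):7] <- ""
    tibble::as_tibble(m)
  })
}

# Rank-by-rank intersection oracle for the LCA, independent of the
# package implementation: intersect the observed name sets one rank at a
# time and stop at the first rank that is ambiguous or unresolved.
lca_oracle <- function(lineages) {
  out <- stats::setNames(rep("", 7), TAXONOMIC_RANKS)
  for (r in seq_len(7)) {
    vals <- lineages[[TAXONOMIC_RANKS[r]]]
    vals[is.na(vals)] <- ""
    if (length(unique(vals)) > 1 || any(vals == "")) break
    out[r] <- vals[1]
  }
  out
}
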