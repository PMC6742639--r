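test_that("LCA resolves toy lineage sets as constructed", {
  lin <- toy_lineages()
  # singleton identity
  expect_identical(unname(lca_lineage(lin[1, ])),
                   unname(unlist(lin[1, TAXONOMIC_RANKS])))
  # two congeners resolve through the genus, species left empty
  two <- lca_lineage(lin[lin$Genus == "G2", ])
  expect_identical(two[["Genus"]], "G2")
  expect_identical(two[["Species"]], "")
  # cross-phylum set resolves to the superkingdom only
  cross <- lca_lineage(lin[c(1, 3), ])
  expect_identical(unname(cross),
                   c("Bacteria", "", "", "", "", "", ""))
  expect_error(lca_lineage(lin[0, ]), "empty")
})

test_that("LCA agrees with the rank-by-rank intersection oracle", {
  taxonomy <- sim_community(small_config(seed = 31))$taxonomy
  set.seed(99)
  sets <- random_lineages(1000, taxonomy)
  agree <- vapply(sets, function(s)
    identical(lca_lineage(s), lca_oracle(s)), logical(1))
  expect_true(all(agree))
})

test_that("LCA is idempotent, order-invariant and monotone", {
  taxonomy <- sim_community(small_config(seed = 32))$taxonomy
  set.seed(7)
  for (s in random_lineages(50, taxonomy)) {
    l <- lca_lineage(s)
    expect_identical(lca_lineage(tibble::as_tibble(t(l))), l)
    expect_identical(lca_lineage(s[rev(seq_len(nrow(s))), ]), l)
    # adding one more lineage can only shorten the resolved prefix
    extra <- taxonomy[sample(nrow(taxonomy), 1), TAXONOMIC_RANKS]
    l2 <- lca_lineage(dplyr::bind_rows(s, extra))
    expect_lte(sum(l2 != ""), sum(l != ""))
  }
})

test_that("peptide assignment follows protein membership and LCA", {
  ds <- toy_dataset()
  ass <- assign_peptide_taxonomy(ds)
  ass <- ass[match(c("p1", "p2", "p3"), ass$Peptide), ]
  expect_identical(ass$Taxon, c("SpA1", "G1", "Bacteria"))
  expect_identical(ass$Depth, c(7L, 6L, 1L))
})

test_that("a precomputed Lineage column is used verbatim", {
  ds <- toy_dataset()
  ds$peptides$Lineage <- c("Bacteria;P9;C9;O9;F9;G9;S9", "Bacteria;P9",
                           "", "Bacteria", "Bacteria;P1;C1;O1;F1",
                           "Bacteria;P2")
  ass <- assign_peptide_taxonomy(ds)
  expect_identical(ass$Taxon[1], "S9")
  expect_identical(ass$Depth, c(7L, 2L, 0L, 1L, 5L, 2L))
})

test_that("assignment depth matches the planted peptide degeneracy", {
  cfg <- sim_config(n_phyla = 4, n_genera = 12, n_species = 50,
                    proteins_per_species = 8, peptides_per_protein = 3,
                    frac_peptides_shared_within_genus = 0.2,
                    frac_peptides_shared_across_phyla = 0, seed = 33)
  sim <- sim_dataset(sim_community(cfg),
                     design_stability(n_subjects = 1, timepoints = c(0, 9),
                                      n_replicates = 1))
  ass <- assign_peptide_taxonomy(sim$dataset)
  frac_above_species <- mean(ass$Depth < 7)
  expect_lt(abs(frac_above_species - 0.2), 0.05)
})

test_that("biomass matrix applies the distinct-peptide filter and normalizes", {
  ds <- toy_dataset()
  # SpA1: p1 unique (1 distinct species-level peptide); SpB1: p4; SpB2: p5
  ass <- assign_peptide_taxonomy(ds)
  bm2 <- biomass_matrix(ds, ass, "Species", min_distinct_peptides = 2,
                        normalize = FALSE)
  expect_identical(nrow(bm2), 0L)  # no species has 2 distinct peptides
  bm1 <- biomass_matrix(ds, ass, "Species", min_distinct_peptides = 1,
                        normalize = FALSE)
  expect_setequal(bm1$Taxon, c("SpA1", "SpA2", "SpB1", "SpB2"))
  norm <- biomass_matrix(ds, ass, "Species", min_distinct_peptides = 1,
                         normalize = TRUE)
  expect_equal(colSums(as.matrix(norm[, -1])), c(Intensity.S1 = 1,
                                                 Intensity.S2 = 1) |>
                 setNames(c("S1", "S2")), tolerance = 1e-9)
  expect_error(biomass_matrix(ds, ass, "Strain"), "rank")
})

test_that("intensity is conserved between taxa and the unassigned bucket", {
  sim <- sim_dataset(sim_community(small_config(seed = 34)),
                     design_stability(n_subjects = 1,
                                      timepoints = c(0, 24),
                                      n_replicates = 2))
  pep <- sim$dataset$peptides
  icols <- grep("^Intensity\\.", names(pep), value = TRUE)
  totals <- colSums(as.matrix(pep[, icols]))
  names(totals) <- sub("^Intensity\\.", "", names(totals))
  for (rank in c("Species", "Genus", "Phylum")) {
    bm <- biomass_matrix(sim$dataset, rank = rank,
                         min_distinct_peptides = 3, normalize = FALSE)
    got <- colSums(as.matrix(bm[, -1])) + attr(bm, "unassigned")
    expect_equal(got, totals[names(got)], tolerance = 1e-9)
  }
})

test_that("rank aggregation is consistent when peptides are unambiguous", {
  cfg <- small_config(frac_peptides_shared_within_genus = 0,
                      frac_peptides_shared_across_phyla = 0, seed = 35)
  sim <- sim_dataset(sim_community(cfg),
                     design_stability(n_subjects = 1, timepoints = c(0, 9),
                                      n_replicates = 1))
  sp <- biomass_matrix(sim$dataset, rank = "Species",
                       min_distinct_peptides = 1, normalize = FALSE)
  ph <- biomass_matrix(sim$dataset, rank = "Phylum",
                       min_distinct_peptides = 1, normalize = FALSE)
  lin <- sim$dataset$lineages
  agg <- rowsum(as.matrix(sp[, -1]),
                lin$Phylum[match(sp$Taxon, lin$Taxon)])
  phm <- as.matrix(ph[, -1])
  rownames(phm) <- ph$Taxon
  expect_equal(agg[rownames(phm), , drop = FALSE], phm,
               tolerance = 1e-12)
})

test_that("noise-free estimates equal planted relative abundances", {
  cfg <- small_config(noise_sigma = 0, detection_quantile = 0, seed = 36)
  sim <- sim_dataset(sim_community(cfg),
                     design_stability(n_subjects = 1, timepoints = c(0, 9),
                                      n_replicates = 1))
  bm <- biomass_matrix(sim$dataset, rank = "Species", normalize = TRUE)
  s <- names(bm)[2]
  est <- setNames(bm[[s]], bm$Taxon)
  tr <- sim$truth[sim$truth$Sample == s, ]
  truth <- setNames(tr$true_relative_abundance, tr$Species)[names(est)]
  truth <- truth / sum(truth)
  expect_equal(est, truth, tolerance = 1e-9)
})

test_that("relative change follows (post - pre) / pre", {
  expect_equal(relative_change(1, 1), 0)
  expect_equal(relative_change(2, 3), 0.5)
  expect_equal(relative_change(0.2, 0.88), 3.4)
  expect_equal(relative_change(c(1, 2), c(2, 1)), c(1, -0.5))
  expect_error(relative_change(0, 1), "pseudo-abundance",
               class = "mipror_domain_error")
})
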