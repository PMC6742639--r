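test_that("profile cells follow peptide LCA nodes and protein COGs", {
  ds <- toy_dataset()
  prof <- build_taxfunc_profile(ds)
  s1 <- prof[prof$Sample == "S1", ]
  # p1 (10) unique to SpA1 via PG_1 (COG C): cell (SpA1, C)
  cell <- s1[s1$Taxon == "SpA1" & s1$COG == "C", ]
  expect_equal(cell$intensity, 10)
  expect_equal(cell$protein_count, 1L)
  # p2 shared by two G1 congeners lands on the genus node, once
  g1 <- s1[s1$Taxon == "G1", ]
  expect_equal(g1$intensity, 6)
  expect_equal(g1$protein_count, 2L)
  # p3 resolves to superkingdom only and is excluded
  expect_false("Bacteria" %in% prof$Taxon)
})

test_that("profiles conserve intensity under full annotation", {
  cfg <- small_config(frac_peptides_shared_within_genus = 0,
                      frac_peptides_shared_across_phyla = 0, seed = 51)
  sim <- sim_dataset(sim_community(cfg),
                     design_stability(n_subjects = 1,
                                      timepoints = c(0, 24),
                                      n_replicates = 2))
  prof <- build_taxfunc_profile(sim$dataset)
  pep <- sim$dataset$peptides
  icols <- grep("^Intensity\\.", names(pep), value = TRUE)
  totals <- colSums(as.matrix(pep[, icols]))
  names(totals) <- sub("^Intensity\\.", "", names(totals))
  by_sample <- tapply(prof$intensity, prof$Sample, sum)
  expect_equal(as.numeric(by_sample[names(totals)]),
               as.numeric(totals), tolerance = 1e-9)
  # with degenerate peptides, cross-phylum mass resolves to the root and
  # is excluded, while a peptide whose parents disagree on COG can land in
  # one cell per distinct parent COG: the total is bounded by the sum of
  # peptide intensity times the number of distinct parent COGs
  sim2 <- sim_dataset(sim_community(small_config(seed = 52)),
                      design_stability(n_subjects = 1,
                                       timepoints = c(0, 9),
                                       n_replicates = 1))
  ds2 <- sim2$dataset
  prof2 <- build_taxfunc_profile(ds2)
  pep2 <- ds2$peptides
  n_cogs <- vapply(strsplit(pep2$ProteinGroups, ";"), function(pgs)
    dplyr::n_distinct(ds2$proteins$COG[match(pgs,
                                             ds2$proteins$ProteinGroup)]),
    integer(1))
  bound <- sum(rowSums(as.matrix(
    pep2[, grep("^Intensity\\.", names(pep2))])) * n_cogs)
  expect_lte(sum(prof2$intensity), bound + 1e-6)
})

test_that("profile correlation behaves like Pearson on union cells", {
  ds <- toy_dataset()
  prof <- build_taxfunc_profile(ds)
  s1 <- prof[prof$Sample == "S1", ]
  s2 <- s1
  # identity and scale invariance
  expect_equal(taxfunc_correlation(s1, s1), 1.0)
  s2$intensity <- s2$intensity * 2
  expect_equal(taxfunc_correlation(s1, s2), 1.0)
  # hand-built reversed vectors give exactly -1
  pa <- tibble::tibble(Sample = "a", Taxon = paste0("t", 1:4),
                       Rank = "Species", COG = "C",
                       intensity = c(1, 2, 3, 4), protein_count = 1L)
  pb <- pa
  pb$intensity <- c(4, 3, 2, 1)
  expect_equal(taxfunc_correlation(pa, pb), -1.0)
  expect_warning(r <- taxfunc_correlation(pa[1:2, ], pb[1:2, ]),
                 "fewer than 3")
  expect_true(is.na(r))
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  sim <- sim_dataset(sim_community(small_config(seed = 53)),
                     design_stability(n_subjects = 1,
                                      timepoints = c(0, 24),
                                      n_replicates = 2))
  prof <- build_taxfunc_profile(sim$dataset)
  meta <- sim$dataset$metadata
  bl <- meta$Sample[meta$Timepoint == 0]
  tc <- taxfunc_cor_matrix(prof, bl, meta)
  R <- tc$matrix
  expect_equal(R, t(R), tolerance = 1e-12)
  expect_equal(unname(diag(R)), rep(1, nrow(R)), tolerance = 1e-12)
  expect_error(taxfunc_cor_matrix(prof, "no_such_sample"),
               "no_such_sample", class = "mipror_domain_error")
})

test_that("noise-free replicates have identical profiles and r = 1", {
  cfg <- small_config(noise_sigma = 0, detection_quantile = 0, seed = 54)
  sim <- sim_dataset(sim_community(cfg),
                     design_stability(n_subjects = 1,
                                      timepoints = c(0, 24),
                                      n_replicates = 2))
  prof <- build_taxfunc_profile(sim$dataset)
  meta <- sim$dataset$metadata
  split_prof <- split(prof[, c("Taxon", "COG", "intensity")], prof$Sample)
  expect_equal(split_prof[[meta$Sample[1]]], split_prof[[meta$Sample[2]]],
               ignore_attr = TRUE)
  tc <- taxfunc_cor_matrix(prof, meta$Sample[meta$Timepoint == 0], meta)
  expect_equal(tc$baseline_r$r, rep(1, nrow(tc$baseline_r)),
               tolerance = 1e-12)
})

test_that("stability r declines as measurement noise grows", {
  r_at <- function(noise) {
    cfg <- small_config(noise_sigma = noise, seed = 55)
    sim <- sim_dataset(sim_community(cfg),
                       design_stability(n_subjects = 1,
                                        timepoints = c(0, 24),
                                        n_replicates = 3))
    meta <- sim$dataset$metadata
    prof <- build_taxfunc_profile(sim$dataset)
    tc <- taxfunc_cor_matrix(prof, meta$Sample[meta$Timepoint == 0], meta)
    mean(tc$baseline_r$r)
  }
  rs <- vapply(c(0, 0.2, 0.5, 1.0), r_at, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_gte(rs[2], 0.95)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # population of 20 protein memberships: 10 proteins of taxon T all carry
  # COG Q and co-occur; the other 10 are spread over other taxa/functions
  mem <- dplyr::bind_rows(
    tibble::tibble(Sample = "x", ProteinGroup = sprintf("PG_%02d", 1:10),
                   Taxon = "T", COG = "Q"),
    tibble::tibble(Sample = "x", ProteinGroup = sprintf("PG_%02d", 11:20),
                   Taxon = sprintf("U%d", 1:10),
                   COG = rep(c("R", "S"), 5)))
  prof <- dplyr::bind_rows(
    tibble::tibble(Sample = c("x", "y"), Taxon = "T", Rank = "Species",
                   COG = "Q", intensity = c(100, 90), protein_count = 10L),
    tibble::tibble(Sample = c("x", "y"), Taxon = "U1", Rank = "Species",
                   COG = "R", intensity = c(5, 6), protein_count = 1L))
  mem <- dplyr::bind_rows(mem, tibble::tibble(
    Sample = "y", ProteinGroup = sprintf("PG_%02d", 1:10), Taxon = "T",
    COG = "Q"))
  attr(prof, "memberships") <- mem
  res <- taxfunc_enrichment(prof, "x", "y", p_threshold = 1, top_n = 10)
  tq <- res[res$Taxon == "T" & res$COG == "Q", ]
  # exact enumeration: draw 10 of 20, all 10 successes
  p_exact <- sum(vapply(10:10, function(k)
    choose(10, k) * choose(10, 10 - k), numeric(1))) / choose(20, 10)
  expect_equal(tq$p_taxon, p_exact, tolerance = 1e-12)
  expect_equal(tq$p_function, p_exact, tolerance = 1e-12)
  expect_equal(tq$n_proteins, 10L)
})

test_that("enrichment ranking returns at most top_n qualifying links", {
  sim <- sim_dataset(sim_community(small_config(seed = 56)),
                     design_stability(n_subjects = 1,
                                      timepoints = c(0, 24),
                                      n_replicates = 3))
  meta <- sim$dataset$metadata
  prof <- build_taxfunc_profile(sim$dataset)
  pre <- meta$Sample[meta$Timepoint == 0]
  post <- meta$Sample[meta$Timepoint == 24]
  full <- taxfunc_enrichment(prof, pre, post, p_threshold = 0.05,
                             top_n = Inf)
  top <- taxfunc_enrichment(prof, pre, post, p_threshold = 0.05,
                            top_n = 10)
  expect_identical(nrow(top), min(10L, nrow(full)))
  expect_true(all(diff(top$n_proteins) <= 0))
  # asking for more than exist returns everything
  expect_identical(nrow(taxfunc_enrichment(prof, pre, post, top_n = 1e6)),
                   nrow(full))
})
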