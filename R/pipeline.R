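write_tsv_quiet <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "", progress = FALSE)
  path
}

report_manifest <- function(params, seed) {
  list(package_version = as.character(utils::packageVersion("mipror")),
       seed = seed, params = params,
       params_hash = rlang::hash(params))
}

#' Run the culture-stability analysis end to end
#'
#' Orchestrates the full stability workflow on a dataset: peptide taxonomy
#' assignment, species- and phylum-level biomass matrices, COG rollup
#' after a Q25 presence filter, taxon-function coupled profiles and their
#' correlation against the baseline (inoculum) samples, Bray-Curtis
#' dissimilarity with PCoA and ANOSIM (one run per grouping factor within
#' each condition, so both time- and subject-based groupings are
#' available), Shannon diversity, and PCA on the COG matrix. Fully
#' reproducible from the dataset plus seed.
#'
#' @param dataset A [mipro_dataset()].
#' @param baseline_timepoint Timepoint of the inoculum samples (default 0).
#' @param q_filter Presence threshold for the COG analysis (default 0.25,
#'   the Q25 rule).
#' @param min_distinct_peptides Distinct-peptide filter for biomass
#'   matrices (default 3).
#' @param anosim_by Metadata columns to use, in turn, as the ANOSIM
#'   grouping factor (default Timepoint and Subject).
#' @param n_permutations,seed ANOSIM permutation settings.
#' @param out_dir Optional directory; when given, all report tables are
#'   written as TSV/JSON with a run manifest.
#' @return A list of class `stability_report`.
#' @export
run_stability <- function(dataset, baseline_timepoint = 0,
                          q_filter = 0.25, min_distinct_peptides = 3,
                          anosim_by = c("Timepoint", "Subject"),
                          n_permutations = 999, seed = 1L,
                          out_dir = NULL) {
  stopifnot(inherits(dataset, "mipro_dataset"))
  meta <- dataset$metadata
  baseline_samples <- meta$Sample[meta$Timepoint == baseline_timepoint]
  if (length(baseline_samples) == 0)
    abort(sprintf("no sample at baseline timepoint %s",
                  format(baseline_timepoint)),
          class = "mipror_domain_error")

  assignments <- assign_peptide_taxonomy(dataset)
  species <- biomass_matrix(dataset, assignments, "Species",
                            min_distinct_peptides, normalize = TRUE)
  phylum <- biomass_matrix(dataset, assignments, "Phylum",
                           min_distinct_peptides, normalize = TRUE)
  cog <- cog_rollup(presence_filter(dataset$proteins,
                                    min_fraction = q_filter))
  profiles <- build_taxfunc_profile(dataset, assignments)
  taxfunc <- taxfunc_cor_matrix(profiles, baseline_samples, meta)

  d <- bray_curtis(species)
  ordination <- pcoa_ord(d)
  pca <- pca_functions(cog)
  shannon <- shannon_index(species)

  conditions <- setdiff(unique(meta$Condition), "baseline")
  anosim <- list()
  for (cond in conditions) {
    sel <- meta$Sample[meta$Condition %in% c("baseline", cond)]
    dm <- stats::as.dist(as.matrix(d)[sel, sel])
    for (fac in anosim_by) {
      labels <- meta[[fac]][match(sel, meta$Sample)]
      sizes <- table(labels)
      if (length(sizes) < 2 || any(sizes < 2)) next
      res <- anosim_test(dm, labels, n_permutations = n_permutations,
                         seed = seed)
      anosim[[paste(cond, fac, sep = ".")]] <-
        tibble(Condition = cond, grouping = fac, R = res$R, p = res$p,
               method = res$method)
    }
  }
  anosim <- bind_rows(anosim)

  report <- structure(
    list(assignments = assignments, species = species, phylum = phylum,
         cog = cog, profiles = profiles, taxfunc = taxfunc,
         bray_curtis = d, pcoa = ordination, pca = pca,
         shannon = shannon, anosim = anosim,
         manifest = report_manifest(
           list(baseline_timepoint = baseline_timepoint,
                q_filter = q_filter,
                min_distinct_peptides = min_distinct_peptides,
                anosim_by = anosim_by,
                n_permutations = n_permutations), seed)),
    class = "stability_report")
  if (!is.null(out_dir)) write_stability_report(report, out_dir)
  report
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  cat(sprintf("  mean taxon-function r vs baseline: %.3f\n",
              mean(x$taxfunc$baseline_r$r, na.rm = TRUE)))
  if (nrow(x$anosim) > 0) {
    cat("  ANOSIM:\n")
    print(x$anosim)
  }
  invisible(x)
}

#' Write a stability report to a directory
#' @param report A [run_stability()] result.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the directory path.
#' @export
write_stability_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)
  write_tsv_quiet(report$species, f("species_abundance.tsv"))
  write_tsv_quiet(attr(report$species, "peptide_counts"),
                  f("species_peptide_counts.tsv"))
  write_tsv_quiet(report$phylum, f("phylum_abundance.tsv"))
  write_tsv_quiet(report$cog, f("cog_abundance.tsv"))
  write_tsv_quiet(as_tibble(report$profiles), f("taxfunc_profile.tsv"))
  write_tsv_quiet(report$taxfunc$baseline_r, f("taxfunc_baseline_r.tsv"))
  if (!is.null(report$taxfunc$baseline_summary))
    write_tsv_quiet(report$taxfunc$baseline_summary,
                    f("taxfunc_baseline_summary.tsv"))
  write_tsv_quiet(matrix_to_tbl(as.matrix(report$bray_curtis), "Sample"),
                  f("bray_curtis.tsv"))
  write_tsv_quiet(report$pcoa$points, f("pcoa_coordinates.tsv"))
  write_tsv_quiet(report$pca$points, f("pca_coordinates.tsv"))
  write_tsv_quiet(report$shannon, f("shannon.tsv"))
  if (nrow(report$anosim) > 0)
    jsonlite::write_json(report$anosim, f("anosim.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  jsonlite::write_json(report$manifest, f("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the drug-response / IVIVC analysis end to end
#'
#' Orchestrates the paired-arm workflow: a Q50 presence filter within
#' every compared subgroup of each arm, protein-level PLS-DA with VIP
#' scoring per comparison (in vitro treated vs untreated; in vivo treated
#' at each timepoint vs untreated), selection of differential proteins
#' (VIP > `vip_protein_threshold`), a pathway rollup restricted to the
#' pathways those proteins carry, species-level PLS-DA with the stringent
#' all-components VIP rule, in vitro/in vivo change tables and
#' concordance at phylum, genus and species rank and at pathway level,
#' and within-pathway enzyme fractions compared between treated and
#' untreated samples by a two-sided rank-sum test.
#'
#' @param dataset_invitro,dataset_invivo [mipro_dataset()] objects.
#' @param q_filter Per-subgroup presence threshold (default 0.5, Q50).
#' @param vip_protein_threshold VIP cutoff for differential proteins
#'   (default 1).
#' @param vip_species_threshold All-components VIP cutoff for species
#'   (default 2).
#' @param n_components PLS components (default 3).
#' @param enzyme_pathway Pathway whose enzyme balance to analyze (default
#'   `"ko00010"`, glycolysis/gluconeogenesis).
#' @param pre_label,post_label Condition labels for untreated/treated.
#' @param out_dir Optional output directory for report artifacts.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A list of class `drug_response_report`.
#' @export
run_drug_response <- function(dataset_invitro, dataset_invivo,
                              q_filter = 0.5, vip_protein_threshold = 1,
                              vip_species_threshold = 2, n_components = 3,
                              enzyme_pathway = "ko00010",
                              pre_label = "untreated",
                              post_label = "treated",
                              out_dir = NULL, seed = 1L) {
  arms <- list(in_vitro = dataset_invitro, in_vivo = dataset_invivo)
  for (a in names(arms)) {
    meta <- arms[[a]]$metadata
    bad <- setdiff(c(pre_label, post_label), meta$Condition)
    if (length(bad) > 0)
      abort(paste0("arm ", a, " has no sample with condition ",
                   paste(bad, collapse = ", ")),
            class = "mipror_domain_error")
  }

  comparisons <- list()
  vitro_meta <- dataset_invitro$metadata
  comparisons[["in_vitro"]] <-
    list(dataset = dataset_invitro,
         samples = vitro_meta$Sample[vitro_meta$Condition %in%
                                       c(pre_label, post_label)])
  vivo_meta <- dataset_invivo$metadata
  for (tp in sort(unique(vivo_meta$Timepoint[vivo_meta$Condition ==
                                               post_label]))) {
    sel <- vivo_meta$Condition == pre_label |
      (vivo_meta$Condition == post_label & vivo_meta$Timepoint == tp)
    comparisons[[sprintf("in_vivo_t%g", tp)]] <-
      list(dataset = dataset_invivo, samples = vivo_meta$Sample[sel])
  }

  protein_vip <- list()
  selected <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    meta <- cmp$dataset$metadata
    labels <- meta$Condition[match(cmp$samples, meta$Sample)]
    grouping <- split(cmp$samples, labels)
    filtered <- presence_filter(
      select(cmp$dataset$proteins, "ProteinGroup", "COG", "KEGG_Pathway",
             "Enzyme", all_of(paste0("LFQ.", cmp$samples))),
      min_fraction = q_filter, grouping = grouping)
    lfq <- intensity_matrix(filtered, "ProteinGroup", "LFQ")
    fit <- plsda_vip(lfq, labels, n_components = n_components)
    protein_vip[[nm]] <- fit
    selected[[nm]] <- select_features(fit, vip_protein_threshold)
  }
  selected_proteins <- sort(unique(unlist(selected)))

  pw_of_selected <- sort(unique(unlist(split_pathways(
    bind_rows(dataset_invitro$proteins, dataset_invivo$proteins) |>
      filter(.data$ProteinGroup %in% selected_proteins) |>
      pull("KEGG_Pathway")))))
  pw_of_selected <- setdiff(pw_of_selected, "")

  changes <- list()
  ivivc <- list()
  for (lv in c("Phylum", "Genus", "Species")) {
    ch <- ivivc_changes(dataset_invitro, dataset_invivo, level = lv,
                        pre_label = pre_label, post_label = post_label)
    changes[[lv]] <- ch
    ivivc[[lv]] <- ivivc_correlation(ch)
  }
  if (length(pw_of_selected) > 0) {
    ch <- ivivc_changes(dataset_invitro, dataset_invivo,
                        level = pw_of_selected, pre_label = pre_label,
                        post_label = post_label)
    changes[["pathway"]] <- ch
    ivivc[["pathway"]] <- ivivc_correlation(ch)
  }

  species_vip <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    meta <- cmp$dataset$metadata
    sub <- cmp$dataset
    keep <- c("Peptide", "ProteinGroups",
              intersect("Lineage", names(sub$peptides)),
              paste0("Intensity.", cmp$samples))
    sub <- mipro_dataset(sub$peptides[, keep],
                         select(sub$proteins, -all_of(
                           setdiff(sample_columns(sub$proteins, "LFQ"),
                                   paste0("LFQ.", cmp$samples)))),
                         sub$lineages,
                         filter(meta, .data$Sample %in% cmp$samples))
    sp <- biomass_matrix(sub, rank = "Species", normalize = TRUE)
    labels <- sub$metadata$Condition[match(colnames(tbl_to_matrix(sp)),
                                           sub$metadata$Sample)]
    species_vip[[nm]] <- plsda_vip(sp, labels,
                                   n_components = n_components)
  }
  species_hits <- lapply(species_vip, select_features,
                         threshold = vip_species_threshold,
                         all_components = TRUE)

  enzymes <- list()
  for (a in names(arms)) {
    ds <- arms[[a]]
    ef <- tryCatch(enzyme_fraction(ds$proteins, enzyme_pathway),
                   error = function(e) NULL)
    if (is.null(ef)) next
    m <- tbl_to_matrix(ef)
    meta <- ds$metadata
    pre_s <- intersect(colnames(m), meta$Sample[meta$Condition == pre_label])
    post_s <- intersect(colnames(m),
                        meta$Sample[meta$Condition == post_label])
    if (length(pre_s) < 3 || length(post_s) < 3) next
    enzymes[[a]] <- tibble(
      arm = a, enzyme = rownames(m),
      mean_untreated = rowMeans(m[, pre_s, drop = FALSE], na.rm = TRUE),
      mean_treated = rowMeans(m[, post_s, drop = FALSE], na.rm = TRUE),
      p = apply(m, 1, function(v)
        group_compare(v[pre_s][!is.na(v[pre_s])],
                      v[post_s][!is.na(v[post_s])])))
  }
  enzymes <- bind_rows(enzymes)

  report <- structure(
    list(protein_vip = protein_vip, selected_proteins = selected_proteins,
         selected_pathways = pw_of_selected, species_vip = species_vip,
         species_hits = species_hits, changes = changes, ivivc = ivivc,
         enzymes = enzymes,
         manifest = report_manifest(
           list(q_filter = q_filter,
                vip_protein_threshold = vip_protein_threshold,
                vip_species_threshold = vip_species_threshold,
                n_components = n_components,
                enzyme_pathway = enzyme_pathway), seed)),
    class = "drug_response_report")
  if (!is.null(out_dir)) write_drug_response_report(report, out_dir)
  report
}

#' @export
print.drug_response_report <- function(x, ...) {
  cat("<drug_response_report>\n")
  cat(sprintf("  %d differential proteins (VIP threshold), %d pathways\n",
              length(x$selected_proteins), length(x$selected_pathways)))
  for (lv in names(x$ivivc))
    cat(sprintf("  %s: mean per-subject r = %.3f, quadrant agreement %.1f%%\n",
                lv, mean(x$ivivc[[lv]]$per_subject$r, na.rm = TRUE),
                x$ivivc[[lv]]$quadrant_agreement_pct))
  invisible(x)
}

#' Write a drug-response report to a directory
#' @param report A [run_drug_response()] result.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the directory path.
#' @export
write_drug_response_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)
  for (nm in names(report$protein_vip))
    write_tsv_quiet(report$protein_vip[[nm]]$vip,
                    f(sprintf("protein_vip_%s.tsv", nm)))
  for (nm in names(report$species_vip))
    write_tsv_quiet(report$species_vip[[nm]]$vip,
                    f(sprintf("species_vip_%s.tsv", nm)))
  for (lv in names(report$changes))
    write_tsv_quiet(as_tibble(report$changes[[lv]]),
                    f(sprintf("changes_%s.tsv", lv)))
  ivivc_json <- lapply(report$ivivc, function(x)
    list(per_subject = x$per_subject, summary = x$summary,
         quadrant_agreement_pct = x$quadrant_agreement_pct))
  jsonlite::write_json(ivivc_json, f("ivivc.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  if (nrow(report$enzymes) > 0)
    write_tsv_quiet(report$enzymes, f("enzyme_fractions.tsv"))
  jsonlite::write_json(report$manifest, f("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
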