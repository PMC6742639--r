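#' Build per-sample taxon-function coupled profiles
#'
#' Creates the three-dimensional sample-taxon-function dataset behind the
#' stability statistic. For every peptide whose assigned lineage is
#' resolved below superkingdom, and every protein group containing it that
#' carries a COG category, the peptide's intensity in a sample is added to
#' the cell (deepest resolved node of the peptide's lineage, COG
#' category). Peptide intensities — not protein LFQ values — populate
#' cells, keyed by the peptide's own LCA node, so a protein group is never
#' attributed to taxa its peptides do not support. A peptide's intensity
#' is added once per distinct cell its protein memberships support (a
#' peptide shared by two proteins with the same COG and LCA node counts
#' once), which conserves total intensity: when every peptide resolves
#' below superkingdom, every protein carries a COG and peptide parents
#' agree on it, the profile total equals the sample's total peptide
#' intensity. A cell's matched-protein count is the number of distinct
#' protein groups contributing to it in that sample.
#'
#' @param dataset A [mipro_dataset()].
#' @param assignments Peptide assignments from [assign_peptide_taxonomy()];
#'   computed on the fly when `NULL`.
#' @return A long tibble of class `taxfunc_profile`: `Sample`, `Taxon`,
#'   `Rank`, `COG`, `intensity`, `protein_count`, one row per nonzero cell
#'   per sample. Attribute `memberships` records the distinct
#'   (Sample, ProteinGroup, Taxon, COG) contributions used by
#'   [taxfunc_enrichment()].
#' @export
build_taxfunc_profile <- function(dataset, assignments = NULL) {
  stopifnot(inherits(dataset, "mipro_dataset"))
  if (is.null(assignments)) assignments <- assign_peptide_taxonomy(dataset)

  ass <- assignments |>
    filter(.data$Depth >= 2) |>
    mutate(Rank = TAXONOMIC_RANKS[.data$Depth]) |>
    select("Peptide", "Taxon", "Rank")

  pep <- dataset$peptides |>
    semi_join(ass, by = "Peptide")
  long <- tibble(Peptide = pep$Peptide,
                 ProteinGroup = strsplit(pep$ProteinGroups, ";",
                                         fixed = TRUE)) |>
    tidyr::unnest("ProteinGroup") |>
    left_join(dataset$proteins |> select("ProteinGroup", "COG"),
              by = "ProteinGroup") |>
    filter(!is.na(.data$COG) & .data$COG != "") |>
    inner_join(ass, by = "Peptide")

  inten <- intensity_matrix(dataset$peptides, "Peptide", "Intensity")
  cells <- long |>
    bind_cols(as_tibble(inten[long$Peptide, , drop = FALSE])) |>
    tidyr::pivot_longer(all_of(colnames(inten)), names_to = "Sample",
                        values_to = "intensity") |>
    filter(.data$intensity > 0)

  profile <- cells |>
    group_by(.data$Sample, .data$Taxon, .data$Rank, .data$COG) |>
    summarise(intensity = sum(.data$intensity[!duplicated(.data$Peptide)]),
              protein_count = n_distinct(.data$ProteinGroup),
              .groups = "drop") |>
    arrange(.data$Sample, .data$Taxon, .data$COG)

  memberships <- cells |>
    distinct(.data$Sample, .data$ProteinGroup, .data$Taxon, .data$COG)

  structure(profile, class = c("taxfunc_profile", class(profile)),
            memberships = memberships)
}

profile_cells <- function(profile) {
  paste(profile$Taxon, profile$COG, sep = "\r")
}

#' Pearson correlation of two taxon-function coupled profiles
#'
#' Both profiles are vectorized over the union of their (taxon, COG) cells
#' with zero fill, and the Pearson product-moment correlation of the two
#' raw intensity vectors is returned. Degenerate inputs (fewer than three
#' union cells, or zero variance) yield `NA` with a warning.
#'
#' @param profile_a,profile_b Single-sample slices of a
#'   [build_taxfunc_profile()] tibble (columns `Taxon`, `COG`,
#'   `intensity`).
#' @return Pearson r in \[-1, 1\], or `NA` for degenerate input.
#' @export
taxfunc_correlation <- function(profile_a, profile_b) {
  keys <- union(profile_cells(profile_a), profile_cells(profile_b))
  if (length(keys) < 3) {
    warn("fewer than 3 taxon-function cells in the union; correlation undefined")
    return(NA_real_)
  }
  a <- setNames(rep(0, length(keys)), keys)
  b <- a
  a[profile_cells(profile_a)] <- profile_a$intensity
  b[profile_cells(profile_b)] <- profile_b$intensity
  if (sd(a) == 0 || sd(b) == 0) {
    warn("degenerate (zero-variance) taxon-function profile; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Pairwise taxon-function correlation matrix and baseline stability
#'
#' Computes the Pearson correlation of the taxon-function coupled profile
#' between every pair of samples (each pair vectorized over the union of
#' its cells with zero fill), then summarizes the correlation of every
#' sample against the baseline (inoculum) samples: per sample, the mean r
#' over baseline replicates (of the same subject, when the metadata
#' carries a `Subject` column — stability is a within-individual
#' question); per timepoint/condition group, mean and SD across samples.
#'
#' @param profiles A [build_taxfunc_profile()] tibble covering all samples.
#' @param baseline_samples Character vector of baseline sample ids (the
#'   0 h inoculum replicates).
#' @param metadata Optional metadata tibble (`Sample`, `Timepoint`,
#'   `Condition`) used to group the baseline summary.
#' @return A list of class `taxfunc_cor`: `matrix` (symmetric, unit
#'   diagonal), `baseline_r` (per non-baseline sample) and
#'   `baseline_summary` (mean ± SD per group; `NULL` without metadata).
#' @export
taxfunc_cor_matrix <- function(profiles, baseline_samples,
                               metadata = NULL) {
  samples <- sort(unique(profiles$Sample))
  missing_bl <- setdiff(baseline_samples, samples)
  if (length(baseline_samples) == 0 || length(missing_bl) > 0)
    abort(paste0("baseline sample(s) absent from the profiles: ",
                 paste(missing_bl, collapse = ", ")),
          class = "mipror_domain_error")

  wide <- profiles |>
    mutate(cell = profile_cells(profiles)) |>
    select("cell", "Sample", "intensity") |>
    tidyr::pivot_wider(names_from = "Sample", values_from = "intensity",
                       values_fill = 0)
  W <- as.matrix(wide[, samples, drop = FALSE])

  n <- length(samples)
  R <- diag(1, n)
  dimnames(R) <- list(samples, samples)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      idx <- W[, i] > 0 | W[, j] > 0
      r <- if (sum(idx) < 3 || sd(W[idx, i]) == 0 || sd(W[idx, j]) == 0)
        NA_real_ else cor(W[idx, i], W[idx, j])
      R[i, j] <- R[j, i] <- r
    }
  }

  others <- setdiff(samples, baseline_samples)
  subject_of <- NULL
  if (!is.null(metadata) && "Subject" %in% names(as_tibble(metadata))) {
    md <- as_tibble(metadata)
    subject_of <- setNames(as.character(md$Subject), md$Sample)
  }
  baseline_r <- tibble(
    Sample = others,
    r = map_dbl(others, function(s) {
      bl <- baseline_samples
      # compare each sample to its own subject's inoculum replicates
      if (!is.null(subject_of)) {
        own <- bl[subject_of[bl] == subject_of[[s]]]
        if (length(own) > 0) bl <- own
      }
      mean(R[s, bl, drop = TRUE], na.rm = TRUE)
    }))

  baseline_summary <- NULL
  if (!is.null(metadata)) {
    baseline_summary <- baseline_r |>
      left_join(as_tibble(metadata), by = "Sample") |>
      group_by(.data$Timepoint, .data$Condition) |>
      summarise(mean_r = mean(.data$r), sd_r = sd(.data$r), n = n(),
                .groups = "drop")
  }
  structure(list(matrix = R, baseline_r = baseline_r,
                 baseline_summary = baseline_summary,
                 baseline_samples = baseline_samples),
            class = "taxfunc_cor")
}

#' @export
print.taxfunc_cor <- function(x, ...) {
  cat(sprintf("<taxfunc_cor> %d samples, %d baseline replicate(s)\n",
              nrow(x$matrix), length(x$baseline_samples)))
  cat(sprintf("mean r vs baseline: %.3f\n", mean(x$baseline_r$r,
                                                 na.rm = TRUE)))
  invisible(x)
}

#' Taxon-function enrichment ranking between two sample groups
#'
#' For every (taxon, COG) cell observed in both groups, tests whether the
#' co-occurrence of that taxon and that function among protein-group cell
#' memberships is larger than expected from the margins, using a one-sided
#' hypergeometric test on each margin (population: all distinct
#' protein-group memberships in the compared samples). Cells with both
#' p-values below `p_threshold` are ranked by matched-protein count
#' (descending), ties broken by summed intensity then lexicographic id,
#' and the `top_n` links are returned.
#'
#' @param profiles A [build_taxfunc_profile()] tibble.
#' @param group_pre,group_post Character vectors of sample ids.
#' @param p_threshold Enrichment threshold for both margins (default 0.05).
#' @param top_n Number of links to return (default 30).
#' @return A tibble: `Taxon`, `COG`, matched-protein counts and summed
#'   intensities per group, total count, and the two hypergeometric
#'   p-values; zero rows when nothing qualifies.
#' @export
taxfunc_enrichment <- function(profiles, group_pre, group_post,
                               p_threshold = 0.05, top_n = 30) {
  if (length(group_pre) == 0 || length(group_post) == 0)
    abort("both sample groups must be non-empty")
  mem <- attr(profiles, "memberships")
  if (is.null(mem))
    abort("profiles lack the memberships attribute; rebuild with build_taxfunc_profile()")
  mem <- mem |> filter(.data$Sample %in% c(group_pre, group_post)) |>
    distinct(.data$ProteinGroup, .data$Taxon, .data$COG)

  N <- nrow(mem)
  taxon_k <- mem |> count(.data$Taxon, name = "K_taxon")
  cog_k <- mem |> count(.data$COG, name = "K_cog")

  per_group <- function(g, suffix) {
    profiles |>
      filter(.data$Sample %in% g) |>
      group_by(.data$Taxon, .data$COG) |>
      summarise("intensity{suffix}" := sum(.data$intensity),
                .groups = "drop")
  }
  pre <- per_group(group_pre, "_pre")
  post <- per_group(group_post, "_post")

  counts <- mem |> count(.data$Taxon, .data$COG, name = "n_proteins")

  links <- inner_join(pre, post, by = c("Taxon", "COG")) |>
    inner_join(counts, by = c("Taxon", "COG")) |>
    left_join(taxon_k, by = "Taxon") |>
    left_join(cog_k, by = "COG") |>
    mutate(
      p_taxon = phyper(.data$n_proteins - 1, .data$K_taxon,
                       N - .data$K_taxon, .data$K_cog, lower.tail = FALSE),
      p_function = phyper(.data$n_proteins - 1, .data$K_cog,
                          N - .data$K_cog, .data$K_taxon,
                          lower.tail = FALSE)) |>
    filter(.data$p_taxon < p_threshold, .data$p_function < p_threshold) |>
    arrange(desc(.data$n_proteins),
            desc(.data$intensity_pre + .data$intensity_post),
            .data$Taxon, .data$COG) |>
    select("Taxon", "COG", "n_proteins", "intensity_pre", "intensity_post",
           "p_taxon", "p_function")
  head(links, top_n)
}
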