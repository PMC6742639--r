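#' Lowest common ancestor of a set of taxonomic lineages
#'
#' A lineage is an ordered assignment of names to the seven ranks
#' superkingdom through species; trailing ranks may be unresolved (empty
#' string or `NA`). The lowest common ancestor (LCA) is the deepest
#' lineage prefix on which all inputs agree, comparing rank by rank from
#' superkingdom downward; an unresolved rank in any input terminates
#' agreement at the last mutually resolved, equal rank. Disagreement at
#' superkingdom yields a fully unresolved ("root") lineage, which is a
#' valid output.
#'
#' @param lineages A data frame with the seven rank columns of
#'   [TAXONOMIC_RANKS] (extra columns ignored), one row per lineage.
#' @return A named character vector over the seven ranks; unresolved ranks
#'   are empty strings.
#' @export
lca_lineage <- function(lineages) {
  lineages <- as_tibble(lineages)
  if (nrow(lineages) == 0) abort("empty lineage set has no LCA")
  check_columns(lineages, TAXONOMIC_RANKS, "lineage")
  out <- setNames(rep("", 7L), TAXONOMIC_RANKS)
  for (r in TAXONOMIC_RANKS) {
    vals <- lineages[[r]]
    vals[is.na(vals)] <- ""
    u <- unique(vals)
    if (length(u) != 1L || u == "") break
    out[[r]] <- u
  }
  out
}

lineage_depth <- function(lin) sum(cumprod(lin != "" & !is.na(lin)))

#' Assign every peptide a taxonomic lineage by lowest common ancestor
#'
#' If the peptide table carries a precomputed `Lineage` column
#' (semicolon-separated ranked names), it is used verbatim. Otherwise each
#' peptide's lineage is the LCA of the lineages of the species of origin
#' of all proteins containing it, looked up through the protein table's
#' `Species` column and the lineage table. Peptides resolving only to the
#' root (or with no resolvable lineage source) are marked unassigned.
#'
#' @param dataset A [mipro_dataset()].
#' @return A tibble of class `peptide_assignments`: `Peptide`, the seven
#'   rank columns (empty = unresolved), `Depth` (number of resolved ranks,
#'   0 = unassigned) and `Taxon`, the deepest resolved node (`NA` when
#'   unassigned).
#' @export
assign_peptide_taxonomy <- function(dataset) {
  stopifnot(inherits(dataset, "mipro_dataset"))
  pep <- dataset$peptides

  if ("Lineage" %in% names(pep)) {
    parts <- strsplit(ifelse(is.na(pep$Lineage), "", pep$Lineage), ";",
                      fixed = TRUE)
    ranks <- t(vapply(parts, function(p) {
      out <- rep("", 7L)
      p <- p[p != ""]
      out[seq_along(head(p, 7L))] <- head(p, 7L)
      out
    }, character(7L)))
    colnames(ranks) <- TAXONOMIC_RANKS
    res <- bind_cols(tibble(Peptide = pep$Peptide), as_tibble(ranks))
  } else {
    if (!"Species" %in% names(dataset$proteins))
      abort(paste0("cannot assign taxonomy: peptide table has no `Lineage` ",
                   "column and protein table has no `Species` column"))
    long <- tibble(Peptide = pep$Peptide,
                   ProteinGroup = strsplit(pep$ProteinGroups, ";",
                                           fixed = TRUE)) |>
      tidyr::unnest("ProteinGroup") |>
      left_join(dataset$proteins |> select("ProteinGroup", "Species"),
                by = "ProteinGroup") |>
      left_join(dataset$lineages, by = c(Species = "Taxon"),
                suffix = c("", ".lineage"))
    rank_cols <- TAXONOMIC_RANKS
    if ("Species.lineage" %in% names(long)) {
      long$Species <- long$Species.lineage
    }
    res <- long |>
      group_by(.data$Peptide) |>
      summarise(across(all_of(rank_cols), function(v) {
        v[is.na(v)] <- ""
        u <- unique(v)
        if (length(u) == 1L) u else ""
      }), .groups = "drop")
    # enforce the prefix property: a break at one rank unresolves deeper ones
    m <- as.matrix(res[, rank_cols])
    keep <- t(apply(m != "", 1, cumprod)) == 1
    m[!keep] <- ""
    res[, rank_cols] <- as_tibble(m)
    res <- res[match(pep$Peptide, res$Peptide), ]
  }

  m <- as.matrix(res[, TAXONOMIC_RANKS])
  depth <- apply(m != "" & !is.na(m), 1, function(x) sum(cumprod(x)))
  taxon <- ifelse(depth > 0, m[cbind(seq_len(nrow(m)), pmax(depth, 1))], NA)
  out <- res |>
    mutate(Depth = as.integer(depth), Taxon = taxon)
  class(out) <- c("peptide_assignments", class(out))
  out
}

#' Taxon biomass-contribution matrix at a chosen rank
#'
#' Sums peptide intensities per taxon at the requested rank: a peptide
#' contributes to the taxon named at that rank of its assigned lineage
#' when the lineage is resolved at least that deep; peptides resolved only
#' above the requested rank contribute to an explicit unassigned bucket
#' (reported separately, never redistributed). Taxa quantified by fewer
#' than `min_distinct_peptides` distinct peptide identifiers (with nonzero
#' intensity somewhere in the dataset) are dropped, mirroring the
#' "quantified with >= 3 peptides" convention of metaproteomic biomass
#' comparisons. Optionally each sample column is rescaled to sum to one
#' over the retained taxa.
#'
#' @param dataset A [mipro_dataset()].
#' @param assignments Peptide assignments from [assign_peptide_taxonomy()];
#'   computed on the fly when `NULL`.
#' @param rank One of [TAXONOMIC_RANKS].
#' @param min_distinct_peptides Distinct-peptide filter, counted dataset
#'   wide (default 3).
#' @param normalize Rescale sample columns to relative abundances.
#' @return A tibble of class `abundance_matrix` with a `Taxon` column and
#'   one column per sample, plus attributes `normalized`, `rank`,
#'   `unassigned` (per-sample intensity left above the rank) and
#'   `peptide_counts` (distinct-peptide sidecar).
#' @export
biomass_matrix <- function(dataset, assignments = NULL, rank = "Species",
                           min_distinct_peptides = 3, normalize = TRUE) {
  stopifnot(inherits(dataset, "mipro_dataset"))
  if (!rank %in% TAXONOMIC_RANKS)
    abort(paste0("unknown rank: ", rank))
  if (is.null(assignments)) assignments <- assign_peptide_taxonomy(dataset)
  r <- match(rank, TAXONOMIC_RANKS)

  inten <- intensity_matrix(dataset$peptides, "Peptide", "Intensity")
  ass <- assignments[match(rownames(inten), assignments$Peptide), ]
  taxon <- ifelse(ass$Depth >= r, ass[[rank]], "unassigned")

  sums <- rowsum(inten, group = taxon)
  unassigned <- if ("unassigned" %in% rownames(sums))
    sums["unassigned", ] else setNames(rep(0, ncol(sums)), colnames(sums))
  sums <- sums[setdiff(rownames(sums), "unassigned"), , drop = FALSE]

  quantified <- rowSums(inten) > 0
  counts <- tibble(Taxon = taxon[quantified]) |>
    count(.data$Taxon, name = "n_peptides") |>
    filter(.data$Taxon != "unassigned")
  keep <- counts$Taxon[counts$n_peptides >= min_distinct_peptides]
  dropped_mass <- sums[!rownames(sums) %in% keep, , drop = FALSE]
  sums <- sums[rownames(sums) %in% keep, , drop = FALSE]
  if (nrow(sums) > 0)
    sums <- sums[order(rownames(sums)), , drop = FALSE]

  if (normalize) {
    tot <- colSums(sums)
    tot[tot == 0] <- 1
    sums <- sweep(sums, 2, tot, "/")
  }
  out <- matrix_to_tbl(sums, "Taxon")
  structure(out,
            class = c("abundance_matrix", class(out)),
            normalized = normalize, rank = rank,
            unassigned = unassigned + colSums(dropped_mass),
            peptide_counts = counts)
}

#' Relative change between a pre and a post measurement
#'
#' The change operator `(post - pre) / pre` used for fold-change style
#' comparisons of cultured versus inoculum measurements. Vectorized.
#'
#' @param pre,post Numeric; `pre` must be strictly positive (apply the
#'   pseudo-abundance policy — half the smallest nonzero value — before
#'   calling if zeros can occur).
#' @return `(post - pre) / pre`.
#' @export
relative_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    abort(paste0("`pre` must be strictly positive; replace zeros by the ",
                 "pseudo-abundance (half the smallest nonzero value) first"),
          class = "mipror_domain_error")
  (post - pre) / pre
}
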