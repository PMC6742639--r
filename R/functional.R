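#' Filter protein groups by presence across samples
#'
#' "Present" means nonzero LFQ intensity. Without a grouping, protein
#' groups present in at least `min_fraction` of all samples are kept (the
#' Q25 rule at the default 0.25). With a grouping — a partition of the
#' samples into subgroups — a protein group must meet the threshold within
#' every subgroup (the Q50 rule at 0.5). The comparison uses `>=`.
#'
#' @param proteins A protein-group table with `LFQ.<sample>` columns (the
#'   `proteins` element of a [mipro_dataset()]).
#' @param min_fraction Presence threshold in (0, 1].
#' @param grouping Optional named list of sample-id character vectors
#'   partitioning all samples.
#' @return The filtered protein table (same columns, fewer rows).
#' @export
presence_filter <- function(proteins, min_fraction = 0.25, grouping = NULL) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    abort("`min_fraction` must lie in (0, 1]")
  lfq <- intensity_matrix(proteins, "ProteinGroup", "LFQ")
  samples <- colnames(lfq)
  if (is.null(grouping)) grouping <- list(all = samples)
  grouping <- lapply(grouping, as.character)
  if (any(lengths(grouping) == 0))
    abort("grouping contains an empty subgroup",
          class = "mipror_domain_error")
  unknown <- setdiff(unlist(grouping), samples)
  if (length(unknown) > 0)
    abort(paste0("grouping names unknown sample(s): ",
                 paste(unknown, collapse = ", ")))
  keep <- rep(TRUE, nrow(proteins))
  for (g in grouping) {
    frac <- rowMeans(lfq[, g, drop = FALSE] > 0)
    keep <- keep & (frac >= min_fraction)
  }
  proteins[keep, , drop = FALSE]
}

#' Roll protein LFQ intensities up to COG categories
#'
#' The abundance of each COG category is the sum of the LFQ intensities of
#' all protein groups carrying that category, per sample. Proteins without
#' a COG annotation are collected in an explicit `"unannotated"` row, so
#' column sums over all rows conserve each sample's total protein LFQ.
#'
#' @param proteins A protein-group table with `COG` and `LFQ.<sample>`
#'   columns.
#' @return A tibble of class `function_matrix` (`Category` column plus one
#'   column per sample) with attribute `system = "COG"`.
#' @export
cog_rollup <- function(proteins) {
  lfq <- intensity_matrix(proteins, "ProteinGroup", "LFQ")
  cat <- ifelse(is.na(proteins$COG) | proteins$COG == "", "unannotated",
                proteins$COG)
  sums <- rowsum(lfq, group = cat)
  sums <- sums[order(rownames(sums) == "unannotated", rownames(sums)), ,
               drop = FALSE]
  out <- matrix_to_tbl(sums, "Category")
  structure(out, class = c("function_matrix", class(out)), system = "COG")
}

split_pathways <- function(x) strsplit(ifelse(is.na(x), "", x), ";",
                                       fixed = TRUE)

#' Roll protein LFQ intensities up to KEGG pathways
#'
#' A protein group contributes its full LFQ intensity to every pathway it
#' is annotated with, so pathway values are not a partition of the total
#' (double counting across pathways is intentional). Pathways in
#' `pathway_set` with no annotated protein are retained as rows of zeros.
#'
#' @param proteins A protein-group table with `KEGG_Pathway` (semicolon
#'   separated) and `LFQ.<sample>` columns.
#' @param pathway_set Character vector of pathway ids to report; defaults
#'   to all pathways seen in the table.
#' @return A tibble of class `function_matrix` with attribute
#'   `system = "KEGG"`.
#' @export
pathway_rollup <- function(proteins, pathway_set = NULL) {
  pw <- split_pathways(proteins$KEGG_Pathway)
  if (is.null(pathway_set))
    pathway_set <- sort(unique(unlist(pw)))
  pathway_set <- setdiff(pathway_set, "")
  if (length(pathway_set) == 0)
    abort("`pathway_set` is empty and no pathway annotations were found")
  lfq <- intensity_matrix(proteins, "ProteinGroup", "LFQ")
  sums <- matrix(0, nrow = length(pathway_set), ncol = ncol(lfq),
                 dimnames = list(pathway_set, colnames(lfq)))
  idx <- tibble(row = rep(seq_along(pw), lengths(pw)),
                pathway = unlist(pw)) |>
    filter(.data$pathway %in% pathway_set)
  if (nrow(idx) > 0) {
    part <- rowsum(lfq[idx$row, , drop = FALSE], group = idx$pathway)
    sums[rownames(part), ] <- part
  }
  out <- matrix_to_tbl(sums, "Category")
  structure(out, class = c("function_matrix", class(out)), system = "KEGG")
}

#' Within-pathway enzyme fractions
#'
#' For one pathway, sums the LFQ intensities of the proteins carrying each
#' enzyme id and normalizes per sample against the summed intensity of all
#' enzyme-annotated proteins in that pathway, so detected-enzyme fractions
#' sum to one in every sample with nonzero pathway signal. Samples with no
#' signal get `NA` fractions.
#'
#' @param proteins A protein-group table with `KEGG_Pathway`, `Enzyme` and
#'   `LFQ.<sample>` columns.
#' @param pathway A single pathway id.
#' @return A tibble of class `function_matrix` (`Category` = enzyme id)
#'   with attribute `system = "enzyme"` and `pathway` recording the
#'   pathway.
#' @export
enzyme_fraction <- function(proteins, pathway) {
  stopifnot(length(pathway) == 1)
  in_pw <- map_lgl(split_pathways(proteins$KEGG_Pathway),
                   function(p) pathway %in% p)
  enz <- ifelse(is.na(proteins$Enzyme), "", proteins$Enzyme)
  sel <- in_pw & enz != ""
  if (!any(sel))
    abort(paste0("pathway ", pathway, " has no enzyme-annotated protein"),
          class = "mipror_domain_error")
  lfq <- intensity_matrix(proteins[sel, ], "ProteinGroup", "LFQ")
  sums <- rowsum(lfq, group = enz[sel])
  tot <- colSums(sums)
  frac <- sweep(sums, 2, tot, "/")
  frac[, tot == 0] <- NA_real_
  frac <- frac[order(rownames(frac)), , drop = FALSE]
  out <- matrix_to_tbl(frac, "Category")
  structure(out, class = c("function_matrix", class(out)),
            system = "enzyme", pathway = pathway)
}
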