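#' Assemble and validate a metaproteomic dataset
#'
#' Bundles the four post-search tables into one validated object. The
#' tables follow a MetaLab-style tab-separated layout:
#' \describe{
#'   \item{peptides}{`Peptide`, `ProteinGroups` (semicolon-separated ids),
#'     optional `Lineage` (semicolon-separated ranked names, empty =
#'     unassigned) and one `Intensity.<sample>` column per sample.}
#'   \item{proteins}{`ProteinGroup`, `COG` (single category letter or
#'     empty), `KEGG_Pathway` (semicolon-separated ids or empty), `Enzyme`
#'     (EC-style id or empty) and one `LFQ.<sample>` column per sample.}
#'   \item{lineages}{`Taxon` plus the seven rank columns
#'     Superkingdom...Species; empty cells are unresolved ranks.}
#'   \item{metadata}{`Sample`, `Subject`, `Timepoint`, `Arm`
#'     (`in_vitro`/`in_vivo`), `Condition`, `Replicate`.}
#' }
#' Zero intensity means "not detected". Validation checks that the sample
#' sets of the peptide intensities, protein intensities and metadata agree,
#' that every protein group referenced by a peptide exists, and that all
#' intensities are non-negative.
#'
#' @param peptides,proteins,lineages,metadata Data frames as above.
#' @return A validated object of class `mipro_dataset`.
#' @export
mipro_dataset <- function(peptides, proteins, lineages, metadata) {
  ds <- structure(list(peptides = as_tibble(peptides),
                       proteins = as_tibble(proteins),
                       lineages = as_tibble(lineages),
                       metadata = as_tibble(metadata)),
                  class = "mipro_dataset")
  validate_dataset(ds)
}

check_columns <- function(tbl, need, table_name) {
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0)
    abort(sprintf("schema error in %s table: missing column(s) %s",
                  table_name, paste0("`", miss, "`", collapse = ", ")),
          class = "mipror_schema_error")
}

validate_dataset <- function(ds) {
  check_columns(ds$peptides, c("Peptide", "ProteinGroups"), "peptide")
  check_columns(ds$proteins, c("ProteinGroup", "COG", "KEGG_Pathway",
                               "Enzyme"), "protein")
  check_columns(ds$lineages, c("Taxon", TAXONOMIC_RANKS), "lineage")
  check_columns(ds$metadata, c("Sample", "Subject", "Timepoint", "Arm",
                               "Condition", "Replicate"), "metadata")

  pep_samples <- sample_ids_of(ds$peptides, "Intensity")
  prot_samples <- sample_ids_of(ds$proteins, "LFQ")
  meta_samples <- as.character(ds$metadata$Sample)
  if (anyDuplicated(meta_samples))
    abort("metadata `Sample` ids must be unique",
          class = "mipror_consistency_error")
  sets <- list(peptide = sort(pep_samples), protein = sort(prot_samples),
               metadata = sort(meta_samples))
  if (!identical(sets$peptide, sets$protein) ||
      !identical(sets$peptide, sets$metadata)) {
    all_s <- unique(c(pep_samples, prot_samples, meta_samples))
    missing_from <- map_chr(all_s, function(s) {
      paste(names(sets)[!map_lgl(sets, function(x) s %in% x)],
            collapse = ",")
    })
    bad <- all_s[missing_from != ""]
    abort(paste0("sample sets disagree across tables; missing: ",
                 paste0(bad, " (from ", missing_from[missing_from != ""],
                        ")", collapse = "; ")),
          class = "mipror_consistency_error")
  }

  referenced <- unique(unlist(strsplit(ds$peptides$ProteinGroups, ";",
                                       fixed = TRUE)))
  unknown <- setdiff(referenced, ds$proteins$ProteinGroup)
  if (length(unknown) > 0)
    abort(paste0("peptides reference protein group(s) absent from the ",
                 "protein table: ", paste(unknown, collapse = ", ")),
          class = "mipror_consistency_error")

  for (pref in list(c("peptides", "Intensity"), c("proteins", "LFQ"))) {
    cols <- sample_columns(ds[[pref[1]]], pref[2])
    vals <- as.matrix(ds[[pref[1]]][, cols, drop = FALSE])
    if (anyNA(vals) || any(vals < 0))
      abort(sprintf("%s intensities must be non-negative with missing encoded as 0",
                    pref[1]),
            class = "mipror_consistency_error")
  }
  ds
}

#' @export
print.mipro_dataset <- function(x, ...) {
  cat(sprintf(paste0("<mipro_dataset> %d peptides, %d protein groups, ",
                     "%d lineages, %d samples\n"),
              nrow(x$peptides), nrow(x$proteins), nrow(x$lineages),
              nrow(x$metadata)))
  invisible(x)
}

read_table_checked <- function(path, need, table_name) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "mipror_io_error")
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  check_columns(tbl, need, table_name)
  tbl
}

parse_intensities <- function(tbl, prefix) {
  cols <- sample_columns(tbl, prefix)
  # base as.numeric (strtod): correctly rounded, '.' decimal separator
  # regardless of locale, so written doubles round-trip bit-exactly
  tbl |> mutate(across(all_of(cols), as.numeric))
}

#' Read a metaproteomic dataset from four tab-separated files
#'
#' Parses the MetaLab-style tables documented in [mipro_dataset()],
#' validates them and joins them into one dataset object. Parsing is
#' locale-independent (`.` decimal separator, UTF-8); unknown extra
#' columns are preserved but ignored.
#'
#' @param peptide_path,protein_path,lineage_path,metadata_path File paths.
#' @return A validated [mipro_dataset()].
#' @export
read_dataset <- function(peptide_path, protein_path, lineage_path,
                         metadata_path) {
  peptides <- read_table_checked(peptide_path,
                                 c("Peptide", "ProteinGroups"), "peptide") |>
    parse_intensities("Intensity")
  proteins <- read_table_checked(protein_path,
                                 c("ProteinGroup", "COG", "KEGG_Pathway",
                                   "Enzyme"), "protein") |>
    parse_intensities("LFQ")
  lineages <- read_table_checked(lineage_path, c("Taxon", TAXONOMIC_RANKS),
                                 "lineage")
  metadata <- read_table_checked(metadata_path,
                                 c("Sample", "Subject", "Timepoint", "Arm",
                                   "Condition", "Replicate"), "metadata") |>
    mutate(Timepoint = readr::parse_number(.data$Timepoint),
           Replicate = readr::parse_number(.data$Replicate))
  mipro_dataset(peptides, proteins, lineages, metadata)
}

# Canonical table layout: id-sorted rows, fixed leading columns, sample
# columns sorted by sample id.
canonicalize <- function(tbl, id_col, prefix) {
  fixed <- setdiff(names(tbl), sample_columns(tbl, prefix))
  tbl[order(tbl[[id_col]]),
      c(fixed, sort(sample_columns(tbl, prefix)))]
}

#' Write a metaproteomic dataset to a directory
#'
#' Writes `peptides.tsv`, `proteinGroups.tsv`, `lineages.tsv` and
#' `metadata.tsv` in the layout documented in [mipro_dataset()]:
#' deterministic column and row order (sorted by id), UTF-8, tab
#' separators, `.` decimal separator. Two writes of the same dataset are
#' byte-identical.
#'
#' @param dataset A [mipro_dataset()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "mipro_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort(paste0("cannot create output directory: ", out_dir),
          class = "mipror_io_error")
  paths <- c(peptides = file.path(out_dir, "peptides.tsv"),
             proteins = file.path(out_dir, "proteinGroups.tsv"),
             lineages = file.path(out_dir, "lineages.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"))
  readr::write_tsv(canonicalize(dataset$peptides, "Peptide", "Intensity"),
                   paths["peptides"], na = "", progress = FALSE)
  readr::write_tsv(canonicalize(dataset$proteins, "ProteinGroup", "LFQ"),
                   paths["proteins"], na = "", progress = FALSE)
  readr::write_tsv(dataset$lineages[order(dataset$lineages$Taxon), ],
                   paths["lineages"], na = "", progress = FALSE)
  readr::write_tsv(dataset$metadata[order(dataset$metadata$Sample), ],
                   paths["metadata"], na = "", progress = FALSE)
  invisible(paths)
}
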