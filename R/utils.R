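#' The seven taxonomic ranks used throughout the package
#'
#' Lineages are vectors of names over these ranks, superkingdom first.
#' Unresolved ranks are empty strings; once a rank is unresolved all deeper
#' ranks must be unresolved too.
#'
#' @export
TAXONOMIC_RANKS <- c("Superkingdom", "Phylum", "Class", "Order",
                     "Family", "Genus", "Species")

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Names of the per-sample intensity columns of a table, e.g. "Intensity.S1".
sample_columns <- function(tbl, prefix) {
  grep(paste0("^", prefix, "\\."), names(tbl), value = TRUE)
}

sample_ids_of <- function(tbl, prefix) {
  sub(paste0("^", prefix, "\\."), "", sample_columns(tbl, prefix))
}

# Feature-by-sample tibble (id column first, one numeric column per sample)
# to a plain matrix with feature rownames.
tbl_to_matrix <- function(tbl) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- as.character(tbl[[1]])
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m, id_name) {
  ids <- rownames(m) %||% character(nrow(m))
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_name := ids), out)
}

# Intensity matrix (rows = ids, cols = bare sample ids) from a table whose
# per-sample columns are named <prefix>.<sample>.
intensity_matrix <- function(tbl, id_col, prefix) {
  cols <- sample_columns(tbl, prefix)
  m <- as.matrix(tbl[, cols, drop = FALSE])
  rownames(m) <- tbl[[id_col]]
  colnames(m) <- sub(paste0("^", prefix, "\\."), "", cols)
  storage.mode(m) <- "double"
  m
}

# Half the smallest nonzero value: the pseudo-abundance used wherever a
# ratio needs a nonzero denominator.
pseudo_abundance <- function(x) {
  nz <- x[x > 0]
  if (length(nz) == 0) return(0)
  min(nz) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
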