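#' PLS-DA with variable-importance-in-projection scores
#'
#' Fits a two-class partial least squares discriminant model by the
#' standard NIPALS deflation scheme on autoscaled features (each feature
#' centered and scaled to unit variance; zero-variance features are kept
#' with scaled value 0) against a centered two-level dummy response, and
#' returns VIP scores
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)`,
#' where `p` is the number of features, `w_a` the a-th weight vector and
#' `SSY_a` the response variance explained by component a. VIPs are also
#' reported for every cumulative model A = 1..`n_components`, which is how
#' "VIP above a threshold on all components" selections are evaluated. The
#' fit is deterministic given input order, and every fit satisfies
#' `mean(VIP^2) = 1`.
#'
#' @param x Feature-by-sample table (id column first) such as a protein
#'   LFQ or species abundance matrix, or a numeric matrix with feature
#'   rownames and sample colnames.
#' @param labels Class label per sample; exactly two classes, each with at
#'   least 3 samples.
#' @param n_components Number of PLS components (default 3); reduced with
#'   a warning when the data support fewer.
#' @return An object of class `vip_result`: `vip` (tibble with `feature`,
#'   `VIP_1..VIP_A` cumulative scores and `VIP` for the full model),
#'   `weights`, `scores`, `ssy`, `n_components`, `classes`.
#' @export
plsda_vip <- function(x, labels, n_components = 3) {
  m <- if (is.matrix(x)) x else tbl_to_matrix(as_tibble(x))
  labels <- as.character(labels)
  if (length(labels) != ncol(m))
    abort("`labels` must have one entry per sample")
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    abort("PLS-DA needs exactly two classes",
          class = "mipror_domain_error")
  if (any(table(labels) < 3))
    abort("each class needs at least 3 samples")

  p <- nrow(m); n <- ncol(m)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  Xs <- (m - mu) / ifelse(s > 0, s, 1)
  Xs[s == 0, ] <- 0
  X <- t(Xs)                                   # samples x features
  y <- as.numeric(labels == classes[2])
  y <- y - mean(y)
  ssy_tot <- sum(y^2)

  A <- min(n_components, n - 1, p)
  if (A < n_components)
    warn(sprintf("n_components reduced from %d to %d (data rank)",
                 n_components, A))
  W <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  ssy <- numeric(0)
  for (a in seq_len(A)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, ssy_tot)) {
      if (a <= n_components)
        warn(sprintf("n_components reduced to %d (response fully explained)",
                     a - 1))
      break
    }
    w <- w / nw
    t_ <- drop(X %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-24) break
    pv <- drop(crossprod(X, t_)) / tt
    q <- sum(y * t_) / tt
    W <- cbind(W, w)
    Tm <- cbind(Tm, t_)
    ssy <- c(ssy, q^2 * tt)
    X <- X - tcrossprod(t_, pv)
    y <- y - q * t_
  }
  A <- ncol(W)
  if (A == 0) abort("no usable PLS component: response has no association with the features")

  vip_cum <- vapply(seq_len(A), function(k) {
    num <- (W[, seq_len(k), drop = FALSE]^2) %*% ssy[seq_len(k)]
    sqrt(p * drop(num) / sum(ssy[seq_len(k)]))
  }, numeric(p))
  colnames(vip_cum) <- paste0("VIP_", seq_len(A))

  vip <- bind_cols(tibble(feature = rownames(m)),
                   as_tibble(vip_cum, .name_repair = "minimal")) |>
    mutate(VIP = unname(vip_cum[, A]))
  structure(list(vip = vip, weights = W, scores = Tm, ssy = ssy,
                 n_components = A, classes = classes),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result> %d features, %d component(s); classes: %s\n",
              nrow(x$vip), x$n_components, paste(x$classes,
                                                 collapse = " vs ")))
  print(head(x$vip |> arrange(desc(.data$VIP)), 5))
  invisible(x)
}

#' Select features by VIP threshold
#'
#' Strict inequality: a feature qualifies when its VIP score exceeds the
#' threshold (a VIP exactly equal to the threshold is excluded). In
#' `all_components` mode a feature must exceed the threshold on every
#' cumulative-component evaluation A = 1..n_components.
#'
#' @param vip A [plsda_vip()] result.
#' @param threshold Positive VIP cutoff (1 for differential-protein
#'   selection, 2 for the stringent all-components species selection).
#' @param all_components Require the threshold on every cumulative model.
#' @return Character vector of qualifying feature ids (possibly empty).
#' @export
select_features <- function(vip, threshold = 1, all_components = FALSE) {
  stopifnot(inherits(vip, "vip_result"), threshold > 0)
  tbl <- vip$vip
  if (all_components) {
    cols <- paste0("VIP_", seq_len(vip$n_components))
    ok <- rowSums(as.matrix(tbl[, cols, drop = FALSE]) > threshold) ==
      length(cols)
  } else {
    ok <- tbl$VIP > threshold
  }
  tbl$feature[ok]
}

# Per-subject pre/post mean relative-abundance profiles for one arm.
arm_profiles <- function(dataset, level, assignments = NULL,
                         min_distinct_peptides = 3) {
  meta <- dataset$metadata
  if (length(level) == 1 && level %in% TAXONOMIC_RANKS) {
    ab <- biomass_matrix(dataset, assignments, rank = level,
                         min_distinct_peptides = min_distinct_peptides,
                         normalize = TRUE)
    m <- tbl_to_matrix(ab)
  } else {
    pr <- pathway_rollup(dataset$proteins,
                         pathway_set = if (identical(level, "pathway"))
                           NULL else level)
    m <- tbl_to_matrix(pr)
    tot <- colSums(intensity_matrix(dataset$proteins, "ProteinGroup",
                                    "LFQ"))
    m <- sweep(m, 2, ifelse(tot > 0, tot, 1), "/")
  }
  list(matrix = m, meta = meta)
}

#' Paired in vitro / in vivo treatment-induced changes
#'
#' For every subject present in both arms and every feature (taxa at a
#' rank, or KEGG pathways as a share of total protein intensity), computes
#' the change in relative abundance, `mean(post) - mean(pre)`, in each
#' arm. Pre samples are those with `Condition == pre_label`; post samples
#' have `Condition == post_label`, the in vivo arm contributing one change
#' per treated timepoint. A log2 ratio with pseudo-abundance protection is
#' emitted as an auxiliary column. Subjects missing an arm are excluded
#' with a warning.
#'
#' @param dataset_invitro,dataset_invivo [mipro_dataset()] objects for the
#'   two arms.
#' @param level A rank from [TAXONOMIC_RANKS], `"pathway"` (all annotated
#'   pathways), or a character vector of pathway ids.
#' @param pre_label,post_label Condition labels marking untreated and
#'   treated samples (defaults `"untreated"`/`"treated"`).
#' @param min_distinct_peptides Passed to [biomass_matrix()] for taxon
#'   levels.
#' @return A tibble of class `change_table`: `Subject`, `feature`,
#'   `invivo_timepoint`, `in_vitro_change`, `in_vivo_change`,
#'   `in_vitro_log2`, `in_vivo_log2`.
#' @export
ivivc_changes <- function(dataset_invitro, dataset_invivo,
                          level = "Phylum", pre_label = "untreated",
                          post_label = "treated",
                          min_distinct_peptides = 3) {
  arms <- list(in_vitro = arm_profiles(dataset_invitro, level,
                                       min_distinct_peptides = min_distinct_peptides),
               in_vivo = arm_profiles(dataset_invivo, level,
                                      min_distinct_peptides = min_distinct_peptides))
  features <- intersect(rownames(arms$in_vitro$matrix),
                        rownames(arms$in_vivo$matrix))
  if (length(features) == 0)
    abort("no feature is quantified in both arms")

  subj_ok <- function(arm) {
    meta <- arm$meta
    meta |>
      group_by(.data$Subject) |>
      summarise(ok = any(.data$Condition == pre_label) &
                  any(.data$Condition == post_label)) |>
      filter(.data$ok) |> pull("Subject")
  }
  subjects <- intersect(subj_ok(arms$in_vitro), subj_ok(arms$in_vivo))
  all_subj <- union(arms$in_vitro$meta$Subject, arms$in_vivo$meta$Subject)
  if (length(setdiff(all_subj, subjects)) > 0)
    warn(paste0("subject(s) missing an arm or a condition, excluded: ",
                paste(setdiff(all_subj, subjects), collapse = ", ")))
  if (length(subjects) == 0) abort("no subject has matched pre/post samples in both arms")

  eps <- pseudo_abundance(c(arms$in_vitro$matrix[features, ],
                            arms$in_vivo$matrix[features, ]))
  mean_profile <- function(arm, subject, cond, tp = NULL) {
    meta <- arm$meta
    sel <- meta$Subject == subject & meta$Condition == cond
    if (!is.null(tp)) sel <- sel & meta$Timepoint == tp
    rowMeans(arm$matrix[features, meta$Sample[sel], drop = FALSE])
  }

  vivo_meta <- arms$in_vivo$meta
  vivo_tps <- sort(unique(vivo_meta$Timepoint[vivo_meta$Condition ==
                                                post_label]))
  rows <- list()
  for (subject in subjects) {
    pre_vitro <- mean_profile(arms$in_vitro, subject, pre_label)
    post_vitro <- mean_profile(arms$in_vitro, subject, post_label)
    pre_vivo <- mean_profile(arms$in_vivo, subject, pre_label)
    for (tp in vivo_tps) {
      post_vivo <- mean_profile(arms$in_vivo, subject, post_label, tp)
      rows[[length(rows) + 1]] <- tibble(
        Subject = subject, feature = features, invivo_timepoint = tp,
        in_vitro_change = post_vitro - pre_vitro,
        in_vivo_change = post_vivo - pre_vivo,
        in_vitro_log2 = log2((post_vitro + eps) / (pre_vitro + eps)),
        in_vivo_log2 = log2((post_vivo + eps) / (pre_vivo + eps)))
    }
  }
  out <- bind_rows(rows)
  structure(out, class = c("change_table", class(out)), level = level)
}

#' In vitro - in vivo concordance of treatment-induced changes
#'
#' Per subject (and in vivo timepoint), the Pearson correlation across
#' features between the in vitro and in vivo changes; summarized as mean
#' +/- SD per timepoint. Quadrant agreement is the percentage of
#' (subject, feature) rows whose two changes share a sign, among rows
#' where both are nonzero — rows in quadrants I and III of the
#' change-change plane.
#'
#' @param changes A [ivivc_changes()] table.
#' @return An object of class `ivivc_result`: `per_subject` (Subject,
#'   invivo_timepoint, r, n_features), `summary` (mean/sd of r per
#'   timepoint), `quadrant_agreement_pct` (per timepoint and overall).
#' @export
ivivc_correlation <- function(changes) {
  per_subject <- changes |>
    group_by(.data$Subject, .data$invivo_timepoint) |>
    summarise(n_features = n(),
              r = if (n() >= 3)
                cor(.data$in_vitro_change, .data$in_vivo_change)
              else NA_real_,
              .groups = "drop")
  skipped <- per_subject |> filter(.data$n_features < 3)
  if (nrow(skipped) > 0) {
    warn(paste0("subject(s) with fewer than 3 features skipped: ",
                paste(unique(skipped$Subject), collapse = ", ")))
    per_subject <- per_subject |> filter(.data$n_features >= 3)
  }
  summary <- per_subject |>
    group_by(.data$invivo_timepoint) |>
    summarise(mean_r = mean(.data$r), sd_r = sd(.data$r), n = n(),
              .groups = "drop")
  agree <- changes |>
    filter(.data$in_vitro_change != 0, .data$in_vivo_change != 0) |>
    mutate(agree = sign(.data$in_vitro_change) ==
             sign(.data$in_vivo_change))
  quad <- agree |>
    group_by(.data$invivo_timepoint) |>
    summarise(agreement_pct = 100 * mean(.data$agree), n_rows = n(),
              .groups = "drop")
  overall <- if (nrow(agree) > 0) 100 * mean(agree$agree) else NA_real_
  structure(list(per_subject = per_subject, summary = summary,
                 quadrant = quad, quadrant_agreement_pct = overall),
            class = "ivivc_result")
}

#' @export
print.ivivc_result <- function(x, ...) {
  cat("<ivivc_result>\n")
  print(x$summary)
  cat(sprintf("overall quadrant agreement: %.1f%%\n",
              x$quadrant_agreement_pct))
  invisible(x)
}

#' Two-sided non-parametric comparison of two groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) test: exact when both groups have at
#' most 8 values and the pooled values are tie-free, otherwise the normal
#' approximation with tie correction. Constant pooled values give p = 1.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @return Two-sided p-value.
#' @export
group_compare <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    abort("each group needs at least 3 values")
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) return(1)
  exact <- length(values_a) <= 8 && length(values_b) <= 8 &&
    !anyDuplicated(pooled)
  suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided",
                exact = exact)$p.value)
}
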