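#' Tidy an ANOSIM result
#' @param x An `anosim_result`.
#' @param ... Unused.
#' @return One-row tibble with `R`, `p.value`, `method`, `n_permutations`.
#' @method tidy anosim_result
#' @export
tidy.anosim_result <- function(x, ...) {
  tibble(R = x$R, p.value = x$p, method = x$method,
         n_permutations = x$n_permutations)
}

#' @rdname tidy.anosim_result
#' @method glance anosim_result
#' @export
glance.anosim_result <- function(x, ...) {
  tibble(R = x$R, p.value = x$p, n_groups = length(x$groups),
         n_samples = sum(x$groups))
}

#' Tidy a PLS-DA VIP result
#' @param x A `vip_result`.
#' @param ... Unused.
#' @return The per-feature VIP tibble (cumulative components + final VIP).
#' @method tidy vip_result
#' @export
tidy.vip_result <- function(x, ...) as_tibble(x$vip)

#' @rdname tidy.vip_result
#' @method glance vip_result
#' @export
glance.vip_result <- function(x, ...) {
  tibble(n_features = nrow(x$vip), n_components = x$n_components,
         explained_y_variance = sum(x$ssy),
         mean_vip_sq = mean(x$vip$VIP^2))
}

#' Tidy an ordination
#' @param x A `mipro_ordination`.
#' @param ... Unused.
#' @return Sample coordinates with per-axis variance proportions attached
#'   as the `proportions` attribute.
#' @method tidy mipro_ordination
#' @export
tidy.mipro_ordination <- function(x, ...) {
  structure(x$points, proportions = x$proportions)
}

#' @rdname tidy.mipro_ordination
#' @method glance mipro_ordination
#' @export
glance.mipro_ordination <- function(x, ...) {
  tibble(type = x$type, n_axes = length(x$proportions),
         axis1_prop = x$proportions[1],
         axis2_prop = if (length(x$proportions) > 1)
           x$proportions[2] else NA_real_)
}

#' Tidy an IVIVC result
#' @param x An `ivivc_result`.
#' @param ... Unused.
#' @return The per-subject correlation tibble.
#' @method tidy ivivc_result
#' @export
tidy.ivivc_result <- function(x, ...) x$per_subject

#' @rdname tidy.ivivc_result
#' @method glance ivivc_result
#' @export
glance.ivivc_result <- function(x, ...) {
  tibble(mean_r = mean(x$per_subject$r, na.rm = TRUE),
         sd_r = sd(x$per_subject$r),
         quadrant_agreement_pct = x$quadrant_agreement_pct,
         n_subjects = dplyr::n_distinct(x$per_subject$Subject))
}

#' Tidy a taxon-function correlation object
#' @param x A `taxfunc_cor`.
#' @param ... Unused.
#' @return Per-sample correlation against the baseline.
#' @method tidy taxfunc_cor
#' @export
tidy.taxfunc_cor <- function(x, ...) x$baseline_r

#' @rdname tidy.taxfunc_cor
#' @method glance taxfunc_cor
#' @export
glance.taxfunc_cor <- function(x, ...) {
  tibble(mean_r = mean(x$baseline_r$r, na.rm = TRUE),
         sd_r = sd(x$baseline_r$r),
         n_samples = nrow(x$matrix),
         n_baseline = length(x$baseline_samples))
}
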