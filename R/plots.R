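#' Plot an ordination (PCoA or PCA) as a scatter of the first two axes
#'
#' @param object A `mipro_ordination`.
#' @param metadata Optional metadata tibble joined on `Sample`; its
#'   `colour_by` column maps to point colour.
#' @param colour_by Metadata column name for colour (default `Condition`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mipro_ordination
#' @export
autoplot.mipro_ordination <- function(object, metadata = NULL,
                                      colour_by = "Condition", ...) {
  pts <- object$points
  if (ncol(pts) < 3) abort("ordination has fewer than 2 axes to plot")
  if (!is.null(metadata))
    pts <- left_join(pts, as_tibble(metadata), by = "Sample")
  pct <- round(100 * object$proportions[1:2], 1)
  p <- ggplot(pts, aes(.data$Axis1, .data$Axis2)) +
    labs(x = sprintf("Axis 1 (%.1f%%)", pct[1]),
         y = sprintf("Axis 2 (%.1f%%)", pct[2]),
         title = toupper(object$type)) +
    theme_minimal()
  if (!is.null(metadata) && colour_by %in% names(pts))
    p + geom_point(aes(colour = factor(.data[[colour_by]])), size = 2) +
      labs(colour = colour_by)
  else p + geom_point(size = 2)
}

#' Plot taxon-function stability against the baseline over time
#'
#' Boxplots of the per-sample Pearson r of the taxon-function coupled
#' profile versus the inoculum, grouped by timepoint and condition.
#'
#' @param object A `taxfunc_cor` built with metadata.
#' @param metadata Metadata tibble (`Sample`, `Timepoint`, `Condition`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot taxfunc_cor
#' @export
autoplot.taxfunc_cor <- function(object, metadata, ...) {
  df <- left_join(object$baseline_r, as_tibble(metadata), by = "Sample")
  ggplot(df, aes(factor(.data$Timepoint), .data$r,
                 fill = .data$Condition)) +
    geom_boxplot() +
    labs(x = "Timepoint", y = "Pearson r vs baseline") +
    theme_minimal()
}

#' Plot top VIP scores of a PLS-DA fit
#'
#' @param object A `vip_result`.
#' @param top_n Number of features to show (default 20).
#' @param threshold Reference line (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vip_result
#' @export
autoplot.vip_result <- function(object, top_n = 20, threshold = 1, ...) {
  df <- object$vip |> arrange(desc(.data$VIP)) |> head(top_n)
  ggplot(df, aes(.data$VIP, stats::reorder(.data$feature, .data$VIP))) +
    geom_segment(aes(x = 0, xend = .data$VIP,
                     yend = stats::reorder(.data$feature, .data$VIP)),
                 colour = "grey60") +
    geom_point() +
    geom_vline(xintercept = threshold, linetype = 2, colour = "red") +
    labs(x = "VIP", y = NULL) +
    theme_minimal()
}

#' Quadrant plot of in vitro versus in vivo changes
#'
#' Scatter of the paired changes; points in quadrants I and III indicate
#' in vitro - in vivo consistency.
#'
#' @param object A `change_table` from [ivivc_changes()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot change_table
#' @export
autoplot.change_table <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(.data$in_vitro_change, .data$in_vivo_change,
             colour = .data$feature)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_vline(xintercept = 0, colour = "grey70") +
    geom_point() +
    facet_wrap(~invivo_timepoint, labeller = label_both) +
    labs(x = "In vitro change in relative abundance",
         y = "In vivo change in relative abundance") +
    theme_minimal()
}

#' Stacked composition bars of an abundance matrix
#'
#' @param object An `abundance_matrix` from [biomass_matrix()].
#' @param top_n Taxa to name individually; the rest pool into "other".
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abundance_matrix
#' @export
autoplot.abundance_matrix <- function(object, top_n = 12, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-"Taxon", names_to = "Sample",
                        values_to = "abundance")
  keep <- long |> group_by(.data$Taxon) |>
    summarise(tot = sum(.data$abundance)) |>
    arrange(desc(.data$tot)) |> head(top_n) |> pull("Taxon")
  long <- long |>
    mutate(Taxon = ifelse(.data$Taxon %in% keep, .data$Taxon, "other"))
  ggplot(long, aes(.data$Sample, .data$abundance, fill = .data$Taxon)) +
    geom_col() +
    labs(y = if (isTRUE(attr(object, "normalized")))
      "Relative abundance" else "Summed intensity") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}
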