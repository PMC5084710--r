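# ggplot2 displays for the main result types.

#' Boxplots of new-wall angles per region
#'
#' Recreates the standard zonation display: one box per region (optionally
#' split by a grouping column such as genotype) of the chosen orientation
#' metric over called new walls. Boxes use the same quantile convention as
#' [summarize_by_region()].
#'
#' @param facets Classified facet tibble.
#' @param metric `"angle_to_axis"` or `"radial_angle"`.
#' @param group Optional column name mapped to fill.
#' @return A ggplot object.
#' @export
plot_angle_boxes <- function(facets, metric = "angle_to_axis", group = NULL) {
  dat <- facets[facets$is_new_wall & !is.na(facets$region) &
                  !is.na(facets[[metric]]), , drop = FALSE]
  aes <- if (is.null(group)) {
    ggplot2::aes(x = .data$region, y = .data[[metric]])
  } else {
    ggplot2::aes(x = .data$region, y = .data[[metric]], fill = .data[[group]])
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_boxplot(outlier.colour = "red", outlier.size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 90),
                                breaks = seq(0, 90, 30)) +
    ggplot2::labs(x = NULL, y = paste(gsub("_", " ", metric), "(degrees)")) +
    ggplot2::theme_classic()
}

#' Vertical or radial projection of clonal sectors
#'
#' @param landmarks Aligned landmark tibble (`apex_id`, `sector_id`, `x`,
#'   `y`, `z`).
#' @param mode `"vertical"` or `"radial"` (see [project_sectors()]).
#' @return A ggplot object.
#' @export
plot_sector_projection <- function(landmarks, mode = c("vertical", "radial")) {
  mode <- match.arg(mode)
  pr <- project_sectors(landmarks, mode)
  pr$sector <- factor(pr$sector_id)
  labs <- if (mode == "vertical") c("x (um)", "y (um)") else
    c("signed radius (um)", "z (um)")
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$u, y = .data$v,
                                   colour = .data$sector)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_classic()
}

#' Position histograms of observed vs simulated peak centers
#'
#' Frequency of peak centers at transcript-relative positions (nt), observed
#' against the Monte Carlo null, around the transcript start
#' (`which = "start"`) or end (`which = "end"`).
#'
#' @param x An `apexkit_enrichment` object (run with `positions = TRUE`).
#' @param which `"start"` or `"end"`.
#' @param binwidth Bin width in nt (default 150).
#' @param window Display range in nt around the reference point.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.apexkit_enrichment <- function(x, which = c("start", "end"),
                                        binwidth = 150, window = c(-3000, 3000),
                                        ...) {
  which <- match.arg(which)
  if (is.null(x$observed_positions)) {
    abort("run positional_enrichment() with positions = TRUE to plot")
  }
  col <- if (which == "start") "rel_start" else "rel_end"
  breaks <- seq(window[1], window[2], by = binwidth)
  bin_counts <- function(v) {
    v <- v[v >= window[1] & v < window[2]]
    tabulate(findInterval(v, breaks), nbins = length(breaks) - 1L)
  }
  n_sim_sets <- length(x$null_positions[[col]]) / x$n_obs
  df <- dplyr::bind_rows(
    tibble(pos = head(breaks, -1L) + binwidth / 2,
           freq = bin_counts(x$observed_positions[[col]]),
           set = "observed"),
    tibble(pos = head(breaks, -1L) + binwidth / 2,
           freq = bin_counts(x$null_positions[[col]]) / n_sim_sets,
           set = "simulated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$freq,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge", width = binwidth * 0.9) +
    ggplot2::scale_fill_manual(values = c(observed = "firebrick",
                                          simulated = "steelblue")) +
    ggplot2::labs(x = sprintf("position relative to transcript %s (nt)", which),
                  y = "peak centers per bin", fill = NULL) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
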