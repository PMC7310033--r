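# ggplot2 figures for the main result types.

#' Plot a sliding-window diversity profile
#'
#' Draws pi against alignment position with the hotspot threshold line;
#' hotspot intervals (computed at `threshold`, or supplied) are shaded.
#'
#' @param profile A [sliding_window_pi()] result.
#' @param threshold Hotspot threshold drawn as a dashed line.
#' @param hotspots Optional [detect_hotspots()] tibble; computed when `NULL`.
#' @param regions Optional tibble (`region`, `start`, `end`) drawn as a rug.
#' @return A ggplot object.
#' @export
plot_window_profile <- function(profile, threshold = 0.006, hotspots = NULL,
                                regions = NULL) {
  hotspots <- hotspots %||% detect_hotspots(profile, threshold)
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$mid, y = .data$pi)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "alignment position (bp)", y = expression(pi)) +
    ggplot2::theme_minimal()
  if (nrow(hotspots) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = hotspots, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15)
  }
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_vline(xintercept = c(regions$start, max(regions$end)),
                                 linetype = "dotted", colour = "grey70")
  }
  p
}

#' @method autoplot plast_windows
#' @export
autoplot.plast_windows <- function(object, ...) plot_window_profile(object, ...)

#' Box plots of pairwise omega per gene
#'
#' The screening figure behind the per-gene selection summary: one box per
#' gene over the pairwise omega estimates (pairs with defined omega only),
#' ordered by mean omega.
#'
#' @param summary A [gene_selection_summary()] result (its `pairs` attribute
#'   holds the long table), or the long table itself.
#' @return A ggplot object.
#' @export
plot_omega <- function(summary) {
  long <- attr(summary, "pairs") %||% summary
  long <- long[long$status == "ok" & !is.na(long$omega), ]
  ord <- long %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(m = mean(.data$omega), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$m))
  long$gene <- factor(long$gene, levels = ord$gene)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$omega)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = expression(omega == Ka / Ks)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Repeat frequency bar chart
#'
#' Counts repeat loci by motif/unit length, split by region.
#'
#' @param loci An annotated [find_ssrs()]/[find_lsrs()] tibble with a
#'   `region` column (see [annotate_repeat_context()]).
#' @return A ggplot object.
#' @export
plot_repeat_frequency <- function(loci) {
  stopifnot("unit_len" %in% names(loci))
  d <- dplyr::count(loci, .data$unit_len,
                    region = if ("region" %in% names(loci)) .data$region else "all")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$unit_len), y = .data$n,
                                  fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "repeat unit length (bp)", y = "loci") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
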