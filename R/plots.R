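#' Volcano plot of a differential-expression result
#'
#' log2 fold change against -log10 p, with the calling thresholds drawn and
#' passing features coloured by direction.
#'
#' @param results A `cerna_de` tibble.
#' @param thresholds A [de_thresholds()] regime (default: the circRNA
#'   preset). The p-value line uses `max_p` when set, else `max_fdr`.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, thresholds = circ_de_thresholds()) {
  lfc <- base::log2(thresholds$min_linear_fc)
  p_cut <- thresholds$max_p %||% thresholds$max_fdr %||% 0.05
  called <- as_tibble(apply_thresholds(results, thresholds))
  df <- mutate(as_tibble(results),
               status = dplyr::case_when(
                 .data$feature_id %in% called$feature_id & .data$log2_fc > 0 ~ "up",
                 .data$feature_id %in% called$feature_id ~ "down",
                 TRUE ~ "not called"))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#27ae60",
                                            "not called" = "grey60")) +
    ggplot2::labs(x = "log2 fold change (treated vs control)",
                  y = expression(-log[10] ~ p), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ceRNA network
#'
#' Force-directed layout (igraph Fruchterman-Reingold, seeded for
#' reproducibility) with the three partitions shaped and coloured
#' separately.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_network <- function(object, ...) {
  g <- as_igraph_cerna(object)
  if (igraph::vcount(g) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty network"))
  }
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(x = xy[, 1], y = xy[, 2],
                  type = igraph::V(g)$type, id = igraph::V(g)$feature_id)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble(x = xy[el[, 1], 1], y = xy[el[, 1], 2],
                  xend = xy[el[, 2], 1], yend = xy[el[, 2], 2],
                  interaction = igraph::E(g)$interaction)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$interaction),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, colour = .data$type,
                                     shape = .data$type), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(circRNA = "#2980b9",
                                            miRNA = "grey40",
                                            mRNA = "#e67e22")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, shape = NULL, linetype = NULL)
}

#' Lollipop plot of hub scores
#'
#' @param object A `cerna_hubs` ranking from [rank_hubs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_hubs <- function(object, ...) {
  df <- mutate(as_tibble(object),
               node = factor(.data$node, levels = rev(.data$node)))
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$node)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score,
                                       yend = .data$node), colour = "grey70") +
    ggplot2::geom_point(colour = "#2980b9", size = 2.5) +
    ggplot2::labs(x = paste0("hub score (", attr(object, "method"), ")"),
                  y = NULL) +
    ggplot2::theme_minimal()
}
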