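#' Plot an anchor-aligned average occupancy profile
#'
#' @param profile Output of [average_profile()].
#' @param anchor_label Label for the zero offset.
#' @return A ggplot.
#' @export
plot_average_profile <- function(profile, anchor_label = "anchor") {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset,
                                        y = .data$occupancy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("position relative to %s (bp)", anchor_label),
                  y = "mean normalized occupancy")
}

#' Heatmap of signed K-S enrichment scores
#'
#' Tiles of `S_KS` (set shifted high = positive, red; low = negative, blue)
#' by feature and gene set; significant cells are outlined.
#'
#' @param enrichment Output of [ks_enrichment_table()].
#' @return A ggplot.
#' @export
plot_enrichment_heatmap <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$feature_id, y = .data$set_id,
                               fill = .data$S_KS)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = enrichment[which(enrichment$significant), ],
                       colour = "black", linewidth = 0.4, fill = NA) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey85") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "signed\nK-S score")
}

#' Scatter of in vivo versus intrinsic k-mer depletion
#'
#' @param rel Output of [relative_depletion()].
#' @param highlight Optional character vector of merged n-mer classes to
#'   label.
#' @return A ggplot.
#' @export
plot_relative_depletion <- function(rel, highlight = NULL) {
  g <- ggplot2::ggplot(rel, ggplot2::aes(x = .data$depletion_vitro,
                                         y = .data$depletion_vivo)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = "intrinsic (in-vitro-like) depletion score",
                  y = "in vivo depletion score")
  if (!is.null(highlight)) {
    g <- g + ggplot2::geom_point(data = rel[rel$nmer %in% highlight, ],
                                 colour = "red")
  }
  g
}
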