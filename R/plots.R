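# ggplot2 figures; every plot has a numeric backing table written by the
# pipeline, which is the quantitative surface — figures are for reading.

.category_scale <- function() {
  ggplot2::scale_fill_manual(values = c(Structural = "#1b9e77",
                                        Signaling = "#d95f02",
                                        Energy = "#7570b3"),
                             na.value = "grey70")
}

#' Bar plot of per-index log2 fold changes with delta-method error bars
#'
#' @param comparison A two-group table from [compare_indices()].
#' @param only_comparable Drop not-comparable rows (default TRUE).
#' @return A ggplot object.
#' @export
plot_index_summary <- function(comparison, only_comparable = TRUE) {
  df <- dplyr::filter(comparison, !only_comparable | .data$comparable)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$display_name, .data$log2fc),
                                   y = .data$log2fc, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$log2fc - .data$se_log2fc,
                                        ymax = .data$log2fc + .data$se_log2fc),
                           width = 0.3) +
    .category_scale() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log2 fold change (EXP / CTRL)", fill = "Function") +
    ggplot2::theme_minimal()
}

#' Three-panel functional volcano plot
#'
#' @inheritParams plot_index_summary
#' @return A ggplot object faceted by functional category.
#' @export
plot_volcano <- function(comparison) {
  df <- dplyr::filter(comparison, .data$comparable)
  pthr <- attr(comparison, "p_threshold") %||% 0.05
  fthr <- attr(comparison, "fc_threshold") %||% 1
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(pthr), linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-fthr, fthr), linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~category, nrow = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d7191c", `FALSE` = "grey40")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_bw()
}

#' Functional dominance bars (Structural / Signaling / Energy)
#'
#' @param dominance A table from [functional_dominance()].
#' @return A ggplot object.
#' @export
plot_dominance <- function(dominance) {
  ggplot2::ggplot(dominance, ggplot2::aes(.data$category, .data$dominance,
                                          fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    .category_scale() +
    ggplot2::labs(x = NULL, y = "dominance (sum |log2FC| of significant / n evaluated)") +
    ggplot2::theme_minimal()
}

#' Bubble plot of the top indices
#'
#' Shows the `top_n` indices with the smallest p-values; bubble size is
#' -log10 p, colour is the log2 fold change.
#'
#' @inheritParams plot_index_summary
#' @param top_n Number of indices (default 10).
#' @return A ggplot object.
#' @export
plot_bubble <- function(comparison, top_n = 10) {
  df <- comparison %>%
    dplyr::filter(.data$comparable) %>%
    dplyr::arrange(.data$p_value) %>%
    dplyr::slice_head(n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = 1, y = stats::reorder(.data$display_name, -.data$p_value),
                                   size = -log10(.data$p_value), colour = .data$log2fc)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "#2c7bb6", high = "#d7191c", mid = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, size = "-log10 p", colour = "log2FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' VIP score bar plot
#'
#' @param plsda An [index_plsda()] fit.
#' @param top_n Number of indices shown (default 20).
#' @return A ggplot object.
#' @export
plot_vip <- function(plsda, top_n = 20) {
  df <- tibble::tibble(index_id = names(plsda$vip), vip = unname(plsda$vip)) %>%
    dplyr::arrange(dplyr::desc(.data$vip)) %>%
    dplyr::slice_head(n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$index_id, .data$vip), .data$vip)) +
    ggplot2::geom_col(fill = "#2c7bb6") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP score") +
    ggplot2::theme_minimal()
}

#' Correlation heatmap of indices
#'
#' @param correlations A matrix from [index_correlations()].
#' @return A ggplot object.
#' @export
plot_correlations <- function(correlations) {
  df <- as.data.frame(as.table(correlations))
  names(df) <- c("index_a", "index_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$index_a, .data$index_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2c7bb6", high = "#d7191c", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' @describeIn index_pca Score plot (PC1 vs PC2), optionally coloured by
#'   group.
#' @param object An `fla_pca` object.
#' @param groups Optional `(sample_id, group)` table or named vector.
#' @param ... Ignored.
#' @export
autoplot.fla_pca <- function(object, groups = NULL, ...) {
  df <- data.frame(sample_id = object$sample_id,
                   PC1 = object$scores[, 1], PC2 = object$scores[, 2])
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$explained[1:2])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  if (!is.null(groups)) {
    g <- .normalize_groups(groups)
    df$group <- g$group[match(df$sample_id, g$sample_id)]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group))
  }
  p + ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_bw()
}

#' @describeIn index_plsda Score plot with 95% Hotelling confidence
#'   ellipses per group.
#' @param object An `fla_plsda` object.
#' @param ... Ignored.
#' @export
autoplot.fla_plsda <- function(object, ...) {
  df <- data.frame(sample_id = object$sample_id, group = object$groups,
                   comp1 = object$scores[, 1],
                   comp2 = object$scores[, min(2, ncol(object$scores))])
  ell <- purrr::map_dfr(unique(df$group), function(gr) {
    sub <- as.matrix(df[df$group == gr, c("comp1", "comp2")])
    if (nrow(sub) < 3) return(NULL)
    cbind(group = gr, hotelling_ellipse(sub))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$comp1, .data$comp2, colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_path(data = ell, ggplot2::aes(.data$x, .data$y, colour = .data$group),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "component 1", y = "component 2") +
    ggplot2::theme_bw()
}
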