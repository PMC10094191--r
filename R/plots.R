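#' Plot a correspondence-analysis map
#'
#' Genes and codons on two chosen axes, labelled and coloured by point
#' type; codons are additionally shaded by their third-position base class
#' (A/U versus G/C ending), the contrast that usually dominates axis 1.
#'
#' @param object A `codon_ca` object.
#' @param axes Which two axes to draw (default 1 and 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot codon_ca
#' @export
autoplot.codon_ca <- function(object, axes = c(1, 2), ...) {
  if (object$k < max(axes))
    stop("only ", object$k, " axes retained", call. = FALSE)
  ax <- paste0("axis", axes)
  third <- substr(object$codon_coords$codon, 3, 3)
  pts <- dplyr::bind_rows(
    object$gene_coords |> dplyr::rename(label = "gene_id") |>
      dplyr::mutate(what = "gene"),
    object$codon_coords |> dplyr::rename(label = "codon") |>
      dplyr::mutate(what = ifelse(third %in% c("G", "C"),
                                  "codon (G/C-ending)",
                                  "codon (A/U-ending)")))
  pct <- round(100 * object$inertia$fraction[axes], 1)
  ggplot2::ggplot(pts, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                    colour = .data$what)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5,
                       vjust = -0.7, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("Axis %d (%.1f%%)", axes[1], pct[1]),
                  y = sprintf("Axis %d (%.1f%%)", axes[2], pct[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' ENc versus GC3s with Wright's null curve
#'
#' The classic diagnostic: genes lying on the curve
#' ENc = 2 + s + 29 / (s^2 + (1 - s)^2), with s the GC3s fraction, are
#' consistent with codon usage shaped by third-position composition alone
#' (mutation pressure); genes falling well below it suggest additional
#' selection on codon choice.
#'
#' @param index_table A tibble with `gc3s` (percent) and `enc` columns,
#'   e.g. from [codon_usage_indices()].
#' @param label Optional column name for point labels (default `gene_id`
#'   if present).
#' @return A ggplot object.
#' @export
plot_enc_gc3s <- function(index_table, label = NULL) {
  curve <- tibble::tibble(s = seq(0.01, 0.99, by = 0.01))
  curve$enc <- pmin(2 + curve$s + 29 / (curve$s^2 + (1 - curve$s)^2), 61)
  p <- ggplot2::ggplot(index_table,
                       ggplot2::aes(.data$gc3s, .data$enc)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(100 * .data$s, .data$enc),
                       colour = "grey40", linetype = 2) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "GC3s (%)", y = "ENc") +
    ggplot2::ylim(15, 62) +
    ggplot2::theme_minimal()
  if (is.null(label) && "gene_id" %in% names(index_table))
    label <- "gene_id"
  if (!is.null(label))
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data[[label]]),
                                size = 2.5, vjust = -0.8)
  p
}

#' RSCU heatmap with genes ordered by clustering
#'
#' @param profiles An RSCU tibble over several genes.
#' @param linkage Linkage for the gene ordering (see [cluster_rscu()]).
#' @return A ggplot object.
#' @export
plot_rscu_heatmap <- function(profiles, linkage = "average") {
  h <- cluster_rscu(profiles, linkage = linkage)
  gene_levels <- h$labels[h$order]
  profiles |>
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = gene_levels)) |>
    ggplot2::ggplot(ggplot2::aes(.data$codon, .data$gene_id,
                                 fill = .data$rscu)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
}
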