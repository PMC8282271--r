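#' Heatmap of a stratified gene-based association scan
#'
#' Gene x (method, stratum) heatmap of -log10 p; strata without variants
#' (absent-marker records) are shown in grey, mirroring the standard
#' presentation of stratified kernel-test results.
#'
#' @param object a [gene_scan()] tibble.
#' @param alpha reference significance level drawn into the fill scale.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gene_scan
#' @export
autoplot.gene_scan <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) %>%
    mutate(
      analysis = paste(.data$method, .data$stratum, sep = "-"),
      neg_log10_p = -log10(.data$p)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$analysis, y = .data$gene,
                                   fill = .data$neg_log10_p)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "grey80",
                                  name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar-and-point display of sub-pathway enrichment
#'
#' Bars show significant / non-significant gene counts per sub-pathway;
#' points show -log10 of the enrichment p-value with a dashed line at the
#' significance threshold.
#'
#' @param object an [subpathway_enrichment()] result.
#' @param alpha significance threshold for the dashed reference line.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) %>%
    mutate(
      sub_pathway = factor(.data$sub_pathway,
                           levels = rev(.data$sub_pathway)),
      n_nonsig = .data$n_category - .data$n_category_significant
    ) %>%
    tidyr::pivot_longer(c("n_category_significant", "n_nonsig"),
                        names_to = "class", values_to = "count")
  scale_max <- max(c(df$count, object$neg_log10_p), na.rm = TRUE)
  ggplot2::ggplot(df) +
    ggplot2::geom_col(ggplot2::aes(x = .data$sub_pathway, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_point(
      data = as_tibble(object),
      ggplot2::aes(x = .data$sub_pathway, y = .data$neg_log10_p)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(n_category_significant = "#c0392b", n_nonsig = "#2980b9"),
      labels = c("significant", "not significant"), name = NULL) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = expression(count ~ "/" ~ -log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Plot a seed subnetwork
#'
#' Deterministic (seeded) force-directed layout with seed genes emphasised.
#'
#' @param object a [extract_subnetwork()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot subnetwork
#' @export
autoplot.subnetwork <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = tidy(object))
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                  is_seed = igraph::V(g)$is_seed)
  edges <- object$edges %>%
    left_join(nodes[c("node", "x", "y")], by = c(from = "node")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(nodes[c("node", "x", "y")], by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y),
                          color = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$is_seed,
                                     size = .data$is_seed)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#c0392b",
                                           `FALSE` = "#7f8c8d"),
                                name = "seed") +
    ggplot2::scale_size_manual(values = c(`TRUE` = 3, `FALSE` = 1.5),
                               guide = "none") +
    ggplot2::theme_void()
}
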