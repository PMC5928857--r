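#' Plot a scaffold graph
#'
#' Classical multidimensional scaling of one minus the cosine-similarity
#' weights lays the nodes out; retained edges are drawn, nodes are sized by
#' cell count and colored by phenotype, landmarks outlined.
#'
#' @param graph A `"scaffold_graph"`.
#' @return A ggplot object.
#' @export
plot_scaffold_graph <- function(graph) {
  nodes <- graph$nodes
  ids <- nodes$node_id
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  d[cbind(graph$edges$from, graph$edges$to)] <- 1 - graph$edges$weight
  d <- d + t(d)
  xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  edges <- graph$edges |> filter(.data$retained)
  edges$x <- nodes$x[match(edges$from, ids)]
  edges$y <- nodes$y[match(edges$from, ids)]
  edges$xend <- nodes$x[match(edges$to, ids)]
  edges$yend <- nodes$y[match(edges$to, ids)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$weight),
      color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_cells,
                   color = if ("phenotype" %in% names(nodes))
                     .data$phenotype else NULL,
                   shape = if ("landmark" %in% names(nodes))
                     .data$landmark else NULL)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::guides(alpha = "none") +
    ggplot2::labs(color = "phenotype", size = "cells", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Z ratios as a diverging bar chart
#'
#' @param zr Result of [z_ratio()].
#' @param cutoff Significance cutoff drawn as dashed lines, default 1.96.
#' @return A ggplot object.
#' @export
plot_zratio <- function(zr, cutoff = 1.96) {
  zr <- arrange(zr, .data$z_ratio)
  zr$feature <- factor(zr$feature, levels = zr$feature)
  ggplot2::ggplot(zr, ggplot2::aes(x = .data$feature, y = .data$z_ratio,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Z ratio (subtype I - II)") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot for a survival comparison
#'
#' @param object A `"survival_comparison"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survival_comparison
#' @export
autoplot.survival_comparison <- function(object, ...) {
  km <- object$km |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, survival = 1),
      .x)) |>
    ungroup()
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival",
                  subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-sample average neoantigen abundance by subtype
#'
#' @param abundance Result of [average_neoantigen_abundance()].
#' @param subtypes Tibble `sample_id`, `subtype`.
#' @return A ggplot object.
#' @export
plot_abundance <- function(abundance, subtypes) {
  d <- inner_join(abundance, subtypes, by = "sample_id") |>
    filter(!is.na(.data$mean_auc))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subtype, y = .data$mean_auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~mhc_class,
                        labeller = ggplot2::as_labeller(
                          c(I = "MHC-I", II = "MHC-II"))) +
    ggplot2::labs(x = "TiME subtype", y = "average neoantigen abundance (AUC)") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of signature classification scores
#'
#' @param calls Result of [classify_samples()].
#' @return A ggplot object.
#' @export
plot_signature_scores <- function(calls) {
  calls <- arrange(calls, dplyr::desc(.data$score))
  calls$sample_id <- factor(calls$sample_id, levels = calls$sample_id)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$sample_id, y = .data$score,
                                      fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "cor(good) - cor(bad)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
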