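#' Dot plot of paired differences per protein
#'
#' One point per patient and protein: the log2 excision-minus-core
#' difference, coloured by surgery type when metadata is supplied.
#'
#' @param diffs difference tibble from [difference_matrix()].
#' @param samples optional lane metadata (for surgery colouring).
#' @return a ggplot object.
#' @export
plot_paired_differences <- function(diffs, samples = NULL) {
  d <- diffs
  if (!is.null(samples)) {
    d <- dplyr::left_join(
      d, dplyr::distinct(samples, .data$patient_id, .data$surgery),
      by = "patient_id")
  } else {
    d$surgery <- "unknown"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$protein, y = .data$difference,
                                  colour = .data$surgery)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "log2(excision) - log2(core)",
                  colour = "surgery") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Scatter plot of panel expression against IHC score
#'
#' One panel per protein; points coloured by specimen type, with the pooled
#' Spearman rho annotated from a concordance result if given.
#'
#' @param expr log2 `npx_matrix` (no-IgG branch).
#' @param ihc IHC record tibble.
#' @param samples lane metadata tibble.
#' @param mapping mapping tibble (default [default_ihc_mapping()]).
#' @return a ggplot object.
#' @export
plot_concordance <- function(expr, ihc, samples,
                             mapping = default_ihc_mapping()) {
  meta <- canonical_lanes(samples)
  values <- unclass(expr)
  d <- ihc |>
    dplyr::inner_join(mapping, by = "protein") |>
    dplyr::filter(.data$target %in% rownames(values)) |>
    dplyr::inner_join(meta, by = c("patient_id", "specimen")) |>
    dplyr::mutate(expression = values[cbind(.data$target, .data$lane_id)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expression, y = .data$value,
                                  colour = .data$specimen)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~protein, scales = "free") +
    ggplot2::labs(x = "log2 normalized counts", y = "IHC score",
                  colour = "specimen") +
    ggplot2::theme_minimal()
}

#' Heatmap of the two-way clustering
#'
#' Tile heatmap of the mean-centered log2 matrix with rows and columns in
#' dendrogram order.
#'
#' @param object an `"npx_clustering"` from [two_way_cluster()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.npx_clustering <- function(object, ...) {
  m <- tidy(object$scaled)
  m$probe_id <- factor(m$probe_id, levels = object$rows$order)
  m$lane_id <- factor(m$lane_id, levels = object$cols$order)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$lane_id, y = .data$probe_id,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "log2 diff\nfrom protein mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
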