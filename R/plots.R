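#' Plot a hallmark enrichment table
#'
#' Log2 fold-change per hallmark, signed toward the enriched class, ordered
#' by AHo position.
#'
#' @param hallmarks Hallmark tibble (e.g. [nbframe_hallmarks()] or
#'   [discover_hallmarks()] output).
#' @return A ggplot object.
#' @export
plot_hallmarks <- function(hallmarks) {
  df <- dplyr::mutate(
    hallmarks,
    slot = factor(paste0(.data$position, .data$aa),
                  levels = unique(paste0(.data$position, .data$aa)[order(.data$position)])),
    enriched_in = ifelse(.data$log2fc >= 0, "kinked", "extended")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slot, y = .data$log2fc,
                                   fill = .data$enriched_in)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$region),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "framework hallmark (AHo position + residue)",
                  y = "log2 fold change (kinked / extended)",
                  fill = "enriched in") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot blueprint probabilities with call thresholds
#'
#' @param calls Tibble with a `p_kinked` column (e.g. output of
#'   [classify_structure()] or [classify_sequence()]).
#' @param scheme Threshold scheme drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_blueprint_calls <- function(calls, scheme = "deployment") {
  th <- if (scheme == "deployment") c(0.3, 0.7) else c(0.25, 0.55)
  calls$label <- call_blueprint(calls$p_kinked, scheme)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$p_kinked, fill = .data$label)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05), colour = "grey30") +
    ggplot2::geom_vline(xintercept = th, linetype = "dashed") +
    ggplot2::labs(x = "P(kinked)", y = "structures", fill = "call") +
    ggplot2::theme_minimal()
}

#' Plot region-stratified RMSD results
#'
#' @param rmsd Tibble from [region_rmsd()], optionally row-bound over many
#'   structures with an `id` column.
#' @return A ggplot object.
#' @export
plot_region_rmsd <- function(rmsd) {
  rmsd$region <- factor(rmsd$region, levels = unique(rmsd$region))
  ggplot2::ggplot(rmsd, ggplot2::aes(x = .data$region, y = .data$rmsd)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "backbone RMSD after framework superposition (Å)") +
    ggplot2::theme_minimal()
}
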