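#' Barcode rank (knee) plot
#'
#' Ranks barcodes by count on log-log axes; whitelisted barcodes are
#' highlighted when a whitelist is supplied. The knee separates true cells
#' from low-count erroneous barcodes.
#'
#' @param counts Tibble with columns `cb`, `n` (see [count_barcodes()]).
#' @param whitelist Optional [build_whitelist()] result.
#' @return A ggplot object.
#' @export
plot_barcode_ranks <- function(counts, whitelist = NULL) {
  df <- counts |>
    dplyr::arrange(dplyr::desc(.data$n), .data$cb) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      whitelisted = if (is.null(whitelist)) NA else .data$cb %in% whitelist$cb
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$n))
  p <- if (is.null(whitelist)) {
    p + ggplot2::geom_line()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$whitelisted),
                            size = 0.8) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey60"),
        name = "whitelisted"
      )
  }
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "read count",
                  title = "Barcode rank plot")
}

#' @describeIn run_pipeline Bar chart of per-read outcomes
#'   (mapped and the typed discard reasons).
#' @param object A `pipeline_run`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pipeline_run <- function(object, ...) {
  s <- object$stats
  df <- tibble::tibble(
    status = base::factor(MAP_STATUSES, levels = MAP_STATUSES),
    reads = vapply(MAP_STATUSES, function(k) as.numeric(s[[k]]), numeric(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$reads)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "reads", title = "Read fates")
}

#' @describeIn assemble_matrix Heatmap of molecule counts for the
#'   highest-count cells and genes.
#' @param object A `gene_cell_matrix`.
#' @param max_cells,max_genes Display caps.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_cell_matrix <- function(object, max_cells = 50,
                                      max_genes = 50, ...) {
  df <- tidy(object)
  top_cells <- df |>
    dplyr::summarise(total = sum(.data$count), .by = "cb") |>
    dplyr::slice_max(.data$total, n = max_cells, with_ties = FALSE)
  top_genes <- df |>
    dplyr::summarise(total = sum(.data$count), .by = "gene_id") |>
    dplyr::slice_max(.data$total, n = max_genes, with_ties = FALSE)
  df <- df |>
    dplyr::filter(.data$cb %in% top_cells$cb,
                  .data$gene_id %in% top_genes$gene_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$cb,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "gene", y = "cell", fill = "molecules") +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.ticks = ggplot2::element_blank())
}
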