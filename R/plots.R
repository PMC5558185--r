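#' Plot a disease score table as a stacked breakdown bar chart
#'
#' One bar per disease (rank order, highest score on top), stacked by
#' per-phenotype contribution — the graphical "score breakdown by
#' phenotype" of the result table.
#'
#' @param object A `pdr_scores` object.
#' @param top_n Number of top-ranked diseases shown (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pdr_scores <- function(object, top_n = 15, ...) {
  dat <- tidy.pdr_scores(object) |>
    dplyr::filter(.data$rank <= top_n) |>
    dplyr::mutate(label = sprintf("%d. %s", .data$rank, .data$disease_name))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$contribution,
    y = stats::reorder(.data$label, -.data$rank),
    fill = .data$phenotype
  )) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "score (sum of phenotype contributions)", y = NULL,
                  fill = "phenotype") +
    ggplot2::theme_minimal()
}

#' Plot top-k recovery fractions of a planted-case experiment
#'
#' @param object A `pdr_recovery` object.
#' @param ... Unused.
#' @return A ggplot object with binomial standard-error bars.
#' @export
autoplot.pdr_recovery <- function(object, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       k = factor(.data$k, levels = sort(unique(.data$k))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$fraction - .data$se),
      ymax = pmin(1, .data$fraction + .data$se)
    ), width = 0.2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "top-k cutoff", y = "fraction of cases recovered") +
    ggplot2::theme_minimal()
}

#' Plot an evidence subnetwork
#'
#' Simple layered layout (genes, disease, intermediates, phenotypes) of the
#' subgraph returned by [evidence_subnetwork()]; for publication-grade
#' network figures export the tables with [write_subnetwork()] and use a
#' dedicated viewer.
#'
#' @param subnetwork A list from [evidence_subnetwork()].
#' @return A ggplot object.
#' @export
plot_subnetwork <- function(subnetwork) {
  layer_of <- c(gene = 1, disease = 2, intermediate = 3, phenotype = 4)
  nodes <- subnetwork$nodes |>
    dplyr::mutate(y = layer_of[.data$category]) |>
    dplyr::group_by(.data$y) |>
    dplyr::mutate(x = seq_along(.data$id) - (dplyr::n() + 1) / 2) |>
    dplyr::ungroup()
  seg <- subnetwork$edges |>
    dplyr::left_join(dplyr::select(nodes, "id", x0 = "x", y0 = "y"),
                     by = c(source = "id")) |>
    dplyr::left_join(dplyr::select(nodes, "id", x1 = "x", y1 = "y"),
                     by = c(target = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$kind),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$category),
      size = 5
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(
      gene = "darkorange", disease = "forestgreen",
      phenotype = "steelblue", intermediate = "grey60"
    )) +
    ggplot2::theme_void()
}
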