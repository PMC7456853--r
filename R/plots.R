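#' Volcano plot of a differential-expression result
#'
#' @param de a DE tibble (from [call_de_mirnas()] or [call_de_proteins()])
#'   with `log2fc`, `p` and `significant` columns.
#' @return a ggplot object.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (ablated / intact)",
                  y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' @describeIn regulatory_network bipartite plot: miRNAs on the left,
#'   proteins on the right, node colour by regulation direction.
#' @param object a `regulatory_network`.
#' @export
autoplot.regulatory_network <- function(object, ...) {
  nodes <- object$nodes |>
    dplyr::arrange(.data$kind, .data$id) |>
    dplyr::mutate(x = ifelse(.data$kind == "miRNA", 0, 1)) |>
    dplyr::mutate(y = seq_len(dplyr::n()) / dplyr::n(), .by = "kind")
  pos <- nodes[, c("id", "x", "y")]
  edges <- object$edges |>
    dplyr::left_join(pos, by = c(mirna_id = "id")) |>
    dplyr::left_join(pos, by = c(protein_id = "id"),
                     suffix = c("", "_p"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_p, yend = .data$y_p),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$direction,
                                     shape = .data$kind), size = 2) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue")) +
    ggplot2::theme_void()
}

#' Plot comparative-CT relative expression over time
#'
#' @param rq a tibble from [relative_expression()].
#' @return a ggplot object.
#' @export
plot_timecourse <- function(rq) {
  ggplot2::ggplot(rq, ggplot2::aes(x = .data$time_h, y = .data$rq_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$rq_mean - .data$rq_sd,
      ymax = .data$rq_mean + .data$rq_sd)) +
    ggplot2::labs(x = "hours post treatment",
                  y = expression(2^{-Delta * Delta * C[T]})) +
    ggplot2::theme_minimal()
}

#' @describeIn anova_tukey bar plot of group means with compact letters.
#' @param object a `tukey_result`.
#' @export
autoplot.tukey_result <- function(object, ...) {
  m <- object$means
  m$letters <- object$letters[as.character(m$group)]
  ggplot2::ggplot(m, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean + .data$sd),
                       vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "relative luciferase activity") +
    ggplot2::theme_minimal()
}
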