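#' Plot a guide-gene correlation network
#'
#' Draws the positive-edge network with a deterministic circular layout;
#' edge width tracks the correlation coefficient (the closer r is to 1 the
#' thicker the line) and node colour the pathway branch.
#'
#' @param object A `correlation_network`.
#' @param label `"role"` (default) or `"gene_id"` node labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_network <- function(object, label = c("role", "gene_id"),
                                         ...) {
  label <- match.arg(label)
  nodes <- object$nodes
  k <- nrow(nodes)
  theta <- 2 * pi * (seq_len(k) - 1L) / k
  layout <- tibble(role = nodes$role, gene_id = nodes$gene_id,
                   branch = nodes$branch,
                   x = cos(theta), y = sin(theta))
  pos <- object$edges[object$edges$positive, ]
  seg <- dplyr::bind_cols(
    pos["r"],
    layout[match(pos$role_a, layout$role), c("x", "y")],
    setNames(layout[match(pos$role_b, layout$role), c("x", "y")],
             c("xend", "yend"))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$r),
      colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$branch), size = 4
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                   label = .data[[label]]),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.8), limits = c(0, 1)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(
      linewidth = "Pearson r", colour = "branch",
      title = sprintf("Positive co-expression edges (r > %g, P < %g)",
                      object$config$r_min, object$config$p_max)
    )
}

#' Plot candidate link counts
#'
#' Bar chart of positive guide links per retained candidate, with the
#' retention threshold marked.
#'
#' @param object A `candidate_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candidate_screen <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- tidy(object)
  df$gene_id <- factor(df$gene_id, levels = rev(df$gene_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_positive_links,
                                   y = .data$gene_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = cfg$min_links - 0.5, linetype = 2) +
    ggplot2::labs(x = "positive links to guide genes", y = NULL,
                  title = "Guilt-by-association candidate screen") +
    ggplot2::theme_minimal()
}

#' Plot qPCR fold changes
#'
#' Per-sample 2^-ddCt fold changes on a log2 axis with replicate-SD error
#' bars (propagated on the dCt scale, shown as a fold-change interval).
#'
#' @param object A `fold_change_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fold_change_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$fold_change,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 2^(-(.data$delta_delta_ct + .data$sd)),
                   ymax = 2^(-(.data$delta_delta_ct - .data$sd))),
      width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "fold change (2^-ddCt)",
                  title = paste0(attr(object, "target"), " relative to ",
                                 attr(object, "reference"))) +
    ggplot2::theme_minimal()
}
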