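#' Plot a network-size distribution with its power-law fit
#'
#' Log-log scatter of frequency against network size with the fitted
#' `f(x) = k x^-n` line.
#'
#' @param object A `packnet_powerlaw` from [size_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot packnet_powerlaw
#' @export
autoplot.packnet_powerlaw <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = dplyr::mutate(df, fitted = object$k * .data$size^-object$exponent),
      ggplot2::aes(y = .data$fitted), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "network size (nodes)", y = "frequency",
                  title = sprintf("Power-law fit, n = %.2f", object$exponent)) +
    ggplot2::theme_minimal()
}

#' Plot observed vs expected angular bin occupancies
#'
#' @param object A `chi2_angles` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chi2_angles
#' @export
autoplot.chi2_angles <- function(object, ...) {
  df <- tidyr::pivot_longer(object$table, c("observed", "expected"),
                            names_to = "kind", values_to = "count")
  df$bin <- sprintf("%g-%g", df$bin_lo, df$bin_hi)
  df$bin <- factor(df$bin, levels = unique(df$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "angle bin (degrees)", y = "count",
                  title = sprintf("X2 = %.1f (df = %d)", object$statistic,
                                  object$df)) +
    ggplot2::theme_minimal()
}

#' Plot fold-compatibility scores
#'
#' snet against dnet for every candidate; native-like candidates sit towards
#' the upper-left (high similarity, low distance).
#'
#' @param object A `fold_scores` result from [score_candidates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fold_scores
#' @export
autoplot.fold_scores <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$dnet, y = .data$snet)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "dnet (topological distance)",
                  y = "snet (conserved-link fraction)") +
    ggplot2::theme_minimal()
}

#' Draw a contact network
#'
#' Simple ggplot rendering with a deterministic force-directed layout; edge
#' width follows weight.
#'
#' @param net An igraph contact network.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, seed = 1) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  xy <- igraph::layout_with_fr(net)
  nodes <- tibble::tibble(
    x = xy[, 1], y = xy[, 2],
    name = igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  )
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight %||% rep(1, nrow(el))
  edges <- tibble::tibble(
    x = xy[el[, 1], 1], y = xy[el[, 1], 2],
    xend = xy[el[, 2], 1], yend = xy[el[, 2], 2],
    weight = w
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey50") +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 6,
                        colour = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name), size = 3) +
    ggplot2::theme_void()
}
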