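#' Plot rank-probability decay
#'
#' PageRank probability against the rank index on log-log axes, the standard
#' view of the (approximately algebraic) decay of centrality probabilities.
#'
#' @param object A `rank_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.rank_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank index K", y = "probability P") +
    ggplot2::theme_minimal()
}

#' Plot a complex Google-matrix spectrum
#'
#' Eigenvalues in the complex plane inside the unit circle, colored by the
#' inverse participation ratio of the corresponding eigenvector.
#'
#' @param object A `spectrum_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.spectrum_result <- function(object, ...) {
  d <- tidy(object)
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- tibble::tibble(x = cos(th), y = sin(th))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y),
                       linetype = 2, colour = "grey60", inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$ipr), size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = expression(Re(lambda)), y = expression(Im(lambda)),
                  colour = "IPR") +
    ggplot2::theme_minimal()
}

#' Plot a two-condition rank comparison
#'
#' Scatter of per-node log10 rank-index ratios (PageRank axis vs CheiRank
#' axis when available), with dashed guides at plus and minus two standard
#' deviations of each axis.
#'
#' @param object A `rank_comparison`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.rank_comparison <- function(object, ...) {
  d <- tidy(object)
  if (!"log_kstar_ratio" %in% names(d)) {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log_k_ratio)) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::labs(x = expression(log[10](K[B] / K[A])), y = "nodes")
  } else {
    s <- object$sigma
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log_k_ratio,
                                         y = .data$log_kstar_ratio)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.6) +
      ggplot2::geom_vline(xintercept = c(-2, 2) * s[["k"]], linetype = 2,
                          colour = "grey50") +
      ggplot2::geom_hline(yintercept = c(-2, 2) * s[["k_star"]], linetype = 2,
                          colour = "grey50") +
      ggplot2::labs(x = expression(log[10](K[B] / K[A])),
                    y = expression(log[10]("K*"[B] / "K*"[A])))
  }
  p + ggplot2::theme_minimal()
}

#' Heatmap of reduced-Google-matrix components
#'
#' @param object A `reduced_google`.
#' @param component One of `"g_rr"`, `"g_pr"`, `"g_qr"`, `"g_qrnd"`,
#'   `"g_qrd"` or `"g_r"` (the full reduced matrix).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.reduced_google <- function(object, component = "g_qrnd", ...) {
  m <- if (component == "g_r") reduced_matrix(object) else object[[component]]
  d <- tibble::tibble(
    source = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    target = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    value = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source, y = .data$target,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "source (column)", y = "target (row)", fill = component) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
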