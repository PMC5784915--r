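#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a rank result
#'
#' @param x A `rank_result` from [pagerank()] or [cheirank()].
#' @param ... Ignored.
#' @return A tibble with one row per node: `node`, `p`, `k`.
#' @export
tidy.rank_result <- function(x, ...) {
  tibble::tibble(node = x$nodes, p = unname(x$p), k = x$k)
}

#' @rdname tidy.rank_result
#' @export
glance.rank_result <- function(x, ...) {
  tibble::tibble(n = length(x$p), alpha = x$alpha,
                 iterations = x$iterations, residual = x$residual)
}

#' Tidy a reduced Google matrix
#'
#' Long format: one row per (source, target, component) entry.
#'
#' @param x A `reduced_google`.
#' @param components Which components to include.
#' @param ... Ignored.
#' @return A tibble with columns `source`, `target`, `component`, `value`
#'   (column-stochastic convention: `source` indexes the column).
#' @export
tidy.reduced_google <- function(x, components = c("g_rr", "g_pr", "g_qr"), ...) {
  purrr::map_dfr(components, function(cm) {
    m <- x[[cm]]
    tibble::tibble(
      source = rep(colnames(m), each = nrow(m)),
      target = rep(rownames(m), times = ncol(m)),
      component = cm, value = as.vector(m)
    )
  })
}

#' @rdname tidy.reduced_google
#' @export
glance.reduced_google <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_r = length(x$subset), alpha = x$alpha,
    lambda_c = x$lambda_c, one_minus_lambda_c = x$one_minus_lambda_c,
    w_rr = x$weights[["w_rr"]], w_pr = x$weights[["w_pr"]],
    w_qr = x$weights[["w_qr"]],
    negative_weight = x$negative_weight, n_terms = x$n_terms
  )
}

#' Tidy a spectrum result
#'
#' @param x A `spectrum_result` from [leading_spectrum()].
#' @param ... Ignored.
#' @return A tibble with columns `index`, `re`, `im`, `mod`, `ipr`.
#' @export
tidy.spectrum_result <- function(x, ...) {
  tibble::tibble(index = seq_along(x$values),
                 re = Re(x$values), im = Im(x$values),
                 mod = Mod(x$values), ipr = x$ipr)
}

#' Tidy a rank comparison
#'
#' @param x A `rank_comparison` from [compare_ranks()].
#' @param ... Ignored.
#' @return The per-node log-ratio tibble.
#' @export
tidy.rank_comparison <- function(x, ...) x$table

#' @rdname tidy.rank_comparison
#' @export
glance.rank_comparison <- function(x, ...) {
  out <- tibble::tibble(n_common = nrow(x$table), sigma_k = x$sigma[["k"]])
  if ("k_star" %in% names(x$sigma)) out$sigma_k_star <- x$sigma[["k_star"]]
  out
}
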