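#' Compare rank indexes between two conditions
#'
#' For every node present in both rank results, computes the decimal
#' logarithm of the rank-index ratios log10(K_B / K_A) (PageRank axis) and,
#' when both results carry them, log10(K*_B / K*_A) — ranks computed on each
#' full network, as in a normal-versus-cancer comparison.  A node whose
#' incoming regulation weakens in condition B has a growing K index and thus
#' a positive log-ratio.  Nodes deviating from zero by one or two standard
#' deviations of each axis are returned, both tails separately, for
#' enrichment-style follow-up.
#'
#' @param rank_a,rank_b `rank_result` objects (condition A and B).
#' @param rank_star_a,rank_star_b Optional CheiRank `rank_result`s for the
#'   second axis.
#' @return A `rank_comparison`: list with `table` (tibble: `node`,
#'   `log_k_ratio`, and `log_kstar_ratio` when available), `sigma` (named sd
#'   per axis) and `selected` (nested list
#'   `selected[[axis]][[c("1sigma","2sigma")]][[c("up","down")]]` of node
#'   labels).
#' @export
compare_ranks <- function(rank_a, rank_b, rank_star_a = NULL, rank_star_b = NULL) {
  stopifnot(inherits(rank_a, "rank_result"), inherits(rank_b, "rank_result"))
  common <- intersect(rank_a$nodes, rank_b$nodes)
  if (length(common) == 0) stop("the two rank results share no nodes", call. = FALSE)
  ka <- rank_a$k[match(common, rank_a$nodes)]
  kb <- rank_b$k[match(common, rank_b$nodes)]
  tab <- tibble::tibble(node = common, log_k_ratio = log10(kb / ka))
  sigma <- c(k = stats::sd(tab$log_k_ratio))
  if (!is.null(rank_star_a) && !is.null(rank_star_b)) {
    ksa <- rank_star_a$k[match(common, rank_star_a$nodes)]
    ksb <- rank_star_b$k[match(common, rank_star_b$nodes)]
    tab$log_kstar_ratio <- log10(ksb / ksa)
    sigma <- c(sigma, k_star = stats::sd(tab$log_kstar_ratio))
  }
  pick <- function(x, s) {
    lapply(c(`1sigma` = 1, `2sigma` = 2), function(m) {
      list(up = tab$node[x > m * s], down = tab$node[x < -m * s])
    })
  }
  selected <- list(k = pick(tab$log_k_ratio, sigma[["k"]]))
  if ("k_star" %in% names(sigma)) {
    selected$k_star <- pick(tab$log_kstar_ratio, sigma[["k_star"]])
  }
  structure(list(table = tab, sigma = sigma, selected = selected),
            class = "rank_comparison")
}

#' @exportS3Method base::print
print.rank_comparison <- function(x, ...) {
  cat("<rank_comparison> ", nrow(x$table), " common nodes; sigma: ",
      paste(names(x$sigma), format(x$sigma, digits = 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' PageRank mass captured by a node subset
#'
#' Sigma_P = ||P_r||_1, the global PageRank probability concentrated on the
#' subset; approximately equal to 1 - lambda_c of the corresponding
#' scattering block.
#'
#' @param rank A `rank_result` for the full network.
#' @param subset Character labels (or `gene_set`).
#' @return Scalar in \[0, 1\].
#' @export
subset_pagerank_mass <- function(rank, subset) {
  stopifnot(inherits(rank, "rank_result"))
  if (inherits(subset, "gene_set")) subset <- subset$labels
  sum(rank$p[match(intersect(subset, rank$nodes), rank$nodes)])
}

#' Infer hidden interactions from the reduced Google matrix
#'
#' Scores indirect (hidden) directed relations between distinct subset
#' members by the off-diagonal part of the hidden component, `g_qrnd`; pairs
#' with score strictly above `threshold` (default 0.01) are retained.  The
#' diagonal part (probability of returning to the same node) is never
#' reported as an interaction.  With a second condition, each retained pair
#' is classified `common` (above threshold in both), `emergent_in_b` or
#' `disappearing_in_b`; with one condition all pairs are `common`.
#'
#' @param rgm_a A `reduced_google` (condition A).
#' @param rgm_b Optional `reduced_google` for condition B; must share
#'   `rgm_a`'s subset ordering.
#' @param threshold Retention threshold on G_qrnd (>= 0).
#' @param top_k Keep at most this many pairs per class, ranked by score
#'   (score in B for emergent pairs, in A otherwise).  `Inf` keeps all.
#' @return A `hidden_interactions` tibble with columns `source`, `target`,
#'   `score_a`, `score_b` (NA when `rgm_b` absent), `class`; attributes
#'   `threshold` and `subset`.
#' @export
infer_hidden <- function(rgm_a, rgm_b = NULL, threshold = 0.01, top_k = Inf) {
  stopifnot(inherits(rgm_a, "reduced_google"), threshold >= 0)
  if (!is.null(rgm_b)) {
    stopifnot(inherits(rgm_b, "reduced_google"))
    if (!identical(rgm_a$subset, rgm_b$subset)) {
      stop("the two reduced matrices have different subset orderings",
           call. = FALSE)
    }
  }
  labs <- rgm_a$subset
  nr <- length(labs)
  off <- which(row(rgm_a$g_qrnd) != col(rgm_a$g_qrnd))
  # column-stochastic convention: entry [i, j] is a transition j -> i
  src <- labs[col(rgm_a$g_qrnd)[off]]
  tgt <- labs[row(rgm_a$g_qrnd)[off]]
  sa <- rgm_a$g_qrnd[off]
  sb <- if (is.null(rgm_b)) NA_real_ else rgm_b$g_qrnd[off]
  in_a <- sa > threshold
  in_b <- if (is.null(rgm_b)) in_a else sb > threshold
  keep <- in_a | in_b
  cls <- dplyr::case_when(
    in_a & in_b ~ "common",
    !in_a & in_b ~ "emergent_in_b",
    in_a & !in_b ~ "disappearing_in_b",
    TRUE ~ NA_character_
  )
  tab <- tibble::tibble(source = src[keep], target = tgt[keep],
                        score_a = sa[keep],
                        score_b = if (is.null(rgm_b)) NA_real_ else sb[keep],
                        class = cls[keep])
  score_for_rank <- ifelse(tab$class == "emergent_in_b", tab$score_b, tab$score_a)
  tab <- tab[order(tab$class, -score_for_rank), ]
  if (is.finite(top_k)) {
    tab <- tab |>
      dplyr::group_by(.data$class) |>
      dplyr::slice_head(n = top_k) |>
      dplyr::ungroup()
  }
  structure(tab, class = c("hidden_interactions", class(tab)),
            threshold = threshold, subset = labs)
}

#' Local PageRank within a subset from its reduced matrix
#'
#' The leading right eigenvector (eigenvalue 1) of
#' G_R = g_rr + g_pr + g_qr, normalized to sum 1, gives the local PageRank
#' probabilities of the subset nodes, ranked descending with the standard
#' tie-break (ascending label).  By the fixed-point property of G_R these
#' coincide, up to normalization, with the global PageRank restricted to the
#' subset.
#'
#' @param rgm A `reduced_google`.
#' @return A tibble with columns `node`, `p_local`, `k_local`.
#' @export
local_pagerank_ranks <- function(rgm) {
  stopifnot(inherits(rgm, "reduced_google"))
  GR <- reduced_matrix(rgm)
  nr <- nrow(GR)
  if (nr == 1) {
    return(tibble::tibble(node = rgm$subset, p_local = 1, k_local = 1L))
  }
  e <- eigen(GR)
  i <- which.min(Mod(e$values - 1))
  if (Mod(e$values[i] - 1) > 1e-6) {
    stop("no eigenvalue of G_R close to 1 (nearest: ",
         format(e$values[i]), ")", call. = FALSE)
  }
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  tibble::tibble(node = rgm$subset, p_local = v,
                 k_local = rank_index(v, rgm$subset))
}

#' Weak-connectivity summary of a subset network
#'
#' Component accounting with edge direction ignored: the size of the largest
#' connected component, the number of nodes in components of size at least
#' two, and the number of orphan (isolated) nodes.  When inferred hidden
#' edges are supplied, the summary is recomputed on direct + hidden edges
#' and the gain in largest-component membership is reported.
#'
#' @param nodes Character vector of subset node labels.
#' @param direct_edges Data frame with columns `from`/`to` (or
#'   `source`/`target`) restricted to `nodes`.
#' @param hidden_edges Optional data frame in the same form (e.g. an
#'   [infer_hidden()] result).
#' @return A one-row tibble: `lcc_size`, `n_connected`, `n_orphan`, plus
#'   `lcc_size_with_hidden` and `lcc_gain` when hidden edges are given.
#' @export
connectivity_summary <- function(nodes, direct_edges, hidden_edges = NULL) {
  norm_edges <- function(e) {
    if (is.null(e) || nrow(as.data.frame(e)) == 0) {
      return(data.frame(from = character(), to = character()))
    }
    e <- as.data.frame(e)
    if (all(c("source", "target") %in% names(e))) {
      e <- data.frame(from = e$source, to = e$target)
    }
    e[, c("from", "to")]
  }
  comp_stats <- function(edges) {
    bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(bad) > 0) {
      stop("edges reference nodes outside the listed set: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
    cs <- igraph::components(g)$csize
    c(lcc = if (length(cs)) max(cs) else 0L,
      connected = sum(cs[cs >= 2]), orphan = sum(cs == 1))
  }
  direct_edges <- norm_edges(direct_edges)
  st <- comp_stats(direct_edges)
  out <- tibble::tibble(lcc_size = st[["lcc"]], n_connected = st[["connected"]],
                        n_orphan = st[["orphan"]])
  if (!is.null(hidden_edges)) {
    both <- rbind(direct_edges, norm_edges(hidden_edges))
    st2 <- comp_stats(both)
    out$lcc_size_with_hidden <- st2[["lcc"]]
    out$lcc_gain <- st2[["lcc"]] - st[["lcc"]]
  }
  out
}

#' Shortest and second-shortest directed paths
#'
#' All directed simple paths of minimal length L from `src` to `dst`, and
#' all of length L + 1 ("second-shortest": the lengths attained once an edge
#' of a shortest path is removed).  Used to explain which global-network
#' cascades carry an inferred hidden interaction.
#'
#' @param net A [directed_network()].
#' @param src,dst Node labels.
#' @return A list with `shortest` and `second_shortest` (each a list of
#'   label vectors, possibly empty) and logical `found`.
#' @export
short_paths <- function(net, src, dst) {
  stopifnot(inherits(net, "directed_network"))
  if (!all(c(src, dst) %in% net$nodes)) {
    stop("src and dst must be network nodes", call. = FALSE)
  }
  g <- as_igraph(net)
  d <- igraph::distances(g, v = src, to = dst, mode = "out")[1, 1]
  if (!is.finite(d)) {
    return(list(shortest = list(), second_shortest = list(), found = FALSE))
  }
  as_labels <- function(p) igraph::V(g)$name[as.integer(p)]
  sp <- igraph::all_shortest_paths(g, from = src, to = dst, mode = "out")$vpaths
  shortest <- lapply(sp, as_labels)
  all_next <- igraph::all_simple_paths(g, from = src, to = dst,
                                       mode = "out", cutoff = d + 1)
  second <- Filter(function(p) length(p) == d + 2, lapply(all_next, as_labels))
  list(shortest = shortest, second_shortest = unname(second), found = TRUE)
}
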