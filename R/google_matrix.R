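#' Build the column-stochastic transition model of a directed network
#'
#' Constructs the matrix of Markov transitions S from the 0/1 adjacency
#' A (A[i, j] = 1 when node j points to node i): column j of S is
#' A[, j] / k_out(j) when node j has outgoing links, and uniform 1/N when it
#' has none (dangling node).  The Google matrix G = alpha * S + (1 - alpha)/N
#' is never stored densely; the model is the contract "apply G to a vector"
#' (see [apply_google()]).  `alpha` is the damping factor: the probability of
#' following links rather than teleporting uniformly.
#'
#' @param net A [directed_network()] with at least one node.
#' @param alpha Damping factor in (0, 1); default 0.85, the value standard
#'   for directed-network centrality analysis.
#' @return A `google_model`: list with `S` (sparse `dgCMatrix`, dangling
#'   columns left structurally zero), `dangling` (logical mask), `alpha`,
#'   `n`, `nodes`.
#' @examples
#' net <- directed_network(data.frame(from = c("A", "B"), to = c("B", "A")))
#' m <- build_transition(net)
#' as.matrix(m$S)  # the 2-cycle permutation matrix
#' @export
build_transition <- function(net, alpha = 0.85) {
  stopifnot(inherits(net, "directed_network"))
  if (net$n < 1) stop("cannot build a transition matrix for an empty network",
                      call. = FALSE)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  n <- net$n
  j <- match(net$edges$from, net$nodes)
  i <- match(net$edges$to, net$nodes)
  kout <- tabulate(j, nbins = n)
  S <- Matrix::sparseMatrix(i = i, j = j, x = 1 / kout[j], dims = c(n, n),
                            dimnames = list(net$nodes, net$nodes))
  structure(
    list(S = S, dangling = kout == 0L, alpha = alpha, n = n, nodes = net$nodes),
    class = "google_model"
  )
}

#' @exportS3Method base::print
print.google_model <- function(x, ...) {
  cat("<google_model> N = ", x$n, ", alpha = ", x$alpha,
      ", dangling nodes = ", sum(x$dangling), "\n", sep = "")
  invisible(x)
}

# S v, with the uniform dangling columns applied matrix-free
apply_transition <- function(model, v) {
  as.vector(model$S %*% v) + sum(v[model$dangling]) / model$n
}

# t(S) w: column j of S dotted with w; dangling columns are uniform 1/N
apply_transition_t <- function(model, w) {
  out <- as.vector(Matrix::crossprod(model$S, w))
  out[model$dangling] <- sum(w) / model$n
  out
}

#' Apply the Google matrix to a vector
#'
#' Computes G v = alpha * S v + (1 - alpha) * sum(v)/N without forming G.
#' Preserves the sum of `v` (G is column-stochastic), hence the 1-norm of
#' probability vectors.
#'
#' @param model A `google_model` from [build_transition()].
#' @param v Numeric vector of length N.
#' @return Numeric vector G v.
#' @export
apply_google <- function(model, v) {
  stopifnot(inherits(model, "google_model"))
  if (length(v) != model$n) {
    stop("length(v) = ", length(v), " but the model has N = ", model$n,
         call. = FALSE)
  }
  model$alpha * apply_transition(model, v) +
    (1 - model$alpha) * sum(v) / model$n
}

# dense S and G, for oracles and small-N eigendecompositions only
dense_transition <- function(model) {
  S <- as.matrix(model$S)
  S[, model$dangling] <- 1 / model$n
  S
}

#' Dense Google matrix (small networks only)
#'
#' Materializes G = alpha * S + (1 - alpha)/N as a dense matrix.  Intended
#' for oracles, dense eigendecompositions and the reduced-matrix direct
#' solver; refuses N > 2000.
#'
#' @param model A `google_model`.
#' @return Dense N x N matrix with node labels as dimnames.
#' @export
dense_google <- function(model) {
  stopifnot(inherits(model, "google_model"))
  if (model$n > 2000) {
    stop("dense_google() is restricted to N <= 2000; the production path is ",
         "matrix-free", call. = FALSE)
  }
  G <- model$alpha * dense_transition(model) + (1 - model$alpha) / model$n
  dimnames(G) <- list(model$nodes, model$nodes)
  G
}

# deterministic rank index: descending probability, ties by ascending label
rank_index <- function(p, labels) {
  ord <- order(-p, labels, method = "radix")
  k <- integer(length(p))
  k[ord] <- seq_along(p)
  k
}

#' PageRank by power iteration
#'
#' Iterates v <- G v from the uniform vector until the L1 residual
#' ||G v - v||_1 falls below `tol`.  The PageRank vector is the stationary
#' distribution of the random surfer; the rank index K orders nodes by
#' decreasing probability (K = 1 the most pointed-at node), ties broken by
#' ascending node label.
#'
#' @param model A `google_model`.
#' @param tol L1 convergence tolerance (> 0); default 1e-12, tight enough to
#'   make rank indexes stable.
#' @param max_iter Maximum number of power iterations.
#' @return A `rank_result`: list with `p` (named probability vector summing
#'   to 1), `k` (integer rank index), `nodes`, `alpha`, `iterations`,
#'   `residual`.
#' @export
pagerank <- function(model, tol = 1e-12, max_iter = 10000) {
  stopifnot(inherits(model, "google_model"), tol > 0)
  n <- model$n
  v <- rep(1 / n, n)
  res <- Inf
  for (it in seq_len(max_iter)) {
    v_new <- apply_google(model, v)
    v_new <- v_new / sum(v_new)  # guard drift
    res <- sum(abs(v_new - v))
    v <- v_new
    if (res < tol) break
  }
  if (res >= tol) {
    stop("PageRank power iteration did not converge in ", max_iter,
         " iterations (residual ", format(res), ")", call. = FALSE)
  }
  names(v) <- model$nodes
  structure(
    list(p = v, k = rank_index(v, model$nodes), nodes = model$nodes,
         alpha = model$alpha, iterations = it, residual = res),
    class = "rank_result"
  )
}

#' @exportS3Method base::print
print.rank_result <- function(x, ...) {
  cat("<rank_result> N = ", length(x$p), ", alpha = ", x$alpha,
      ", converged in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' CheiRank: PageRank of the edge-reversed network
#'
#' Builds the Google matrix of the same network with all link directions
#' inverted (dangling handling applied to the reversed network independently)
#' and runs [pagerank()] on it.  CheiRank is high for nodes with many or
#' important outgoing links.
#'
#' @param net A [directed_network()].
#' @inheritParams build_transition
#' @inheritParams pagerank
#' @return A `rank_result` for the reversed network.
#' @export
cheirank <- function(net, alpha = 0.85, tol = 1e-12, max_iter = 10000) {
  pagerank(build_transition(reverse_network(net), alpha = alpha),
           tol = tol, max_iter = max_iter)
}

#' 2DRank: combined PageRank-CheiRank ordering
#'
#' Nodes are taken in the order their (K, K*) cell is first covered by a
#' sequence of squares anchored at K = K* = 1 whose side grows one by one.
#' Within the square of side s the newly covered cells are scanned down the
#' new right column (K = s, K* increasing) and then along the new bottom row
#' (K* = s, K increasing).
#'
#' @param k,k_star Integer rank indexes, each a permutation of 1..N.
#' @return Integer vector K2, a permutation of 1..N aligned with the input.
#' @export
two_d_rank <- function(k, k_star) {
  n <- length(k)
  if (length(k_star) != n ||
      !setequal(k, seq_len(n)) || !setequal(k_star, seq_len(n))) {
    stop("`k` and `k_star` must both be permutations of 1..N", call. = FALSE)
  }
  s <- pmax(k, k_star)
  on_column <- k == s           # new right column, scanned by increasing K*
  key <- ifelse(on_column, k_star, k)
  ord <- order(s, !on_column, key)
  k2 <- integer(n)
  k2[ord] <- seq_len(n)
  k2
}

#' Creative-element scores
#'
#' Scores nodes whose Google-matrix rank is much better than their local
#' connectivity predicts: CE_in = K * (InDegree + 1) and
#' CE_out = K* * (OutDegree + 1).  Low products flag candidate "creative
#' elements" — non-hub connectors with unexpectedly high centrality.
#'
#' @param k,k_star Integer rank indexes.
#' @param in_degree,out_degree Nonnegative integer degrees.
#' @return A tibble with columns `ce_in`, `ce_out`.
#' @export
creative_scores <- function(k, k_star, in_degree, out_degree) {
  stopifnot(all(in_degree >= 0), all(out_degree >= 0))
  tibble::tibble(ce_in = k * (in_degree + 1),
                 ce_out = k_star * (out_degree + 1))
}

#' Full rank table of a directed network
#'
#' One-stop computation of PageRank, CheiRank, 2DRank, degrees and
#' creative-element scores, in the TSV layout used by the command-line
#' interface.
#'
#' @param net A [directed_network()].
#' @inheritParams cheirank
#' @return A tibble with columns `node`, `p`, `k`, `p_star`, `k_star`, `k2`,
#'   `in_degree`, `out_degree`, `ce_in`, `ce_out`, in node order.
#' @export
rank_table <- function(net, alpha = 0.85, tol = 1e-12, max_iter = 10000) {
  pr <- pagerank(build_transition(net, alpha = alpha), tol, max_iter)
  cr <- cheirank(net, alpha = alpha, tol = tol, max_iter = max_iter)
  deg <- network_degrees(net)
  k2 <- two_d_rank(pr$k, cr$k)
  ce <- creative_scores(pr$k, cr$k, deg$in_degree, deg$out_degree)
  tibble::tibble(
    node = net$nodes, p = unname(pr$p), k = pr$k,
    p_star = unname(cr$p), k_star = cr$k, k2 = k2,
    in_degree = deg$in_degree, out_degree = deg$out_degree,
    ce_in = ce$ce_in, ce_out = ce$ce_out
  )
}
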