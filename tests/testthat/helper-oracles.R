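# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (dense, enumerative) and separate
# from the package's production code paths.

# build a network from a character edge spec like c("A>B", "B>C")
net_from <- function(spec, nodes = NULL) {
  parts <- strsplit(spec, ">", fixed = TRUE)
  directed_network(
    tibble::tibble(from = vapply(parts, `[[`, "", 1),
                   to = vapply(parts, `[[`, "", 2)),
    nodes = nodes
  )
}

# dense Google matrix built from first principles (adjacency counting),
# bypassing build_transition's sparse path
dense_google_oracle <- function(net, alpha = 0.85) {
  n <- net$n
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (r in seq_len(nrow(net$edges))) {
    A[net$edges$to[r], net$edges$from[r]] <- 1
  }
  kout <- colSums(A)
  S <- A
  for (j in seq_len(n)) {
    S[, j] <- if (kout[j] > 0) A[, j] / kout[j] else 1 / n
  }
  alpha * S + (1 - alpha) / n
}

# dominant eigenvector of a dense column-stochastic matrix, sum-normalized
dense_pagerank_oracle <- function(G) {
  e <- eigen(G)
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# 2DRank by explicit square-by-square cell sweep
two_d_rank_oracle <- function(k, k_star) {
  n <- length(k)
  cell <- matrix(NA_integer_, n, n)  # cell[K, K*] = node id
  for (i in seq_len(n)) cell[k[i], k_star[i]] <- i
  out <- integer(0)
  for (s in seq_len(n)) {
    for (ks in seq_len(s)) {                    # new right column, top-down
      if (!is.na(cell[s, ks])) out <- c(out, cell[s, ks])
    }
    if (s > 1) {
      for (kk in seq_len(s - 1)) {              # new bottom row, left-right
        if (!is.na(cell[kk, s])) out <- c(out, cell[kk, s])
      }
    }
  }
  k2 <- integer(n)
  k2[out] <- seq_len(n)
  k2
}

# truncated Neumann-series reduced matrix (Eq-8 expansion, dense)
series_reduced_oracle <- function(G, r_idx, L = 500) {
  s_idx <- setdiff(seq_len(nrow(G)), r_idx)
  Grr <- G[r_idx, r_idx, drop = FALSE]
  Grs <- G[r_idx, s_idx, drop = FALSE]
  Gsr <- G[s_idx, r_idx, drop = FALSE]
  Gss <- G[s_idx, s_idx, drop = FALSE]
  acc <- Gsr
  term <- Gsr
  for (l in seq_len(L)) {
    term <- Gss %*% term
    acc <- acc + term
  }
  Grr + Grs %*% acc
}

# all simple directed paths from src to dst grouped by length (DFS)
enumerate_paths_oracle <- function(net, src, dst, max_len) {
  adj <- split(net$edges$to, net$edges$from)
  out <- list()
  walk <- function(path) {
    here <- path[length(path)]
    if (length(path) - 1 > max_len) return()
    if (here == dst && length(path) > 1) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (nx in adj[[here]]) {
      if (!(nx %in% path)) walk(c(path, nx))
    }
  }
  walk(src)
  out
}

# small seeded random model for property loops
random_model <- function(n, seed, dangling_fraction = 0.2, alpha = 0.85) {
  net <- random_network(fixture_spec(n, dangling_fraction = dangling_fraction,
                                     seed = seed))
  build_transition(net, alpha = alpha)
}
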