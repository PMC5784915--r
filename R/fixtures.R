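#' Specification for a synthetic sparse directed network
#'
#' Defaults emulate the topology of a curated human signaling network:
#' roughly 2.7 outgoing links per node on average, a small number of
#' fan-like hubs with out-degree near ten times the mean (transcription
#' factors regulating many targets), and a sizeable fraction of dangling
#' nodes (terminal effectors with no outgoing regulation).
#'
#' @param n Node count (>= 2).
#' @param mean_out_degree Expected out-links per node over the whole network.
#' @param dangling_fraction Probability for each node to have no outgoing
#'   links; in \[0, 1).
#' @param hub_count Number of high-out-degree hub nodes.
#' @param seed Integer seed; every generator is seed-deterministic.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n, mean_out_degree = 2.7, dangling_fraction = 0.15,
                         hub_count = max(0L, round(0.01 * n)), seed = 1L) {
  stopifnot(n >= 2, dangling_fraction >= 0, dangling_fraction < 1,
            mean_out_degree > 0)
  if (mean_out_degree >= n) {
    stop("infeasible spec: mean_out_degree must be < n", call. = FALSE)
  }
  structure(list(n = as.integer(n), mean_out_degree = mean_out_degree,
                 dangling_fraction = dangling_fraction,
                 hub_count = as.integer(hub_count), seed = as.integer(seed)),
            class = "fixture_spec")
}

# evaluate expr under a seed, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# out-targets for one node: k distinct nodes, self excluded
draw_targets <- function(i, k, n) {
  k <- min(k, n - 1L)
  t <- sample.int(n - 1L, k)
  t + (t >= i)
}

#' Generate a random sparse directed network
#'
#' Per-node out-degrees are geometric around the mean (heavy-enough tail to
#' create moderate hubs on its own), designated hub nodes draw out-degrees
#' near ten times the mean (fan-like structure), and a `dangling_fraction`
#' of nodes get no outgoing links at all.  Targets are uniform without
#' multi-edges or self-loops.  The non-hub mean is adjusted so the expected
#' total edge count is `n * mean_out_degree` regardless of the dangling and
#' hub settings.  The same seed always yields the identical network.
#'
#' @param spec A [fixture_spec()].
#' @return A [directed_network()] (layer tag `"background"`), with the spec
#'   attached as attribute `"spec"`.
#' @export
random_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n
    labels <- sprintf("n%04d", seq_len(n))
    dang <- stats::runif(n) < spec$dangling_fraction
    candidates <- which(!dang)
    if (length(candidates) == 0) dang[] <- FALSE
    hubs <- sample(which(!dang), min(spec$hub_count, sum(!dang)))
    rest <- setdiff(which(!dang), hubs)
    target_total <- n * spec$mean_out_degree
    hub_mean <- 10 * spec$mean_out_degree
    m_rest <- (target_total - length(hubs) * hub_mean) / max(length(rest), 1L)
    if (m_rest < 1) {
      stop("infeasible spec: hubs and dangling nodes leave a non-hub mean ",
           "out-degree below 1", call. = FALSE)
    }
    kout <- integer(n)
    kout[rest] <- 1L + stats::rgeom(length(rest), prob = 1 / m_rest)
    kout[hubs] <- pmax(1L, stats::rpois(length(hubs), hub_mean))
    kout <- pmin(kout, n - 1L)
    from_idx <- rep.int(seq_len(n), kout)
    to_idx <- unlist(lapply(seq_len(n), function(i) {
      if (kout[i] == 0L) integer(0) else draw_targets(i, kout[i], n)
    }))
    net <- directed_network(
      tibble::tibble(from = labels[from_idx], to = labels[to_idx],
                     interaction = "reg", layer = "background"),
      nodes = labels
    )
    attr(net, "spec") <- spec
    net
  })
}

#' Fixture with a planted relay path creating a known hidden link
#'
#' Builds a background random network, picks a subset of nodes, and plants a
#' directed chain from subset node r1 through `relay_length` exclusive
#' external relay nodes to subset node r2 — with no direct r1 -> r2 edge.
#' Random walks leaving the subset at r1 return at r2, so the hidden
#' component of the reduced Google matrix must score the ordered pair
#' (r1, r2) well above background.  A paired fixture without the relay chain
#' (but otherwise identical) is returned for contrast.
#'
#' @param n_background Background node count.
#' @param subset_size Subset size (>= 2).
#' @param relay_length Number of exclusive relay nodes (>= 1).
#' @param seed Integer seed.
#' @param spec Optional [fixture_spec()] for the background; defaults to
#'   `fixture_spec(n_background, seed = seed)`.
#' @return List with `network`, `network_no_relay`, `gene_set`,
#'   `pair` (c(source = r1, target = r2)) and `relay_nodes`.
#' @export
planted_relay <- function(n_background, subset_size, relay_length, seed = 1L,
                          spec = NULL) {
  stopifnot(subset_size >= 2, relay_length >= 1,
            n_background >= subset_size + 2)
  if (is.null(spec)) spec <- fixture_spec(n_background, seed = seed)
  bg <- random_network(spec)
  with_local_seed(seed + 104729L, {
    subset <- sample(bg$nodes, subset_size)
    r1 <- subset[1]; r2 <- subset[2]
    relay <- sprintf("relay%02d", seq_len(relay_length))
    chain <- tibble::tibble(
      from = c(r1, relay), to = c(relay, r2),
      interaction = "relay", layer = "planted"
    )
    base_edges <- bg$edges[!(bg$edges$from == r1 & bg$edges$to == r2), ]
    net <- directed_network(dplyr::bind_rows(base_edges, chain),
                            nodes = c(bg$nodes, relay))
    net_no <- directed_network(base_edges, nodes = c(bg$nodes, relay))
    list(network = net, network_no_relay = net_no,
         gene_set = gene_set("planted_subset", subset),
         pair = c(source = r1, target = r2), relay_nodes = relay)
  })
}

#' Two-condition network pair with a rewired transcriptional layer
#'
#' Emulates a normal-versus-cancer comparison: both conditions share a
#' bit-identical signaling layer; condition B differs only in its
#' transcriptional layer, where each edge is rewired (its target replaced by
#' a uniformly chosen node) with probability `rewire_fraction`.  The
#' transcriptional layer is fan-like: a few transcription-factor nodes each
#' regulating many targets.
#'
#' @param base_spec A [fixture_spec()] for the shared signaling layer.
#' @param rewire_fraction Probability in \[0, 1\] for each transcriptional
#'   edge to be rewired in condition B.
#' @param seed Integer seed.
#' @param n_tf Number of transcription factors; default 2% of nodes.
#' @param tf_fanout Mean out-degree of a transcription factor in the
#'   transcriptional layer.
#' @return List with `net_a`, `net_b`, `tfs`, `txn_edges_a`, `txn_edges_b`.
#' @export
two_condition_pair <- function(base_spec, rewire_fraction, seed = 1L,
                               n_tf = max(2L, round(0.02 * base_spec$n)),
                               tf_fanout = 10) {
  stopifnot(inherits(base_spec, "fixture_spec"),
            rewire_fraction >= 0, rewire_fraction <= 1)
  sig <- random_network(base_spec)
  sig$edges$layer <- "signaling"
  with_local_seed(seed + 7919L, {
    n <- base_spec$n
    tfs <- sample(sig$nodes, n_tf)
    fan <- pmax(1L, stats::rpois(n_tf, tf_fanout))
    txn_a <- tibble::tibble(
      from = rep(tfs, fan),
      to = sig$nodes[unlist(lapply(seq_along(tfs), function(i) {
        draw_targets(match(tfs[i], sig$nodes), fan[i], n)
      }))],
      interaction = "txn", layer = "transcriptional"
    )
    txn_b <- txn_a
    hit <- stats::runif(nrow(txn_b)) < rewire_fraction
    if (any(hit)) {
      txn_b$to[hit] <- sample(sig$nodes, sum(hit), replace = TRUE)
    }
    list(
      net_a = directed_network(dplyr::bind_rows(sig$edges, txn_a),
                               nodes = sig$nodes),
      net_b = directed_network(dplyr::bind_rows(sig$edges, txn_b),
                               nodes = sig$nodes),
      tfs = tfs, txn_edges_a = txn_a, txn_edges_b = txn_b
    )
  })
}
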