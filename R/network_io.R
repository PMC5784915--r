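#' Construct a directed network
#'
#' A `directed_network` holds an ordered set of unique node labels and a
#' deduplicated table of directed edges.  It is the common container for
#' signaling and transcriptional regulatory networks read from SIF files or
#' generated synthetically, and the source of the 0/1 adjacency used by
#' [build_transition()].
#'
#' Duplicate edges (same ordered `from`/`to` pair, whatever their interaction
#' tag or layer) collapse to a single entry; the distinct interaction tags are
#' kept, semicolon-joined, as metadata.  Interaction sign (activation /
#' inhibition) is metadata only and never enters any matrix.  Self-loops are
#' retained and count toward out-degree.
#'
#' @param edges A data frame with character columns `from` and `to`, and
#'   optionally `interaction` and `layer`.
#' @param nodes Optional character vector of node labels.  Labels appearing in
#'   `edges` are appended (in order of first appearance) if missing.  Allows
#'   isolated nodes.
#' @return An object of class `directed_network`: a list with elements
#'   `nodes` (character), `edges` (tibble with columns `from`, `to`,
#'   `interaction`, `layer`) and `n` (node count).
#' @examples
#' net <- directed_network(data.frame(from = c("A", "B"), to = c("B", "C")))
#' net$n
#' @export
directed_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            interaction = character(), layer = character())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns `from` and `to`", call. = FALSE)
  }
  if (!"interaction" %in% names(edges)) edges$interaction <- ""
  if (!"layer" %in% names(edges)) edges$layer <- ""
  edges <- dplyr::mutate(edges, dplyr::across(c("from", "to", "interaction", "layer"),
                                              as.character))
  edges <- edges[, c("from", "to", "interaction", "layer")]
  # collapse duplicate (from, to) pairs; keep distinct tags as metadata
  if (nrow(edges) > 0 && anyDuplicated(edges[, c("from", "to")]) > 0) {
    edges <- edges |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(
        interaction = paste(unique(.data$interaction[nzchar(.data$interaction)]),
                            collapse = ";"),
        layer = paste(unique(.data$layer[nzchar(.data$layer)]), collapse = ";"),
        .groups = "drop"
      )
  }
  seen <- unique(c(nodes, rbind(edges$from, edges$to)))
  if (anyDuplicated(nodes) > 0) stop("node labels must be unique", call. = FALSE)
  structure(
    list(nodes = seen, edges = edges, n = length(seen)),
    class = "directed_network"
  )
}

#' @exportS3Method base::print
print.directed_network <- function(x, ...) {
  cat("<directed_network> ", x$n, " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::format
format.directed_network <- function(x, ...) {
  sprintf("<directed_network: %d nodes, %d edges>", x$n, nrow(x$edges))
}

#' @rdname directed_network
#' @param x A `directed_network`.
#' @param ... Ignored.
#' @export
as_tibble.directed_network <- function(x, ...) x$edges

#' Read a directed network from a SIF file
#'
#' Reads the simple interaction format: UTF-8 text, one edge per line,
#' `source interaction target` with tokens separated by tabs or runs of
#' whitespace.  Lines with exactly two tokens are read as `source target`
#' with an empty interaction tag; with more than three tokens, the source is
#' the first token, the target the last, and the middle tokens (joined) form
#' the interaction tag.  `#`-initial lines are ignored.
#'
#' @param path Path to a SIF file.
#' @param layer_tag Layer label recorded on every edge (e.g. `"signaling"`,
#'   `"transcriptional"`).
#' @return A [directed_network()].
#' @examples
#' f <- tempfile(fileext = ".sif")
#' writeLines(c("A act B", "B inh C", "A act B"), f)
#' read_sif(f)  # 3 nodes, 2 edges: the duplicate collapses
#' @export
read_sif <- function(path, layer_tag = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    warning("empty SIF file: ", path, call. = FALSE)
    return(directed_network())
  }
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < 2)) {
    bad <- idx[which(nt < 2)[1]]
    stop("malformed SIF line ", bad, " in ", path,
         ": fewer than 2 tokens", call. = FALSE)
  }
  edges <- tibble::tibble(
    from = vapply(toks, `[[`, "", 1L),
    to = vapply(toks, function(t) t[[length(t)]], ""),
    interaction = vapply(toks, function(t) {
      if (length(t) > 2) paste(t[-c(1L, length(t))], collapse = " ") else ""
    }, ""),
    layer = layer_tag
  )
  directed_network(edges)
}

#' Write a directed network as a SIF file
#'
#' Inverse of [read_sif()] on the (node set, deduplicated edge set): edges are
#' written one per line as `source interaction target` (or `source target`
#' when the interaction tag is empty).  Isolated nodes are written as a
#' single-token comment-free line cannot be represented in SIF and are
#' dropped with a warning.
#'
#' @param net A [directed_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  iso <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
  if (length(iso) > 0) {
    warning(length(iso), " isolated node(s) not representable in SIF dropped",
            call. = FALSE)
  }
  tag <- ifelse(nzchar(net$edges$interaction), net$edges$interaction, NA)
  out <- ifelse(is.na(tag),
                paste(net$edges$from, net$edges$to, sep = "\t"),
                paste(net$edges$from, tag, net$edges$to, sep = "\t"))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Merge directed networks by concatenation
#'
#' The node set is the union of the label sets (order of first appearance)
#' and the edge set is the union of edges with `(from, to)` deduplication
#' across layers; layer tags are preserved (semicolon-joined when the same
#' pair occurs in several layers).  Merging is how a signaling network and a
#' cell-line-specific transcriptional network are combined into one global
#' regulatory network.
#'
#' @param nets A list of [directed_network()] objects (or several networks
#'   passed as `...`).
#' @param ... Additional networks.
#' @return A [directed_network()].
#' @export
merge_networks <- function(nets, ...) {
  if (inherits(nets, "directed_network")) nets <- list(nets)
  nets <- c(nets, list(...))
  stopifnot(length(nets) >= 1,
            all(vapply(nets, inherits, TRUE, "directed_network")))
  edges <- dplyr::bind_rows(lapply(nets, function(x) x$edges))
  nodes <- unique(unlist(lapply(nets, function(x) x$nodes)))
  directed_network(edges, nodes = nodes)
}

#' Reverse every edge of a network
#'
#' Used to define CheiRank: the CheiRank of a network is the PageRank of its
#' edge-reversed counterpart.
#'
#' @param net A [directed_network()].
#' @return A [directed_network()] with all edge directions inverted (node
#'   order preserved).
#' @export
reverse_network <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  e <- net$edges
  directed_network(
    tibble::tibble(from = e$to, to = e$from,
                   interaction = e$interaction, layer = e$layer),
    nodes = net$nodes
  )
}

#' Read a gene set from a plain-text list
#'
#' One label per line; `#` comments and blank lines ignored; duplicate labels
#' dropped (first occurrence kept).
#'
#' @param path Path to the list file.
#' @param name Set name; defaults to the file name without extension.
#' @return A `gene_set`: list with `name` and character `labels`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  labels <- unique(lines[nzchar(lines)])
  gene_set(name, labels)
}

#' @rdname read_gene_set
#' @param labels Character vector of unique labels.
#' @export
gene_set <- function(name, labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels) > 0) {
    labels <- unique(labels)
  }
  structure(list(name = as.character(name), labels = labels), class = "gene_set")
}

#' @exportS3Method base::print
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$labels), " labels\n", sep = "")
  invisible(x)
}

#' Map a gene set onto network nodes
#'
#' Exact, case-sensitive label matching; no alias resolution.  The raw size
#' of the set and the mapped count generally differ (list entries missing
#' from the network), so both are reported.
#'
#' @param net A [directed_network()].
#' @param gs A `gene_set` (or plain character vector of labels).
#' @return A list with `present` and `missing` character vectors (order of
#'   the gene set preserved), and counts `n_raw`, `n_present`.
#' @export
map_gene_set <- function(net, gs) {
  stopifnot(inherits(net, "directed_network"))
  labels <- if (inherits(gs, "gene_set")) gs$labels else as.character(gs)
  hit <- labels %in% net$nodes
  list(present = labels[hit], missing = labels[!hit],
       n_raw = length(labels), n_present = sum(hit))
}

#' In/out degrees of a directed network
#'
#' Degrees are counted on the deduplicated adjacency (each ordered pair once);
#' a self-loop contributes one to both the in- and out-degree of its node.
#'
#' @param net A [directed_network()].
#' @return A tibble with columns `node`, `in_degree`, `out_degree`, in node
#'   order.
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  tibble::tibble(
    node = net$nodes,
    in_degree = as.integer(table(factor(net$edges$to, levels = net$nodes))),
    out_degree = as.integer(table(factor(net$edges$from, levels = net$nodes)))
  )
}

#' Convert a directed network to an igraph graph
#'
#' @param net A [directed_network()].
#' @return A directed `igraph` graph with the same nodes and edges.
#' @keywords internal
as_igraph <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = TRUE, vertices = net$nodes)
}
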