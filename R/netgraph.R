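## Co-expression network built from the extreme PCIT edges, with hub
## (degree) and hub-centrality (betweenness) flags at mean + 2 SD, exact
## connected components, and 1st/2nd-order neighborhoods.

#' Build the co-expression network
#'
#' Nodes are the union of edge endpoints, annotated with biotype, the
#' comparisons in which they were DE, TF status, and RIF significance.
#'
#' @param edges data.frame (node_a, node_b, r) from [extreme_edges()].
#' @param de DE table ([call_de()] output); may be NULL.
#' @param annotation annotation data.frame; nodes without annotation get
#'   biotype `"misc"` with a warning.
#' @param rif RIF table ([rif_all_comparisons()] output); may be NULL.
#' @return a `pcit_network` wrapping an undirected igraph with node/edge
#'   attributes.
#' @export
build_network <- function(edges, de = NULL, annotation = NULL, rif = NULL) {
  if (nrow(edges)) {
    edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  biotype <- rep("misc", length(nodes))
  is_tf <- rep(FALSE, length(nodes))
  if (!is.null(annotation) && length(nodes)) {
    hit <- match(nodes, annotation$transcript_id)
    if (anyNA(hit)) {
      warning("nodes without annotation get biotype 'misc': ",
              paste(head(nodes[is.na(hit)], 5), collapse = ", "))
    }
    biotype[!is.na(hit)] <- annotation$biotype[hit[!is.na(hit)]]
    is_tf[!is.na(hit)] <- annotation$is_tf[hit[!is.na(hit)]]
  }
  de_comparisons <- rep("", length(nodes))
  if (!is.null(de) && length(nodes)) {
    de_hit <- de[de$is_de, c("transcript_id", "comparison")]
    agg <- vapply(nodes, function(id) {
      paste(sort(unique(de_hit$comparison[de_hit$transcript_id == id])),
            collapse = ";")
    }, character(1))
    de_comparisons <- unname(agg)
  }
  rif_significant <- rep(FALSE, length(nodes))
  if (!is.null(rif) && nrow(rif) && length(nodes)) {
    sig_ids <- unique(rif$regulator_id[rif$significant])
    rif_significant <- nodes %in% sig_ids
  }
  vertices <- data.frame(name = nodes, biotype = biotype,
                         de_comparisons = de_comparisons, is_tf = is_tf,
                         rif_significant = rif_significant,
                         hub = rep(FALSE, length(nodes)),
                         hub_centrality = rep(FALSE, length(nodes)),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[c("node_a", "node_b", "r")] else
      data.frame(node_a = character(0), node_b = character(0), r = numeric(0)),
    directed = FALSE, vertices = vertices)
  structure(list(graph = g), class = "pcit_network")
}

#' @export
print.pcit_network <- function(x, ...) {
  cat(sprintf("pcit_network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Flag hub and hub-centrality nodes
#'
#' Hubs have degree strictly greater than `mean + 2 sd` of all degrees
#' (sample sd); hub-centrality nodes exceed the same threshold on exact
#' unnormalized betweenness of the unweighted graph. A zero sd yields no
#' hubs (with a warning).
#'
#' @param network a `pcit_network`.
#' @return the network with `hub` / `hub_centrality` vertex attributes set.
#' @export
classify_hubs <- function(network) {
  g <- network$graph
  if (igraph::vcount(g) < 2) stop("need >= 2 nodes to classify hubs")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE,
                             weights = NA)
  flag <- function(x, what) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero spread in ", what, ": no nodes flagged")
      return(rep(FALSE, length(x)))
    }
    x > mean(x) + 2 * s
  }
  igraph::V(g)$hub <- flag(deg, "degree")
  igraph::V(g)$hub_centrality <- flag(btw, "betweenness")
  network$graph <- g
  network
}

#' Connected components, largest first
#'
#' @param network a `pcit_network`.
#' @return list of node-id vectors, ordered by decreasing size, ties by
#'   the lexicographically smallest member; members sorted.
#' @export
network_components <- function(network) {
  g <- network$graph
  if (igraph::vcount(g) == 0) return(list())
  comp <- igraph::components(g)
  groups <- unname(split(igraph::V(g)$name, comp$membership))
  groups <- lapply(groups, sort)
  sizes <- lengths(groups)
  first <- vapply(groups, `[`, character(1), 1)
  groups[order(-sizes, first)]
}

#' First- and second-order neighborhood of a node
#'
#' @param network a `pcit_network`.
#' @param node a node id present in the network.
#' @return list(first, second, n_positive, n_negative) — `first` is a
#'   data.frame (node, r) of direct neighbors with the signed edge
#'   correlation; `second` the neighbors-of-neighbors excluding `first`
#'   and the node itself; the counts split `first` by correlation sign.
#' @export
neighborhood <- function(network, node) {
  g <- network$graph
  if (!node %in% igraph::V(g)$name) stop("unknown node: ", node)
  inc <- igraph::incident(g, node)
  if (length(inc)) {
    ends <- igraph::ends(g, inc)
    other <- ifelse(ends[, 1] == node, ends[, 2], ends[, 1])
    first <- data.frame(node = other, r = igraph::E(g)$r[as.integer(inc)],
                        stringsAsFactors = FALSE)
    first <- first[order(first$node), , drop = FALSE]
    rownames(first) <- NULL
  } else {
    first <- data.frame(node = character(0), r = numeric(0))
  }
  second <- character(0)
  if (nrow(first)) {
    nb2 <- unique(unlist(lapply(first$node, function(v) {
      igraph::V(g)$name[as.integer(igraph::neighbors(g, v))]
    })))
    second <- sort(setdiff(nb2, c(first$node, node)))
  }
  list(first = first, second = second,
       n_positive = sum(first$r > 0), n_negative = sum(first$r < 0))
}

#' Network summary counts
#' @param network a `pcit_network`.
#' @return list(n_nodes, n_edges, largest_component).
#' @export
network_summary <- function(network) {
  comps <- network_components(network)
  list(n_nodes = igraph::vcount(network$graph),
       n_edges = igraph::ecount(network$graph),
       largest_component = if (length(comps)) length(comps[[1]]) else 0L)
}
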