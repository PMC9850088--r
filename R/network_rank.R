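#' @title Combined network-centrality ranking
#' @description Ranks candidate genes on a confidence-scored interaction
#'   network by a combination of three complementary centrality measures:
#'   degree (direct interaction partners), harmonic closeness (how near a
#'   node is to all others; well-defined on disconnected subnetworks) and
#'   shortest-path betweenness (how often a node lies between others). The
#'   three are min-max normalized and combined as a weighted mean.
#' @name network-rank
#' @keywords internal
NULL

as_igraph <- function(net, use_confidence_weights = FALSE, eps = 1e-6) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("a", "b", "confidence")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  if (use_confidence_weights) {
    igraph::E(g)$length <- 1 - igraph::E(g)$confidence + eps
  }
  g
}

#' Raw centrality measures of every node
#'
#' Degree is the edge count per node (or the sum of edge confidences when
#' confidence weighting is on). Closeness is harmonic: the sum of inverse
#' shortest-path distances to all other nodes, divided by N - 1, so
#' unreachable nodes contribute 0 and disconnected networks pose no
#' problem. Betweenness is shortest-path betweenness, normalized by the
#' number of node pairs excluding the node itself. Isolated nodes score 0
#' on all three. With confidence weighting, path computations use edge
#' length `1 - confidence + 1e-6`.
#'
#' @param net a [gene_network()].
#' @param use_confidence_weights use edge confidences (default `FALSE`:
#'   hop counts and plain degree).
#' @return data.frame with columns `node`, `degree`, `closeness`,
#'   `betweenness`, sorted by node id.
#' @export
centralities <- function(net, use_confidence_weights = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  if (!length(net$nodes)) {
    return(data.frame(node = character(), degree = numeric(),
                      closeness = numeric(), betweenness = numeric()))
  }
  g <- as_igraph(net, use_confidence_weights)
  w <- if (use_confidence_weights && igraph::ecount(g)) igraph::E(g)$length
       else NA
  deg <- if (use_confidence_weights) {
    igraph::strength(g, weights = igraph::E(g)$confidence)
  } else {
    igraph::degree(g)
  }
  n <- igraph::vcount(g)
  clo <- if (n > 1) {
    igraph::harmonic_centrality(g, weights = w, normalized = TRUE)
  } else {
    stats::setNames(0, igraph::V(g)$name)
  }
  btw <- if (n > 2) {
    igraph::betweenness(g, weights = w, directed = FALSE, normalized = TRUE)
  } else {
    stats::setNames(rep(0, n), igraph::V(g)$name)
  }
  out <- data.frame(node = igraph::V(g)$name, degree = as.numeric(deg),
                    closeness = as.numeric(clo),
                    betweenness = as.numeric(btw),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

minmax_scale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Combine centrality measures into one score and rank
#'
#' Each measure is min-max scaled to [0,1] over the node set (a constant
#' measure scales to 0.5 for every node), then combined as a weighted mean.
#' Ranking is dense: rank 1 is the highest combined score, ties share the
#' smaller rank, and tied rows are ordered lexicographically by node id so
#' output is bit-stable.
#'
#' @param raw data.frame from [centralities()].
#' @param weights length-3 numeric `(w_degree, w_closeness, w_betweenness)`;
#'   normalized to sum 1. Default: equal weights.
#' @param normalization currently `"minmax"` only.
#' @return An object of class `centrality_result`: data.frame with `node`,
#'   the three raw measures, `combined` and `rank`, ordered by decreasing
#'   `combined` (node id breaking ties); attributes `weights` and
#'   `normalization`.
#' @export
combined_rank <- function(raw, weights = c(1, 1, 1) / 3,
                          normalization = "minmax") {
  stopifnot(is.data.frame(raw), length(weights) == 3, all(weights >= 0),
            sum(weights) > 0)
  normalization <- match.arg(normalization, "minmax")
  w <- weights / sum(weights)
  scaled <- cbind(minmax_scale(raw$degree), minmax_scale(raw$closeness),
                  minmax_scale(raw$betweenness))
  combined <- as.numeric(scaled %*% w)
  ord <- order(-combined, raw$node)
  out <- raw[ord, , drop = FALSE]
  out$combined <- combined[ord]
  out$rank <- match(out$combined, sort(unique(out$combined),
                                       decreasing = TRUE))
  rownames(out) <- NULL
  attr(out, "weights") <- w
  attr(out, "normalization") <- normalization
  class(out) <- c("centrality_result", "data.frame")
  out
}

#' Rank candidate genes on a network
#'
#' Convenience wrapper: compute raw centralities on the induced subgraph of
#' `candidates` (or the whole network) and rank by the combined score.
#'
#' @param net a [gene_network()].
#' @param candidates optional character vector of node ids; the network is
#'   restricted to these (candidates absent from the network become
#'   isolated nodes).
#' @param weights,use_confidence_weights see [combined_rank()] and
#'   [centralities()].
#' @return a `centrality_result`.
#' @export
rank_genes <- function(net, candidates = NULL, weights = c(1, 1, 1) / 3,
                       use_confidence_weights = FALSE) {
  if (!is.null(candidates)) {
    e <- net$edges[net$edges$a %in% candidates & net$edges$b %in% candidates,
                   , drop = FALSE]
    net <- gene_network(e, nodes = candidates)
  }
  combined_rank(centralities(net, use_confidence_weights), weights = weights)
}
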