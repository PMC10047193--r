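#' Keep only high-confidence interactions
#'
#' Retains edges whose confidence score strictly exceeds `min_score`
#' (highest-confidence selection, `> 0.9` by default); isolated nodes are
#' kept so that centrality scores remain defined for every input protein.
#'
#' @param network an undirected simple `igraph` graph with edge attribute
#'   `score` (see [read_edge_list()] / [ppi_network()]).
#' @param min_score confidence threshold (default 0.9, strict).
#' @return the filtered graph.
#' @export
filter_edges <- function(network, min_score = 0.9) {
  if (igraph::ecount(network) == 0L) return(network)
  score <- igraph::edge_attr(network, "score")
  if (is.null(score)) score <- rep(1.0, igraph::ecount(network))
  igraph::subgraph_from_edges(network, which(score > min_score),
                              delete.vertices = FALSE)
}

#' Degree centrality
#'
#' Number of distinct neighbors of each node.
#'
#' @param network an undirected simple `igraph` graph.
#' @return named integer vector over all nodes.
#' @export
degree_centrality <- function(network) {
  d <- igraph::degree(network, loops = FALSE)
  stats::setNames(as.integer(d), igraph::V(network)$name)
}

#' Maximum neighborhood component (MNC) centrality
#'
#' MNC(v) is the node count of the largest connected component of the
#' subgraph induced by the open neighborhood of v (v itself excluded);
#' isolated nodes score 0.
#'
#' @param network an undirected simple `igraph` graph.
#' @return named integer vector over all nodes.
#' @export
mnc_centrality <- function(network) {
  nodes <- igraph::V(network)
  out <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    nb <- igraph::neighbors(network, nodes[i])
    nb <- setdiff(nb, nodes[i])  # guard against self-loops
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(network, nb)
    out[i] <- max(igraph::components(sub)$csize)
  }
  stats::setNames(out, nodes$name)
}

#' Maximal clique centrality (MCC)
#'
#' MCC(v) is the sum over all maximal cliques C containing v of
#' `(|C| - 1)!`, computed by exact maximal-clique enumeration
#' (Bron-Kerbosch with pivoting); isolated nodes score 0. When the
#' neighborhood of v induces no edges, MCC(v) equals the degree of v.
#'
#' @param network an undirected simple `igraph` graph.
#' @param max_cliques_guard abort if the graph holds more maximal cliques
#'   than this bound (default 1e6); dense graphs can have exponentially many.
#' @return named numeric vector over all nodes (factorial sums grow fast).
#' @export
mcc_centrality <- function(network, max_cliques_guard = 1e6) {
  n_cl <- igraph::count_max_cliques(network, min = 2)
  if (n_cl > max_cliques_guard)
    stop("complexity error: ", n_cl, " maximal cliques exceed the guard (",
         max_cliques_guard, ")", call. = FALSE)
  out <- stats::setNames(numeric(igraph::vcount(network)),
                         igraph::V(network)$name)
  if (igraph::ecount(network) > 0L) {
    cliques <- igraph::max_cliques(network, min = 2)
    for (cl in cliques) {
      w <- factorial(length(cl) - 1)
      members <- igraph::V(network)$name[as.integer(cl)]
      out[members] <- out[members] + w
    }
  }
  out
}

#' Score a network with the three local centralities
#'
#' @param network an undirected simple `igraph` graph (typically already
#'   passed through [filter_edges()]).
#' @return data.frame with columns `node`, `degree`, `mnc`, `mcc`, sorted by
#'   decreasing degree then node id.
#' @export
hub_scores <- function(network) {
  deg <- degree_centrality(network)
  df <- data.frame(node = names(deg), degree = unname(deg),
                   mnc = unname(mnc_centrality(network)),
                   mcc = unname(mcc_centrality(network)),
                   stringsAsFactors = FALSE)
  df[order(-df$degree, df$node), , drop = FALSE]
}

#' Consensus hub selection from the three centralities
#'
#' Per method, a node is selected when its raw score is at least
#' `threshold`; the consensus hubs are the nodes selected by all three
#' methods. An alternative `mode = "rank"` selects the top `threshold`
#' ranked nodes per method instead.
#'
#' @param scores data.frame from [hub_scores()] (columns `node`, `degree`,
#'   `mnc`, `mcc`).
#' @param threshold minimal raw score (default 2), or the number of top
#'   ranks when `mode = "rank"`.
#' @param mode `"score"` (default) or `"rank"`.
#' @return list with `degree`, `mnc`, `mcc` (selected node vectors, sorted
#'   by score descending then node id) and `consensus` (sorted node ids
#'   selected by all three methods).
#' @export
consensus_hubs <- function(scores, threshold = 2, mode = c("score", "rank")) {
  mode <- match.arg(mode)
  pick <- function(col) {
    ord <- order(-scores[[col]], scores$node)
    s <- scores[ord, , drop = FALSE]
    if (mode == "score") s$node[s[[col]] >= threshold]
    else s$node[seq_len(min(threshold, nrow(s)))]
  }
  sets <- list(degree = pick("degree"), mnc = pick("mnc"),
               mcc = pick("mcc"))
  sets$consensus <- sort(Reduce(intersect, sets))
  sets
}

#' Intersect externally ranked hub lists
#'
#' Consensus over node sets produced by an external topology tool (e.g.
#' three ranked hub lists already thresholded at score >= 2): simply the
#' sorted intersection.
#'
#' @param sets list of character vectors of node ids.
#' @return sorted character vector of nodes present in every set.
#' @export
intersect_hub_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  sort(Reduce(intersect, lapply(sets, unique)))
}
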