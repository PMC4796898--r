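#' Degree and centrality table for a protein-protein interaction network
#'
#' Computes, per node of an undirected PPI graph: degree (number of
#' neighbours), betweenness centrality normalised by `(n-1)(n-2)/2` (the
#' undirected-graph convention of Cytoscape's Network Analyser, so values
#' lie in \[0, 1\]), and closeness centrality computed per connected
#' component as `(r-1)/sum(distances)` for `r` reachable nodes, scaled by
#' the component fraction `(r-1)/(n-1)` so that nodes in small fragments do
#' not outrank nodes central to the whole network. Isolated nodes score 0
#' on both centralities. Self-loops are dropped and parallel edges
#' collapsed.
#'
#' @param edges two-column data.frame (or matrix) of undirected edges, or an
#'   [igraph::graph] object.
#' @param nodes optional character vector of node ids to include even if
#'   isolated.
#' @return data.frame per node: `node`, `degree`, `betweenness`,
#'   `closeness`, sorted by decreasing degree then node id.
#' @export
centralityTable <- function(edges, nodes = NULL) {
  if (inherits(edges, "igraph")) {
    g <- edges
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopIfNot1(ncol(edges) >= 2L, "edges must have two columns")
    verts <- unique(c(as.character(edges[[1L]]), as.character(edges[[2L]]),
                      as.character(nodes)))
    stopIfNot1(length(verts) > 0L, "empty graph")
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges[[1L]]),
                 to = as.character(edges[[2L]])),
      directed = FALSE, vertices = verts)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n <- igraph::vcount(g)
  stopIfNot1(n > 0L, "empty graph")
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))

  deg <- igraph::degree(g)
  btwRaw <- igraph::betweenness(g, directed = FALSE)
  btw <- if (n > 2L) btwRaw / ((n - 1) * (n - 2) / 2) else rep(0, n)

  d <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    r <- length(di) + 1L  # component size
    if (r <= 1L || n == 1L) return(0)
    ((r - 1) / sum(di)) * ((r - 1) / (n - 1))
  }, numeric(1L))

  out <- data.frame(node = ids, degree = as.integer(deg),
                    betweenness = unname(btw), closeness = clo,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter and rank high-degree nodes
#'
#' Returns the nodes whose degree strictly exceeds the threshold (the hub
#' criterion used for PPI reporting), sorted by decreasing degree with ties
#' broken by node id.
#'
#' @param records data.frame with at least `node` and `degree` columns
#'   (e.g. from [centralityTable()] or a published degree table).
#' @param degreeThreshold strict lower bound on degree (default 75).
#' @return Sorted subset of `records`.
#' @export
highDegreeNodes <- function(records, degreeThreshold = 75) {
  stopIfNot1(all(c("node", "degree") %in% names(records)),
             "records need columns node, degree")
  out <- records[records$degree > degreeThreshold, , drop = FALSE]
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
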