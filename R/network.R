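# Topology of the pathway graph: degree, closeness, betweenness,
# neighbor means.

#' Node centralities of a pathway network
#'
#' Degree is the incident-edge count.  Closeness follows the within-component
#' convention: (n_c - 1) divided by the sum of shortest-path distances to the
#' other nodes of the node's connected component (n_c = component size), so a
#' node adjacent to every other node scores 1.  Betweenness counts, over
#' unordered node pairs excluding the node itself, the fraction of shortest
#' paths passing through the node (Brandes algorithm via igraph; equal-length
#' alternatives share weight).  A normalized betweenness (divided by
#' (n_c - 1)(n_c - 2)/2) is also reported.
#'
#' @param network A `pathway_network`.
#' @return Data frame with columns `node`, `degree`, `closeness`,
#'   `betweenness`, `betweenness_norm`, `component`.
#' @export
centralities <- function(network) {
  stopifnot(inherits(network, "pathway_network"))
  g <- network$graph
  n <- length(network$nodes)
  if (n == 0) stop("empty network")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("network has ", comp$no, " connected components; closeness and ",
            "betweenness are computed within components")
  }
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    same <- comp$membership == comp$membership[i]
    nc <- sum(same)
    if (nc < 2) return(NA_real_)
    (nc - 1) / sum(d[i, same & seq_len(n) != i])
  }, numeric(1))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  csize <- comp$csize[comp$membership]
  btw_norm <- ifelse(csize > 2, btw / ((csize - 1) * (csize - 2) / 2), 0)
  data.frame(node = network$nodes, degree = as.integer(deg),
             closeness = clo, betweenness = as.numeric(btw),
             betweenness_norm = btw_norm,
             component = as.integer(comp$membership),
             row.names = NULL)
}

#' Mean value over a node's immediate neighbors
#'
#' @param network A `pathway_network`.
#' @param values Named numeric vector (names = node ids); nodes without a
#'   value are treated as missing and skipped in their neighbors' means.
#' @return Named numeric vector over network nodes; `NA` where a node has no
#'   valued neighbor.
#' @export
neighbor_mean <- function(network, values) {
  stopifnot(inherits(network, "pathway_network"))
  g <- network$graph
  out <- stats::setNames(rep(NA_real_, length(network$nodes)), network$nodes)
  for (v in network$nodes) {
    nb <- igraph::neighbors(g, v)$name
    vals <- values[nb]
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0) out[v] <- mean(vals)
  }
  out
}
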