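#' Strength centrality
#'
#' The absolute sum of edge weights connected to each node,
#' \eqn{s_i = \sum_j |w_{ij}|}.  Summed over all nodes this equals twice
#' the network's [global_strength()].
#'
#' @param net A [symptom_network()].
#' @return Named numeric vector.
#' @export
strength_centrality <- function(net) {
  rowSums(abs(net$weights))
}

#' Shortest-path distances on a weighted symptom network
#'
#' Edge lengths are the reciprocal absolute weights \eqn{1/|w_{ij}|}, so
#' strong (positive or negative) connections are short; distances are
#' shortest paths by Dijkstra's algorithm; unreachable pairs are infinite.
#'
#' @param net A [symptom_network()].
#' @return Symmetric p x p distance matrix (zero diagonal).
#' @export
graph_distances <- function(net) {
  w <- abs(net$weights)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  len <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = len, algorithm = "dijkstra")
  d[net$nodes, net$nodes]
}

# number of shortest paths from s to every node, by DP over nodes ordered
# by distance from s (Brandes-style counting on the shortest-path DAG)
shortest_path_counts <- function(d, len, s, tol = 1e-9) {
  p <- nrow(len)
  sigma <- numeric(p)
  sigma[s] <- 1
  ord <- order(d[s, ])
  for (v in ord) {
    if (v == s || !is.finite(d[s, v])) next
    pred <- which(is.finite(len[, v]) &
                    abs(d[s, ] + len[, v] - d[s, v]) < tol)
    sigma[v] <- sum(sigma[pred])
  }
  sigma
}

#' Bridge centrality over the two-community partition
#'
#' For a network with a depression/anxiety partition:
#' \itemize{
#' \item bridge strength: the absolute sum of a node's edge weights to the
#'   other community;
#' \item bridge betweenness: the number of shortest paths between pairs of
#'   nodes from different communities on which the node lies as an
#'   intermediate (tied shortest paths counted fractionally by default, or
#'   once per pair with `fractional = FALSE`);
#' \item bridge closeness: the reciprocal mean shortest-path distance from
#'   the node to all nodes of the other community (0, flagged, when the
#'   whole other community is unreachable).
#' }
#' z-standardized variants (across nodes) are included for plotting.
#'
#' @param net A [symptom_network()] with a two-community partition.
#' @param fractional Fractional counting of tied shortest paths in bridge
#'   betweenness (default TRUE); FALSE counts a node once per
#'   cross-community pair whose shortest paths it intersects.
#' @return Data frame `node, community, strength, bridge_strength,
#'   bridge_betweenness, bridge_closeness` plus `z_`-prefixed standardized
#'   columns; attribute `unreachable` flags nodes with no path to the
#'   other community.
#' @export
bridge_centrality <- function(net, fractional = TRUE) {
  part <- net$partition
  if (is.null(part) || length(unique(part)) != 2)
    stop("bridge centrality requires a two-community partition")
  nodes <- net$nodes
  p <- length(nodes)
  w <- abs(net$weights)
  other <- outer(part, part, "!=")

  bstr <- rowSums(w * other)

  d <- graph_distances(net)
  len <- 1 / w
  len[w == 0] <- Inf
  diag(len) <- Inf

  sigma <- t(vapply(seq_len(p),
                    function(s) shortest_path_counts(d, len, s),
                    numeric(p)))
  # sigma[s, v]: number of shortest s->v paths
  bbet <- numeric(p)
  cross <- which(other & upper.tri(other), arr.ind = TRUE)
  for (r in seq_len(nrow(cross))) {
    s <- cross[r, 1]; t <- cross[r, 2]
    if (!is.finite(d[s, t])) next
    for (v in seq_len(p)) {
      if (v == s || v == t) next
      on_path <- is.finite(d[s, v]) && is.finite(d[v, t]) &&
        abs(d[s, v] + d[v, t] - d[s, t]) < 1e-9
      if (!on_path) next
      bbet[v] <- bbet[v] +
        if (fractional) sigma[s, v] * sigma[t, v] / sigma[s, t] else 1
    }
  }

  bclo <- numeric(p)
  unreachable <- logical(p)
  for (i in seq_len(p)) {
    dd <- d[i, part != part[i]]
    if (all(!is.finite(dd))) {
      unreachable[i] <- TRUE
      bclo[i] <- 0
    } else {
      bclo[i] <- 1 / mean(dd)   # infinite distances drive this to 0 too
      if (!is.finite(bclo[i])) bclo[i] <- 0
    }
  }

  zs <- function(v) if (sd(v) == 0) rep(0, length(v)) else
    (v - mean(v)) / sd(v)
  out <- data.frame(node = nodes, community = unname(part[nodes]),
                    strength = unname(strength_centrality(net)),
                    bridge_strength = unname(bstr),
                    bridge_betweenness = unname(bbet),
                    bridge_closeness = unname(bclo),
                    stringsAsFactors = FALSE)
  for (cn in c("strength", "bridge_strength", "bridge_betweenness",
               "bridge_closeness"))
    out[[paste0("z_", cn)]] <- zs(out[[cn]])
  attr(out, "unreachable") <- setNames(unreachable, nodes)
  out
}

#' Centrality table of a network
#'
#' Convenience wrapper returning strength and all three bridge indices in
#' one table (see [strength_centrality()], [bridge_centrality()]).
#'
#' @param net A [symptom_network()].
#' @param ... Passed to [bridge_centrality()].
#' @return Data frame as from [bridge_centrality()].
#' @export
centrality_table <- function(net, ...) bridge_centrality(net, ...)
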