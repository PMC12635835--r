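#' Random-walk (walktrap) community detection
#'
#' Merges nodes by short-random-walk distance and cuts the resulting
#' dendrogram at the partition of maximal modularity. Deterministic: the
#' walk transition probabilities are exact, nothing is sampled. An edgeless
#' graph places every node in its own community.
#'
#' @param graph a `mapper_graph`.
#' @param walk_length random-walk length (default 4).
#' @param n_communities optionally cut the walktrap dendrogram at a fixed
#'   community count instead of the modularity-maximizing cut (useful when
#'   evaluating recovery of a known number of planted groups).
#' @return An object of class `community_partition`: list with `membership`
#'   (named integer vector, node -> community id) and `Q` (modularity of the
#'   partition, computed by [modularity_q()]).
#' @export
detect_communities <- function(graph, walk_length = 4,
                               n_communities = NULL) {
  V <- length(graph$members)
  if (V < 1) stop("graph has no nodes")
  if (nrow(graph$edges) == 0) {
    if (V > 1)
      warning("graph has no edges; every node is its own community")
    membership <- stats::setNames(seq_len(V), names(graph$members))
    Q <- suppressWarnings(modularity_q(graph, membership))
    part <- list(membership = membership, Q = Q)
    return(structure(part, class = "community_partition"))
  }
  g <- mapper_igraph(graph)
  wt <- igraph::cluster_walktrap(g, steps = walk_length, weights = NULL)
  memb <- if (is.null(n_communities)) igraph::membership(wt)
          else igraph::cut_at(wt, no = n_communities)
  membership <- stats::setNames(as.integer(memb), names(graph$members))
  structure(list(membership = membership,
                 Q = modularity_q(graph, membership)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition: ", length(unique(x$membership)),
      " communities over ", length(x$membership),
      " nodes, Q = ", round(x$Q, 4), "\n", sep = "")
  invisible(x)
}

#' Newman modularity of a partition
#'
#' Direct evaluation of
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)`
#' on the unweighted adjacency matrix. An edgeless graph has `Q = 0` (with a
#' warning).
#'
#' @param graph a `mapper_graph`.
#' @param membership integer community id per node (in node order or named
#'   by node).
#' @return Modularity value in \[-0.5, 1\].
#' @export
modularity_q <- function(graph, membership) {
  V <- length(graph$members)
  if (length(membership) != V)
    stop("membership length must equal the node count")
  if (!is.null(names(membership)))
    membership <- membership[names(graph$members)]
  m <- nrow(graph$edges)
  if (m == 0) {
    warning("graph has no edges; modularity defined as 0")
    return(0)
  }
  A <- matrix(0, V, V)
  A[graph$edges] <- 1
  A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  k <- rowSums(A)
  same <- outer(membership, membership, `==`)
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}

#' Connector, cyclic and bridge nodes; transition states
#'
#' * connector: removing the node (with its incident edges) increases the
#'   number of connected components among the remaining nodes;
#' * cyclic: removing it decreases the graph's cycle rank
#'   (`beta1 = |E| - |V| + #components`);
#' * bridge: the node has an edge into a different community;
#' * transition states: member states shared by two bridge nodes that lie in
#'   different communities.
#'
#' @param graph a `mapper_graph`.
#' @param partition a `community_partition`.
#' @return An object of class `node_taxonomy`: list with `connector_nodes`,
#'   `cyclic_nodes`, `bridge_nodes` (integer node ids) and
#'   `transition_states` (sorted state indices).
#' @export
classify_nodes <- function(graph, partition) {
  V <- length(graph$members)
  g <- mapper_igraph(graph)
  beta <- function(gg) {
    comp <- igraph::components(gg)$no
    c(comp, igraph::ecount(gg) - igraph::vcount(gg) + comp)
  }
  b_full <- beta(g)
  connector <- integer(0)
  cyclic <- integer(0)
  for (v in seq_len(V)) {
    gv <- igraph::delete_vertices(g, v)
    bv <- beta(gv)
    if (V > 1 && bv[1] > b_full[1]) connector <- c(connector, v)
    if (bv[2] < b_full[2]) cyclic <- c(cyclic, v)
  }
  memb <- partition$membership
  bridge <- integer(0)
  if (nrow(graph$edges) > 0) {
    cross <- memb[graph$edges[, 1]] != memb[graph$edges[, 2]]
    bridge <- sort(unique(as.integer(graph$edges[cross, ])))
  }
  transition <- integer(0)
  if (length(bridge) >= 2) {
    for (a in seq_along(bridge)) for (b in seq_along(bridge)) {
      if (a < b && memb[bridge[a]] != memb[bridge[b]]) {
        transition <- c(transition,
                        intersect(graph$members[[bridge[a]]],
                                  graph$members[[bridge[b]]]))
      }
    }
  }
  structure(list(connector_nodes = connector,
                 cyclic_nodes = cyclic,
                 bridge_nodes = bridge,
                 transition_states = sort(unique(transition))),
            class = "node_taxonomy")
}

#' @export
print.node_taxonomy <- function(x, ...) {
  cat("node_taxonomy: ", length(x$connector_nodes), " connector, ",
      length(x$cyclic_nodes), " cyclic, ", length(x$bridge_nodes),
      " bridge node(s); ", length(x$transition_states),
      " transition state(s)\n", sep = "")
  invisible(x)
}
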