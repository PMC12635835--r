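#' Manhattan distances between FC states
#'
#' Each state is vectorized as its upper triangle (diagonal excluded); the
#' distance between two states is the sum of absolute differences over
#' region pairs.
#'
#' @param states a `state_sequence`, or a plain list of same-shaped symmetric
#'   matrices.
#' @return A `U x U` symmetric matrix of class `state_distance` with
#'   attribute `metric_name = "manhattan"`.
#' @export
manhattan_distances <- function(states) {
  mats <- if (inherits(states, "state_sequence")) states$states else states
  if (length(mats) < 2) stop("need at least 2 states")
  dims <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), dims), logical(1))))
    stop("states have mismatching shapes")
  V <- state_vectors(mats)
  D <- as.matrix(stats::dist(V, method = "manhattan"))
  dimnames(D) <- NULL
  structure(D, class = c("state_distance", "matrix"),
            metric_name = "manhattan")
}

# symmetrized (union) k-nearest-neighbour graph as an igraph object
knn_graph <- function(D, k) {
  U <- nrow(D)
  if (k >= U) stop("k must be smaller than the number of states (", U, ")")
  adj <- matrix(FALSE, U, U)
  for (i in seq_len(U)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(U)[-i][nb]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  el <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, U - igraph::vcount(g)))
  igraph::E(g)$weight <- D[el]
  g
}

#' Geodesic distances on the k-nearest-neighbour graph
#'
#' Builds the union-symmetrized k-NN graph weighted by `D` and returns the
#' all-pairs shortest-path metric. A disconnected graph is an error (the
#' components are reported; no silent bridging).
#'
#' @param D a `state_distance` (or plain symmetric distance matrix).
#' @param k number of nearest neighbours (default 30).
#' @return A `state_distance` with `metric_name = "geodesic"` and attribute
#'   `k`.
#' @export
geodesic_distances <- function(D, k = 30) {
  g <- knn_graph(unclass(D), k)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("k-NN graph (k = ", k, ") is disconnected: ", comp$no,
         " components of sizes ", sizes)
  }
  G <- igraph::distances(g, weights = igraph::E(g)$weight)
  dimnames(G) <- NULL
  structure(G, class = c("state_distance", "matrix"),
            metric_name = "geodesic", k = k)
}

#' Agglomerative clustering of states from a distance matrix
#'
#' Single- or complete-link agglomeration cut to exactly `n_clusters`
#' groups. Ties in merge heights are resolved by `stats::hclust`'s ordering
#' (lowest pair index first).
#'
#' @param D distance matrix over states.
#' @param linkage `"single"` or `"complete"`.
#' @param n_clusters number of groups to cut to (default 3).
#' @return Integer vector of cluster labels (1-based) per state.
#' @export
hierarchical_clusters <- function(D, linkage = c("single", "complete"),
                                  n_clusters = 3) {
  linkage <- match.arg(linkage)
  U <- nrow(D)
  if (n_clusters > U) stop("n_clusters exceeds the number of states")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  unname(stats::cutree(hc, k = n_clusters))
}

#' Write / read a distance matrix as delimited text
#'
#' Square tab-separated matrix with a header row of 1-based state indices.
#'
#' @param D distance matrix.
#' @param path output file.
#' @return `write_distances()` returns `path` invisibly; `read_distances()`
#'   a `state_distance`.
#' @export
write_distances <- function(D, path) {
  M <- unclass(D)
  colnames(M) <- paste0("state_", seq_len(ncol(M)))
  utils::write.table(M, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @param metric_name metric label to attach on read.
#' @export
read_distances <- function(path, metric_name = "manhattan") {
  M <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M)) stop("distance matrix must be square")
  structure(M, class = c("state_distance", "matrix"),
            metric_name = metric_name)
}
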