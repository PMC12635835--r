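#' Cover parameters for the Mapper construction
#'
#' @param n number of intervals per filter dimension (>= 1).
#' @param o percent overlap between adjacent intervals, in \[0, 100).
#' @return An object of class `cover_params`.
#' @export
cover_params <- function(n, o) {
  if (n < 1) stop("n must be >= 1")
  if (o < 0 || o >= 100) stop("o must lie in [0, 100)")
  structure(list(n = as.integer(n), o = o), class = "cover_params")
}

#' Two-dimensional Isomap filter
#'
#' The Mapper lens: classical multidimensional scaling of the geodesic
#' distance matrix down to 2 dimensions. The geodesic metric is computed on
#' the union-symmetrized k-nearest-neighbour graph of `D` (see
#' [geodesic_distances()]). Axis signs are fixed by flipping any axis on
#' which the first state has a negative coordinate, so repeated runs give
#' identical output.
#'
#' @param D a `state_distance` (original metric).
#' @param k nearest neighbours for the geodesic graph (default 30).
#' @param geodesic optionally a precomputed geodesic `state_distance`
#'   (then `D`/`k` are not used for the graph).
#' @return An object of class `filter_embedding`: list with `coords`
#'   (`U x 2`) and `k`.
#' @export
isomap_filter <- function(D, k = 30, geodesic = NULL) {
  G <- if (is.null(geodesic)) geodesic_distances(D, k) else geodesic
  U <- nrow(G)
  ndim <- min(2L, U - 1L)
  cm <- stats::cmdscale(stats::as.dist(unclass(G)), k = ndim)
  if (ncol(cm) < 2) cm <- cbind(cm, rep(0, U))  # degenerate configurations
  for (j in 1:2) if (cm[1, j] < 0) cm[, j] <- -cm[, j]
  if (any(!is.finite(cm))) stop("non-finite filter coordinates")
  structure(list(coords = unname(cm), k = if (is.null(geodesic)) k
                 else attr(geodesic, "k")),
            class = "filter_embedding")
}

#' Rectangular cover of the filter space
#'
#' Per dimension the bounding box is split into `n` base intervals of equal
#' length `L`, each extended symmetrically by `(o/100) * L / 2` per side so
#' adjacent intervals overlap by `o`% of `L`. The 2-D cover is the product of
#' the two interval families (`n^2` rectangles). A dimension with zero
#' extent collapses to a single interval.
#'
#' @param embedding a `filter_embedding`.
#' @param params a [cover_params()].
#' @return data.frame with one row per rectangle: `rect`, `xmin`, `xmax`,
#'   `ymin`, `ymax` (rectangles ordered x-major).
#' @export
build_cover <- function(embedding, params) {
  stopifnot(inherits(params, "cover_params"))
  axis_intervals <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) return(data.frame(min = lo, max = hi))
    L <- (hi - lo) / params$n
    ext <- (params$o / 100) * L / 2
    i <- seq_len(params$n)
    mins <- lo + (i - 1) * L - ext
    maxs <- lo + i * L + ext
    # pin the outer edges so rounding never excludes the extreme points
    mins[1] <- lo - ext
    maxs[params$n] <- hi + ext
    data.frame(min = mins, max = maxs)
  }
  ix <- axis_intervals(embedding$coords[, 1])
  iy <- axis_intervals(embedding$coords[, 2])
  grid <- expand.grid(x = seq_len(nrow(ix)), y = seq_len(nrow(iy)))
  grid <- grid[order(grid$x, grid$y), ]
  data.frame(rect = seq_len(nrow(grid)),
             xmin = ix$min[grid$x], xmax = ix$max[grid$x],
             ymin = iy$min[grid$y], ymax = iy$max[grid$y])
}

# states (rows of coords) falling in each rectangle, bounds inclusive
cover_members <- function(embedding, cover) {
  x <- embedding$coords[, 1]; y <- embedding$coords[, 2]
  lapply(seq_len(nrow(cover)), function(r)
    which(x >= cover$xmin[r] & x <= cover$xmax[r] &
          y >= cover$ymin[r] & y <= cover$ymax[r]))
}

#' Partial clustering within one cover element
#'
#' Single-link agglomeration of the member states using the original
#' metric, cut by the "continuous" rule: a Gaussian kernel density
#' (Silverman bandwidth) of the merge heights is evaluated between the
#' smallest and largest height; the cutoff is the height at the global
#' density minimum, and clusters are the connected components of the
#' single-link graph strictly below the cutoff. The minimum only counts as
#' a cut when it is a near-empty valley -- density below 5% of the KDE peak
#' -- separating a low group of merge heights (within-cluster) from a high
#' group (between-cluster); without such a valley the members stay in one
#' cluster. This guard keeps evenly spaced chains of states, whose merge
#' heights are unimodal, from being shattered into singletons.
#'
#' @param member_indices state indices inside the rectangle.
#' @param D_original full distance matrix in the original metric.
#' @param valley_frac a density minimum deeper than this fraction of the
#'   KDE peak counts as a gap (default 0.05).
#' @return List of integer vectors (sorted member state indices), one per
#'   cluster.
#' @export
partial_cluster <- function(member_indices, D_original, valley_frac = 0.05) {
  k <- length(member_indices)
  if (k == 0) return(list())
  if (k == 1) return(list(member_indices))
  sub <- unclass(D_original)[member_indices, member_indices]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  h <- hc$height
  if (max(h) == 0 || length(unique(h)) == 1)
    return(list(sort(member_indices)))
  dens <- stats::density(h, bw = stats::bw.nrd0(h), from = min(h),
                         to = max(h), n = 512)
  imin <- which.min(dens$y)
  if (imin == 1 || imin == length(dens$y) ||
      dens$y[imin] > valley_frac * max(dens$y))
    return(list(sort(member_indices)))
  cutoff <- dens$x[imin]
  lab <- stats::cutree(hc, h = cutoff * (1 - 1e-12))
  lapply(split(member_indices, lab), sort)
}

#' Nerve of the partial clusterings
#'
#' Each cluster becomes a node; two nodes are joined iff they share at least
#' one state. Node ids are assigned rectangle-major, cluster-minor.
#'
#' @param clusters_per_rectangle list (over rectangles) of lists of member
#'   index vectors, as produced by [partial_cluster()].
#' @param params the [cover_params()] used (stored as metadata).
#' @param provenance optional list of lens metadata (filter, k, linkage).
#' @return An object of class `mapper_graph`: list with `members` (named
#'   list, node id -> sorted state indices), `edges` (2-column matrix of
#'   node indices, `u < v`), `params`, `provenance`.
#' @export
nerve <- function(clusters_per_rectangle, params = NULL, provenance = NULL) {
  members <- list()
  rect_of <- integer(0)
  for (r in seq_along(clusters_per_rectangle)) {
    for (cl in clusters_per_rectangle[[r]]) {
      members[[length(members) + 1]] <- sort(cl)
      rect_of[length(members)] <- r
    }
  }
  names(members) <- as.character(seq_along(members))
  V <- length(members)
  edges <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("u", "v")))
  if (V >= 2) {
    el <- list()
    for (u in seq_len(V - 1)) for (v in (u + 1):V) {
      if (length(intersect(members[[u]], members[[v]])) > 0)
        el[[length(el) + 1]] <- c(u, v)
    }
    if (length(el)) edges <- do.call(rbind, el)
    colnames(edges) <- c("u", "v")
  }
  structure(list(members = members, edges = edges, rect = rect_of,
                 params = params, provenance = provenance),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  b <- graph_betti(x)
  cat("mapper_graph: ", length(x$members), " nodes, ", nrow(x$edges),
      " edges; (#components, cycle rank) = (", b[1], ", ", b[2], ")\n",
      sep = "")
  invisible(x)
}

#' Build one Mapper graph for fixed cover parameters
#'
#' Cover the filter space, single-link cluster every rectangle's members in
#' the original metric, and take the nerve.
#'
#' @param D original-metric `state_distance`.
#' @param embedding a `filter_embedding`.
#' @param params a [cover_params()].
#' @return A `mapper_graph`.
#' @export
build_mapper <- function(D, embedding, params) {
  cover <- build_cover(embedding, params)
  memb <- cover_members(embedding, cover)
  clusters <- lapply(memb, partial_cluster, D_original = D)
  g <- nerve(clusters, params = params,
             provenance = list(filter = "isomap", k = embedding$k,
                               linkage = "single"))
  covered <- sort(unique(unlist(g$members)))
  if (!identical(covered, seq_len(nrow(unclass(D)))))
    stop("cover failed to include every state")  # defensive; cannot happen
  g
}

#' Betti numbers of a Mapper graph
#'
#' `h0` is the number of connected components. For `h1` two conventions are
#' available. The raw cycle rank of the 1-skeleton is
#' `|E| - |V| + #components`. With `fill_triangles = TRUE` (the default)
#' `h1` is the first Betti number of the nerve complex up to dimension 2:
#' every 3-clique of nodes whose member sets share a common state is filled
#' as a 2-simplex, and its GF(2) boundary rank is subtracted from the cycle
#' rank. Filling matters because any state lying in three or more
#' overlapping cover rectangles creates a clique of nodes through that
#' single shared point; the clique inflates the raw cycle rank although it
#' bounds no hole in the nerve. Only the filled count can agree with the
#' data-space homology a tuned Mapper is meant to reproduce.
#'
#' @param graph a `mapper_graph`.
#' @param fill_triangles fill common-intersection 3-cliques (default
#'   `TRUE`); `FALSE` gives the raw cycle rank.
#' @return Integer vector `c(h0, h1)`.
#' @export
graph_betti <- function(graph, fill_triangles = TRUE) {
  V <- length(graph$members)
  if (V == 0) return(c(0L, 0L))
  g <- mapper_igraph(graph)
  comp <- igraph::components(g)$no
  b1 <- nrow(graph$edges) - V + comp
  if (fill_triangles && b1 > 0) {
    tris <- igraph::cliques(g, min = 3, max = 3)
    filled <- Filter(function(t3) {
      v <- as.integer(t3)
      length(Reduce(intersect, graph$members[v])) > 0
    }, tris)
    if (length(filled)) {
      edge_id <- new.env()
      for (e in seq_len(nrow(graph$edges)))
        assign(paste(graph$edges[e, ], collapse = "-"), e, envir = edge_id)
      cols <- lapply(filled, function(t3) {
        v <- sort(as.integer(t3))
        vapply(list(c(v[1], v[2]), c(v[1], v[3]), c(v[2], v[3])),
               function(p) get(paste(p, collapse = "-"), envir = edge_id),
               integer(1))
      })
      b1 <- b1 - gf2_rank(cols)
    }
  }
  c(comp, as.integer(b1))
}

# rank over GF(2) of a sparse column collection (columns = sorted int rows)
gf2_rank <- function(cols) {
  pivot <- list()
  rank <- 0L
  for (col in cols) {
    col <- sort(col)
    repeat {
      if (length(col) == 0) break
      p <- col[length(col)]
      key <- as.character(p)
      if (is.null(pivot[[key]])) {
        pivot[[key]] <- col
        rank <- rank + 1L
        break
      }
      other <- pivot[[key]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
  }
  rank
}

# igraph view of a mapper_graph (unweighted, undirected)
mapper_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = length(graph$members), directed = FALSE)
  if (nrow(graph$edges) > 0)
    g <- igraph::add_edges(g, t(graph$edges))
  igraph::V(g)$name <- names(graph$members)
  g
}

#' Persistence-guided tuning of the cover parameters
#'
#' Evaluates every `(n, o)` combination on the grid, keeps the graphs whose
#' `(#components, cycle rank)` equals the target Betti signature, and among
#' those returns the one with the fewest nodes (ties: smaller `n`, then
#' smaller `o`). If no combination matches, the closest graph by
#' `|dh0| + |dh1|` is returned with a warning.
#'
#' @param D original-metric `state_distance`.
#' @param embedding a `filter_embedding`.
#' @param target a `betti_signature` (from [dominant_signature()]).
#' @param n_grid candidate interval counts (default 4:8).
#' @param o_grid candidate overlaps in percent (default 25, 30, ..., 45).
#' @return List with `params` (the chosen [cover_params()]), `graph` (the
#'   corresponding `mapper_graph`) and `search` (data.frame of every
#'   combination with node/edge counts and Betti numbers).
#' @export
tune_parameters <- function(D, embedding, target,
                            n_grid = 4:8, o_grid = seq(25, 45, by = 5)) {
  grid <- expand.grid(n = n_grid, o = o_grid)
  grid <- grid[order(grid$n, grid$o), ]
  rows <- vector("list", nrow(grid))
  graphs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- cover_params(grid$n[i], grid$o[i])
    g <- build_mapper(D, embedding, p)
    b <- graph_betti(g)
    graphs[[i]] <- g
    rows[[i]] <- data.frame(n = p$n, o = p$o,
                            nodes = length(g$members),
                            edges = nrow(g$edges),
                            h0 = b[1], h1 = b[2])
  }
  search <- do.call(rbind, rows)
  match_idx <- which(search$h0 == target$h0 & search$h1 == target$h1)
  if (length(match_idx) == 0) {
    warning("no (n, o) combination matched the target signature (",
            target$h0, ", ", target$h1, "); returning the closest graph")
    dist_sig <- abs(search$h0 - target$h0) + abs(search$h1 - target$h1)
    match_idx <- which(dist_sig == min(dist_sig))
  }
  cand <- search[match_idx, ]
  best <- match_idx[order(cand$nodes, cand$n, cand$o)][1]
  list(params = cover_params(search$n[best], search$o[best]),
       graph = graphs[[best]], search = search)
}
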