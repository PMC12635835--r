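embedding_of <- function(coords) {
  structure(list(coords = as.matrix(coords), k = NA),
            class = "filter_embedding")
}

test_that("two-point MDS preserves the distance and duplicates coincide", {
  D <- matrix(c(0, 3, 3, 0), 2)
  emb <- isomap_filter(structure(D, class = c("state_distance", "matrix")),
                       k = 1)
  expect_equal(dist(emb$coords)[1], 3, tolerance = 1e-9)

  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 1), c(2, 0))
  Dd <- as.matrix(dist(pts))
  embd <- isomap_filter(Dd, k = 3)
  expect_equal(embd$coords[1, ], embd$coords[2, ], tolerance = 1e-9)
})

test_that("a 1-D chain embeds with a monotone first coordinate", {
  D <- as.matrix(dist(c(0, 1, 2.1, 3.4, 4.5, 6, 7.3)))
  emb <- isomap_filter(D, k = 2)
  x <- emb$coords[, 1]
  expect_true(all(diff(x) > 0) || all(diff(x) < 0))
})

test_that("cover construction follows the symmetric-extension rule", {
  emb <- embedding_of(cbind(c(0, 1, 0.5), c(0, 1, 0.5)))
  one <- build_cover(emb, cover_params(1, 0))
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one[, c("xmin", "xmax", "ymin", "ymax")]),
               c(xmin = 0, xmax = 1, ymin = 0, ymax = 1))

  cov <- build_cover(emb, cover_params(2, 50))
  xints <- unique(cov[, c("xmin", "xmax")])
  expect_equal(sort(xints$xmin), c(-0.125, 0.375))
  expect_equal(sort(xints$xmax), c(0.625, 1.125))

  # coverage invariant under arbitrary parameters
  set.seed(2)
  emb2 <- embedding_of(matrix(rnorm(60), ncol = 2))
  for (n in c(1, 3, 5)) for (o in c(0, 20, 45)) {
    cov2 <- build_cover(emb2, cover_params(n, o))
    memb <- dfcmapper:::cover_members(emb2, cov2)
    expect_setequal(unique(unlist(memb)), seq_len(30))
  }

  # zero-extent dimension collapses to a single interval
  flat <- embedding_of(cbind(c(0, 1, 2), 0))
  covf <- build_cover(flat, cover_params(3, 25))
  expect_equal(nrow(covf), 3)
})

test_that("partial clustering separates far blobs and keeps chains whole", {
  pts <- c(0, 0.1, 0.2, 30, 30.1, 30.2)
  D <- as.matrix(dist(pts))
  cl <- partial_cluster(seq_along(pts), D)
  expect_length(cl, 2)
  expect_setequal(cl[[1]], 1:3)
  expect_setequal(cl[[2]], 4:6)
  # minimum-spanning-tree oracle: cutting the largest MST edge gives the
  # same bipartition
  hts <- mst_heights(D)
  expect_gt(hts[length(hts)] / hts[length(hts) - 1], 10)

  expect_equal(partial_cluster(3L, D), list(3L))
  expect_equal(partial_cluster(integer(0), D), list())
  same <- matrix(0, 4, 4)
  expect_length(partial_cluster(1:4, same), 1)
  # an evenly spaced chain has unimodal merge heights: stays one cluster
  chain <- as.matrix(dist(c(0, 1, 2.1, 2.9, 4, 5.2)))
  expect_length(partial_cluster(1:6, chain), 1)
})

test_that("the nerve adds an edge exactly when member sets intersect", {
  clusters <- list(list(c(1L, 2L)), list(c(3L, 4L)))
  g0 <- nerve(clusters)
  expect_equal(nrow(g0$edges), 0)

  clusters <- list(list(c(1L, 2L)), list(c(2L, 3L)))
  g1 <- nerve(clusters)
  expect_equal(nrow(g1$edges), 1)

  # recompute the iff-property from memberships on a real construction
  st <- compute_states(generate_dataset(small_cyclic_config()))
  D <- manhattan_distances(st)
  emb <- isomap_filter(D, k = 15)
  g <- build_mapper(D, emb, cover_params(4, 30))
  V <- length(g$members)
  has_edge <- matrix(FALSE, V, V)
  has_edge[g$edges] <- TRUE
  has_edge <- has_edge | t(has_edge)
  for (u in seq_len(V - 1)) for (v in (u + 1):V) {
    expect_identical(has_edge[u, v],
                     length(intersect(g$members[[u]],
                                      g$members[[v]])) > 0)
  }
  # membership union covers every state
  expect_setequal(unique(unlist(g$members)), seq_len(nrow(unclass(D))))
})

test_that("graph Betti numbers fill common-intersection cliques", {
  # a 4-clique through one shared point is contractible in the nerve
  members <- list(c(1L, 9L), c(2L, 9L), c(3L, 9L), c(4L, 9L))
  g <- nerve(lapply(members, list))
  expect_equal(nrow(g$edges), 6)
  expect_equal(graph_betti(g, fill_triangles = FALSE), c(1L, 3L))
  expect_equal(graph_betti(g), c(1L, 0L))
  # a genuine 4-cycle (no triple intersections) keeps its loop
  ring <- graph_from_edges(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  expect_equal(graph_betti(ring), c(1L, 1L))
})

test_that("more overlap never removes edges on a stable fixture", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(20, 0, 0.2), ncol = 2),
                 matrix(rnorm(20, 4, 0.2), ncol = 2),
                 matrix(rnorm(20, c(0, 8), 0.2), ncol = 2))
  D <- as.matrix(dist(blobs))
  emb <- embedding_of(blobs)
  prev <- -1L
  for (o in c(10, 25, 40)) {
    g <- build_mapper(D, emb, cover_params(3, o))
    expect_gte(nrow(g$edges), prev)
    prev <- nrow(g$edges)
  }
})

test_that("tuning matches the target signature with minimal nodes and fixed
           tie-breaking", {
  # a single tight blob: target (1, 0) should give few nodes at small n
  set.seed(8)
  pts <- matrix(rnorm(40, sd = 0.3), ncol = 2)
  D <- as.matrix(dist(pts))
  emb <- isomap_filter(D, k = 5)
  target <- structure(list(h0 = 1L, h1 = 0L), class = "betti_signature")
  tuned <- tune_parameters(D, emb, target, n_grid = 2:4,
                           o_grid = c(25, 35))
  expect_equal(graph_betti(tuned$graph), c(1L, 0L))
  best_nodes <- min(tuned$search$nodes[tuned$search$h0 == 1 &
                                         tuned$search$h1 == 0])
  expect_equal(length(tuned$graph$members), best_nodes)
  # among equal node counts, ties resolve to smaller n then smaller o
  s <- tuned$search
  match_rows <- s[s$h0 == 1 & s$h1 == 0 & s$nodes == best_nodes, ]
  expect_equal(tuned$params$n, min(match_rows$n))
  expect_equal(tuned$params$o,
               min(match_rows$o[match_rows$n == tuned$params$n]))
})

test_that("an unmatchable target warns and returns the closest graph", {
  pts <- matrix(rnorm(20, sd = 0.1), ncol = 2)
  D <- as.matrix(dist(pts))
  emb <- isomap_filter(D, k = 3)
  target <- structure(list(h0 = 5L, h1 = 7L), class = "betti_signature")
  expect_warning(tuned <- tune_parameters(D, emb, target, n_grid = 2:3,
                                          o_grid = c(25, 30)),
                 "no \\(n, o\\)")
  expect_s3_class(tuned$graph, "mapper_graph")
})
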