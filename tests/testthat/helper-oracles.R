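# Independent oracles used across the suite. Each is deliberately written
# with a different algorithm than the package implementation it checks.

# ---- Vietoris-Rips persistence by full boundary-matrix reduction ----
# All simplices up to triangles enter one global boundary matrix sorted by
# (filtration value, dimension); standard left-to-right GF(2) reduction
# gives the (birth, death) pairs. Suitable for <= 12 points.
oracle_rips <- function(D, R = max(D)) {
  n <- nrow(D)
  simp <- list()
  for (v in seq_len(n)) simp[[length(simp) + 1]] <-
    list(verts = v, dim = 0L, filt = 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (D[i, j] <= R)
    simp[[length(simp) + 1]] <- list(verts = c(i, j), dim = 1L,
                                     filt = D[i, j])
  if (n >= 3)
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      f <- max(D[i, j], D[i, k], D[j, k])
      if (f <= R) simp[[length(simp) + 1]] <-
        list(verts = c(i, j, k), dim = 2L, filt = f)
    }
  ord <- order(vapply(simp, `[[`, numeric(1), "filt"),
               vapply(simp, `[[`, integer(1), "dim"))
  simp <- simp[ord]
  key <- vapply(simp, function(s) paste(s$verts, collapse = "-"),
                character(1))
  idx_of <- stats::setNames(seq_along(simp), key)
  boundary <- lapply(simp, function(s) {
    if (s$dim == 0L) return(integer(0))
    faces <- utils::combn(s$verts, s$dim, simplify = FALSE)
    sort(unname(idx_of[vapply(faces, paste, character(1),
                              collapse = "-")]))
  })
  low_of <- integer(length(simp))  # row -> owning column
  pairs <- list()
  for (jcol in seq_along(simp)) {
    col <- boundary[[jcol]]
    while (length(col) > 0) {
      low <- col[length(col)]
      if (low_of[low] == 0) break
      other <- boundary[[low_of[low]]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
    boundary[[jcol]] <- col
    if (length(col) > 0) {
      low <- col[length(col)]
      low_of[low] <- jcol
      pairs[[length(pairs) + 1]] <- c(low, jcol)
    }
  }
  paired <- unlist(pairs)
  rows <- list()
  for (pr in pairs) {
    s_birth <- simp[[pr[1]]]
    s_death <- simp[[pr[2]]]
    rows[[length(rows) + 1]] <- data.frame(dimension = s_birth$dim,
                                           birth = s_birth$filt,
                                           death = s_death$filt)
  }
  for (i in seq_along(simp)) {
    # unpaired simplex that is itself a cycle (zero reduced boundary,
    # never killed) -> infinite class
    if (length(boundary[[i]]) == 0 && !(i %in% paired))
      rows[[length(rows) + 1]] <- data.frame(dimension = simp[[i]]$dim,
                                             birth = simp[[i]]$filt,
                                             death = Inf)
  }
  df <- do.call(rbind, rows)
  df <- df[df$dimension <= 1 & df$death > df$birth, , drop = FALSE]
  df[order(df$dimension, df$birth, df$death), , drop = FALSE]
}

# drop zero-persistence H0 rows and compare two diagrams
expect_same_diagram <- function(pd, oracle, tol = 1e-10) {
  a <- as.data.frame(pd)
  a <- a[a$death > a$birth, , drop = FALSE]
  a <- a[order(a$dimension, a$birth, a$death), , drop = FALSE]
  b <- oracle[order(oracle$dimension, oracle$birth, oracle$death), ,
              drop = FALSE]
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$dimension, b$dimension)
  expect_equal(a$birth, b$birth, tolerance = tol)
  expect_equal(a$death, b$death, tolerance = tol)
}

# ---- exhaustive modularity maximization ----
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (g in seq_len(max(p) + 1L)) out[[length(out) + 1]] <- c(p, g)
  }
  out
}

best_partition_exhaustive <- function(graph, bipartitions_only = FALSE) {
  V <- length(graph$members)
  parts <- if (bipartitions_only) {
    lapply(0:(2^(V - 1) - 1), function(mask)
      c(1L, 1L + as.integer(intToBits(mask)[seq_len(V - 1)])))
  } else {
    all_partitions(V)
  }
  qs <- vapply(parts, function(p)
    suppressWarnings(modularity_q(graph, p)), numeric(1))
  list(Q = max(qs), membership = parts[[which.max(qs)]])
}

# ---- change-point dynamic program using lm() segment costs ----
oracle_changepoints <- function(y, beta, min_size = 3) {
  n <- length(y)
  cost <- matrix(Inf, n, n)
  for (a in seq_len(n)) for (b in a:n) {
    if (b - a + 1 < min_size) next
    t <- a:b
    cost[a, b] <- sum(stats::resid(stats::lm(y[t] ~ t))^2)
  }
  F <- c(0, rep(Inf, n))
  back <- integer(n)
  for (b in seq_len(n)) {
    for (a in seq_len(b)) {
      val <- F[a] + cost[a, b] + if (a > 1) beta else 0
      if (val < F[b + 1]) { F[b + 1] <- val; back[b] <- a }
    }
  }
  cps <- integer(0)
  b <- n
  while (b > 0) {
    a <- back[b]
    if (a > 1) cps <- c(a, cps)
    b <- a - 1
  }
  cps
}

# ---- misc ----
mst_heights <- function(D) {
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  sort(igraph::E(igraph::mst(g))$weight)
}

# naive agglomerative clustering (single or complete link), O(n^3)
naive_linkage_clusters <- function(D, linkage, n_clusters) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > n_clusters) {
    best <- c(Inf, 0, 0)
    for (a in seq_len(length(clusters) - 1))
      for (b in (a + 1):length(clusters)) {
        ds <- D[clusters[[a]], clusters[[b]], drop = FALSE]
        d <- if (linkage == "single") min(ds) else max(ds)
        if (d < best[1]) best <- c(d, a, b)
      }
    a <- best[2]; b <- best[3]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

adjusted_rand <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}
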