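# Fixtures are generated in code and memoized for the session: the default
# (study-scale) dataset and its derived objects are shared by several files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_dataset <- function() fixture("default_dataset", {
  generate_dataset(generator_config())
})

default_states <- function() fixture("default_states", {
  compute_states(default_dataset())
})

default_distances <- function() fixture("default_distances", {
  manhattan_distances(default_states())
})

default_diagram <- function() fixture("default_diagram", {
  rips_persistence(default_distances())
})

default_tuned <- function() fixture("default_tuned", {
  D <- default_distances()
  tune_parameters(D, isomap_filter(D, k = 30),
                  dominant_signature(default_diagram()))
})

# small fast dataset with the same cyclic structure (loop closes once)
small_cyclic_config <- function(seed = 7) {
  generator_config(P = 4,
                   N_per_network = c(salience = 5, frontoparietal = 4,
                                     default = 6),
                   T_volumes = 121,
                   regime_schedule = cyclic_schedule(121, block_len = 30),
                   seed = seed)
}

# stationary single-regime dataset for null-model behaviour
stationary_config <- function(seed = 11, T_volumes = 120) {
  generator_config(P = 4,
                   N_per_network = c(salience = 5, frontoparietal = 4,
                                     default = 6),
                   T_volumes = T_volumes,
                   regime_schedule = rep("mid", T_volumes),
                   seed = seed)
}

# deterministic mapper_graph realizing an arbitrary edge list: each edge
# gets one shared state, each node one private state, so the nerve
# reproduces exactly the requested graph
graph_from_edges <- function(n_nodes, edges) {
  members <- lapply(seq_len(n_nodes), function(v) v)
  nxt <- n_nodes
  if (length(edges)) {
    edges <- matrix(edges, ncol = 2)
    for (e in seq_len(nrow(edges))) {
      nxt <- nxt + 1L
      members[[edges[e, 1]]] <- c(members[[edges[e, 1]]], nxt)
      members[[edges[e, 2]]] <- c(members[[edges[e, 2]]], nxt)
    }
  }
  nerve(lapply(members, list))
}

# points on a planar circle as a distance matrix
circle_distances <- function(n, radius = 1, jitter_sd = 0, seed = 1) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(radius * cos(th), radius * sin(th))
  if (jitter_sd > 0) xy <- xy + matrix(rnorm(2 * n, sd = jitter_sd), n)
  as.matrix(dist(xy))
}
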