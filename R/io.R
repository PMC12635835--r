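#' Full-pipeline configuration
#'
#' All stage parameters with their standard defaults. Unknown arguments are
#' rejected.
#'
#' @param W,S sliding-window width and step (volumes).
#' @param tau_start,tau_step,kappa_max threshold grid and density ceiling.
#' @param k nearest neighbours for the geodesic lens.
#' @param n_grid,o_grid Mapper cover tuning grids.
#' @param walk_length walktrap random-walk length.
#' @param start_state first state of the suspense-correlation span.
#' @param alpha significance level for the surrogate test.
#' @param n_surrogates surrogate count.
#' @param seed seed for the surrogate draws.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(W = 18, S = 1,
                            tau_start = 0.3, tau_step = 0.1, kappa_max = 0.5,
                            k = 30,
                            n_grid = 4:8, o_grid = seq(25, 45, by = 5),
                            walk_length = 4, start_state = 29,
                            alpha = 0.05, n_surrogates = 100, seed = 1) {
  cfg <- list(W = W, S = S, tau_start = tau_start, tau_step = tau_step,
              kappa_max = kappa_max, k = k, n_grid = n_grid, o_grid = o_grid,
              walk_length = walk_length, start_state = start_state,
              alpha = alpha, n_surrogates = n_surrogates, seed = seed)
  window_params(W, S)  # validates
  if (kappa_max <= 0 || kappa_max > 1) stop("kappa_max must lie in (0, 1]")
  if (k < 1) stop("k must be >= 1")
  if (start_state < 1) stop("start_state must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Keys not understood by [pipeline_config()] are an error.
#'
#' @param path JSON file with a subset of the configuration fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write / read a synthetic dataset as delimited text plus manifest
#'
#' One tab-separated region x time matrix per subject
#' (`subject_<p>.tsv`, row names = region labels) and a `manifest.json`
#' holding the network map, TR and subject file list.
#'
#' @param dataset a `dfc_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` a
#'   `dfc_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "dfc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("subject_%03d.tsv", seq_along(dataset$subjects))
  for (p in seq_along(dataset$subjects)) {
    utils::write.table(dataset$subjects[[p]], file.path(dir, files[p]),
                       sep = "\t", quote = FALSE, col.names = FALSE,
                       row.names = TRUE)
  }
  manifest <- list(subject_files = files,
                   network_map = as.list(dataset$network_map),
                   TR = dataset$TR)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  network_map <- unlist(manifest$network_map)
  subjects <- lapply(manifest$subject_files, function(f) {
    tab <- utils::read.table(file.path(dir, f), sep = "\t",
                             header = FALSE, row.names = 1)
    M <- as.matrix(tab)
    colnames(M) <- NULL
    if (anyNA(M))
      stop("missing values in ", f, " (rows ",
           paste(which(rowSums(is.na(M)) > 0), collapse = ", "), ")")
    M
  })
  shapes <- vapply(subjects, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("subject matrices have mismatching shapes")
  labels <- rownames(subjects[[1]])
  if (!setequal(labels, names(network_map)))
    stop("region labels in matrices do not match the manifest network_map")
  structure(list(subjects = subjects, region_labels = labels,
                 network_map = network_map[labels], TR = manifest$TR),
            class = "dfc_dataset")
}

#' Write / read a suspense trace as single-column CSV
#'
#' @param trace a `suspense_trace`.
#' @param path output CSV (column `suspense`, one row per volume).
#' @param TR repetition time attached on read.
#' @return `write_suspense()` returns `path` invisibly; `read_suspense()` a
#'   `suspense_trace`.
#' @export
write_suspense <- function(trace, path) {
  utils::write.csv(data.frame(suspense = trace$values), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_suspense
#' @export
read_suspense <- function(path, TR = NA_real_) {
  df <- utils::read.csv(path)
  if (!"suspense" %in% names(df)) stop("expected a 'suspense' column")
  if (anyNA(df$suspense))
    stop("missing values in suspense trace (rows ",
         paste(which(is.na(df$suspense)), collapse = ", "), ")")
  structure(list(values = df$suspense, TR = TR), class = "suspense_trace")
}

#' Write the thresholded states as a delimited matrix
#'
#' `U x N(N-1)/2` tab-separated matrix: one row per state (1-based index in
#' the first column), columns are upper-triangle region pairs in
#' column-major order (pair (1,2), (1,3), (2,3), (1,4), ...), as documented
#' in the header line.
#'
#' @param states a `state_sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  V <- state_vectors(states$states)
  labels <- rownames(states$states[[1]])
  N <- length(labels)
  ij <- which(upper.tri(diag(N)), arr.ind = TRUE)
  ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE]  # column-major order
  pair_names <- paste0(labels[ij[, 1]], "|", labels[ij[, 2]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# upper-triangle FC per state, column-major pair ",
                    "order; tau = ", states$tau), con)
  utils::write.table(data.frame(state = seq_len(nrow(V)), V),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("state", pair_names))
  invisible(path)
}

#' Write weight series, aligned suspense and state index as CSV
#'
#' @param weights a `weight_series`.
#' @param aligned_suspense per-state suspense (or `NULL` to omit).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, aligned_suspense = NULL, path) {
  df <- data.frame(state = seq_len(nrow(weights)), unclass(weights))
  if (!is.null(aligned_suspense)) df$suspense <- aligned_suspense
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a Mapper graph as GraphML plus node/edge CSVs
#'
#' Node attributes: comma-joined member state indices, node size, community
#' id (if a partition is supplied) and mean aligned suspense over the
#' members (if supplied).
#'
#' @param graph a `mapper_graph`.
#' @param dir output directory.
#' @param partition optional `community_partition`.
#' @param aligned_suspense optional per-state suspense values.
#' @param prefix file-name prefix (default `"mapper"`).
#' @return The GraphML path, invisibly.
#' @export
write_mapper <- function(graph, dir, partition = NULL,
                         aligned_suspense = NULL, prefix = "mapper") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- mapper_igraph(graph)
  igraph::V(g)$members <- vapply(graph$members, paste, collapse = ",",
                                 FUN.VALUE = character(1))
  igraph::V(g)$size <- lengths(graph$members)
  if (!is.null(partition))
    igraph::V(g)$community <- as.integer(partition$membership)
  if (!is.null(aligned_suspense))
    igraph::V(g)$mean_suspense <- vapply(graph$members, function(m)
      mean(aligned_suspense[m]), numeric(1))
  gml <- file.path(dir, paste0(prefix, ".graphml"))
  igraph::write_graph(g, gml, format = "graphml")
  nodes <- data.frame(node = seq_along(graph$members),
                      size = lengths(graph$members),
                      members = igraph::V(g)$members)
  if (!is.null(partition)) nodes$community <- as.integer(partition$membership)
  if (!is.null(aligned_suspense))
    nodes$mean_suspense <- igraph::V(g)$mean_suspense
  utils::write.csv(nodes, file.path(dir, paste0(prefix, "_nodes.csv")),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(graph$edges),
                   file.path(dir, paste0(prefix, "_edges.csv")),
                   row.names = FALSE)
  invisible(gml)
}

#' Run the full analysis pipeline on files
#'
#' Reads a dataset (and optionally a suspense trace), then executes the
#' stages in order: sliding-window FC and thresholding, Manhattan state
#' distances, Rips persistence and dominant signature, persistence-guided
#' Mapper tuning, walktrap communities and node taxonomy, connectivity
#' weights (plus suspense correlations and change points when a trace is
#' given), and optionally the surrogate test. All artifacts and a run
#' manifest are written under `out_dir`. Deterministic for a fixed
#' `config$seed`. A stage failure aborts with the stage name; files written
#' by the failed run are removed.
#'
#' @param config a [pipeline_config()].
#' @param dataset_path directory readable by [read_dataset()].
#' @param suspense_path optional CSV readable by [read_suspense()].
#' @param out_dir output directory.
#' @param run_surrogates include the surrogate stage (default `FALSE`;
#'   it dominates the runtime).
#' @return Invisibly, a list with the main in-memory results (`states`,
#'   `distances`, `diagram`, `signature`, `tuned`, `partition`, `taxonomy`,
#'   `weights`, `correlations`, `changepoints`, `null_report`).
#' @export
run_pipeline <- function(config, dataset_path, suspense_path = NULL,
                         out_dir, run_surrogates = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  stage <- "read inputs"
  res <- list()
  tryCatch({
    dataset <- read_dataset(dataset_path)
    suspense <- if (!is.null(suspense_path)) read_suspense(suspense_path,
                                                           TR = dataset$TR)

    stage <- "dfc"
    wp <- window_params(config$W, config$S)
    avg <- average_states(dataset, wp)
    tau <- select_threshold(avg$states, config$kappa_max,
                            config$tau_start, config$tau_step)
    states <- apply_threshold(avg, tau)
    res$states <- states
    note(write_states(states, file.path(out_dir, "states.tsv")))

    stage <- "state_space"
    D <- manhattan_distances(states)
    res$distances <- D
    note(write_distances(D, file.path(out_dir, "distances.tsv")))

    stage <- "homology"
    diagram <- rips_persistence(D)
    signature <- dominant_signature(diagram)
    res$diagram <- diagram
    res$signature <- signature
    note(write_diagram(diagram, file.path(out_dir, "persistence.csv")))

    stage <- "mapper"
    emb <- isomap_filter(D, k = config$k)
    tuned <- tune_parameters(D, emb, signature,
                             n_grid = config$n_grid, o_grid = config$o_grid)
    res$tuned <- tuned

    stage <- "graph_topology"
    partition <- detect_communities(tuned$graph, config$walk_length)
    taxonomy <- classify_nodes(tuned$graph, partition)
    res$partition <- partition
    res$taxonomy <- taxonomy

    stage <- "network_dynamics"
    weights <- connectivity_weights(states, dataset$network_map)
    res$weights <- weights
    aligned <- NULL
    if (!is.null(suspense)) {
      aligned <- align_suspense(suspense, states$window_starts, wp$W)
      res$correlations <- suspense_correlations(
        weights, aligned, start_state = config$start_state)
      res$changepoints <- detect_changepoints(aligned)
      jsonlite::write_json(as.list(res$correlations),
                           note(file.path(out_dir, "correlations.json")),
                           auto_unbox = TRUE, digits = NA)
    }
    note(write_weights(weights, aligned, file.path(out_dir, "weights.csv")))
    note(write_mapper(tuned$graph, out_dir, partition, aligned))

    summary_json <- list(
      Q = partition$Q,
      n_communities = length(unique(partition$membership)),
      connector_nodes = taxonomy$connector_nodes,
      cyclic_nodes = taxonomy$cyclic_nodes,
      bridge_nodes = taxonomy$bridge_nodes,
      transition_states = taxonomy$transition_states)
    jsonlite::write_json(summary_json,
                         note(file.path(out_dir, "graph_summary.json")),
                         auto_unbox = TRUE, digits = NA)

    if (run_surrogates) {
      stage <- "surrogate"
      sp <- surrogate_params(config$n_surrogates, config$seed, config$alpha)
      include <- if (is.null(suspense)) "eta" else c("eta", "correlations")
      res$null_report <- null_test(dataset, suspense, sp, wp,
                                   include = include,
                                   start_state = config$start_state,
                                   knn = config$k)
      nr <- res$null_report
      json <- list(eta = nr$eta[c("observed", "percentile", "p_value",
                                  "significant")])
      if (!is.null(nr$correlations))
        json$correlations <- lapply(nr$correlations, function(r)
          r[c("observed", "percentile", "p_value", "significant")])
      jsonlite::write_json(json,
                           note(file.path(out_dir, "null_report.json")),
                           auto_unbox = TRUE, digits = NA)
    }

    stage <- "manifest"
    manifest <- list(
      config = unclass(config),
      U = length(states$states),
      tau = tau,
      signature = list(h0 = signature$h0, h1 = signature$h1),
      mapper = list(n = tuned$params$n, o = tuned$params$o,
                    nodes = length(tuned$graph$members),
                    edges = nrow(tuned$graph$edges)),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, note(file.path(out_dir, "manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
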