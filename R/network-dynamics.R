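canonical_pairs <- function() {
  c("salience_salience", "frontoparietal_frontoparietal",
    "salience_frontoparietal", "default_default",
    "salience_default", "frontoparietal_default")
}

#' Within- and between-network connectivity weights over time
#'
#' For each state, the within-network weight of a network is the mean
#' thresholded FC over its unordered region pairs,
#' `W = 2/(n1(n1-1)) * sum c_ij`; the between-network weight of a pair of
#' networks is the mean over all cross pairs, `W = 1/(n1 n2) * sum c_ij`.
#' Six series are produced, ordered salience-salience,
#' frontoparietal-frontoparietal, salience-frontoparietal, default-default,
#' salience-default, frontoparietal-default.
#'
#' @param states a `state_sequence` (thresholded).
#' @param network_map named character vector, region label -> network (the
#'   three canonical networks `salience`, `frontoparietal`, `default`).
#' @return A `U x 6` matrix of class `weight_series` (columns as above).
#' @export
connectivity_weights <- function(states, network_map) {
  mats <- states$states
  labels <- rownames(mats[[1]])
  if (is.null(labels)) labels <- names(network_map)
  if (!all(labels %in% names(network_map)))
    stop("unmapped region(s): ",
         paste(setdiff(labels, names(network_map)), collapse = ", "))
  nets <- network_map[labels]
  canon <- c("salience", "frontoparietal", "default")
  if (!all(nets %in% canon))
    stop("network_map contains unknown network(s): ",
         paste(setdiff(unique(nets), canon), collapse = ", "))
  sizes <- table(factor(nets, levels = canon))
  if (any(sizes < 2))
    stop("within-network weight undefined: network(s) with < 2 regions: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  masks <- lapply(canonical_pairs(), function(pair) {
    parts <- strsplit(pair, "_")[[1]]
    M <- outer(nets == parts[1], nets == parts[2]) |
         outer(nets == parts[2], nets == parts[1])
    M & upper.tri(M)
  })
  names(masks) <- canonical_pairs()
  W <- vapply(mats, function(m)
    vapply(masks, function(M) mean(m[M]), numeric(1)),
    numeric(6))
  W <- t(W)
  colnames(W) <- canonical_pairs()
  structure(W, class = c("weight_series", "matrix"))
}

#' Align a per-volume rating trace to the FC states
#'
#' Default convention: each state's value is the mean of the trace over the
#' state's window span. The `"center"` alternative takes the sample at the
#' window midpoint (rounded down).
#'
#' @param trace a `suspense_trace` or numeric vector (one value per volume).
#' @param starts 1-based window start volumes (`state_sequence$window_starts`).
#' @param W window width in volumes.
#' @param method `"mean"` (default) or `"center"`.
#' @return Numeric vector of length `U`.
#' @export
align_suspense <- function(trace, starts, W, method = c("mean", "center")) {
  method <- match.arg(method)
  vals <- if (inherits(trace, "suspense_trace")) trace$values else trace
  needed <- max(starts) + W - 1
  if (length(vals) < needed)
    stop("trace has ", length(vals), " samples; windows need ", needed)
  vapply(starts, function(s) {
    span <- vals[s:(s + W - 1)]
    if (method == "mean") mean(span) else span[1 + (W - 1) %/% 2]
  }, numeric(1))
}

#' Correlation of the six weight series with the aligned suspense
#'
#' Pearson correlation per series over states `start_state..end_state`
#' (1-based, inclusive). A constant series on that range yields `NA` with a
#' warning.
#'
#' @param weights a `weight_series`.
#' @param aligned_suspense per-state suspense values (length `U`).
#' @param start_state first state of the correlation span (default 29).
#' @param end_state last state (default: last available state).
#' @return Named numeric vector of six correlations.
#' @export
suspense_correlations <- function(weights, aligned_suspense,
                                  start_state = 29,
                                  end_state = nrow(weights)) {
  if (start_state > end_state) stop("start_state must be <= end_state")
  if (length(aligned_suspense) != nrow(weights))
    stop("aligned suspense length must equal the number of states")
  idx <- start_state:end_state
  s <- aligned_suspense[idx]
  out <- vapply(colnames(weights), function(cn) {
    w <- weights[idx, cn]
    if (stats::sd(w) == 0 || stats::sd(s) == 0) {
      warning("constant series for ", cn, "; correlation undefined")
      return(NA_real_)
    }
    stats::cor(w, s)
  }, numeric(1))
  out
}

# linear-fit residual sum of squares for segment [a, b] from cumulative sums
make_segment_cost <- function(y) {
  n <- length(y)
  t <- seq_len(n)
  c1 <- cumsum(c(0, rep(1, n)))
  ct <- cumsum(c(0, t)); ct2 <- cumsum(c(0, t^2))
  cy <- cumsum(c(0, y)); cy2 <- cumsum(c(0, y^2)); cty <- cumsum(c(0, t * y))
  function(a, b) {
    k <- b - a + 1
    St <- ct[b + 1] - ct[a]; St2 <- ct2[b + 1] - ct2[a]
    Sy <- cy[b + 1] - cy[a]; Sy2 <- cy2[b + 1] - cy2[a]
    Sty <- cty[b + 1] - cty[a]
    Sxx <- St2 - St^2 / k
    Sxy <- Sty - St * Sy / k
    Syy <- Sy2 - Sy^2 / k
    rss <- if (Sxx <= 0) Syy else Syy - Sxy^2 / Sxx
    max(rss, 0)
  }
}

#' Penalized piecewise-linear change-point detection
#'
#' Exact minimization of total segment cost plus a per-change-point penalty,
#' where the cost of a segment is the residual sum of squares of an ordinary
#' least-squares line fit. The optimum is found by pruned dynamic
#' programming (PELT); pruning never changes the solution. The default
#' penalty is BIC-like: `3 * sigma2 * log(n)` per change point (two segment
#' parameters plus the break), with `sigma2` estimated from first
#' differences as `var(diff(y)) / 2`.
#'
#' @param series numeric vector (length >= 4).
#' @param penalty `"bic"` or a nonnegative number used directly.
#' @param min_size minimum segment length (default 3).
#' @return An object of class `changepoint_set`: integer vector of 1-based
#'   indices at which a new segment starts (strictly increasing, within
#'   `[2, U]`), with attributes `penalty` and `segments`.
#' @export
detect_changepoints <- function(series, penalty = "bic", min_size = 3) {
  n <- length(series)
  if (n < 4) stop("series must have length >= 4")
  if (min_size < 2) stop("min_size must be >= 2 for a line fit")
  beta <- if (identical(penalty, "bic")) {
    sigma2 <- stats::var(diff(series)) / 2
    # floor keeps the penalty above the rounding noise of the cumulative
    # segment costs on noise-free signals
    floor_s2 <- 1e-8 * max(stats::var(series), .Machine$double.eps)
    if (!is.finite(sigma2)) sigma2 <- floor_s2
    sigma2 <- max(sigma2, floor_s2)
    3 * sigma2 * log(n)
  } else {
    stopifnot(is.numeric(penalty), penalty >= 0)
    penalty
  }
  cost <- make_segment_cost(series)
  # F[t+1] = optimal cost of y[1..t]; cp backtracking pointers
  F <- c(-beta, rep(Inf, n))
  last <- integer(n + 1)
  cand <- 0L  # candidate last-change positions (0-based "tau")
  for (t in seq_len(n)) {
    if (t < min_size) next
    ok <- cand[t - cand >= min_size]
    if (length(ok) == 0) next
    vals <- vapply(ok, function(s) F[s + 1] + cost(s + 1, t) + beta,
                   numeric(1))
    i <- which.min(vals)
    F[t + 1] <- vals[i]
    last[t + 1] <- ok[i]
    # PELT pruning: drop s that can never be optimal again; candidates too
    # recent to have been usable at this t are kept untouched
    keep <- vapply(seq_along(ok), function(j)
      F[ok[j] + 1] + cost(ok[j] + 1, t) <= F[t + 1], logical(1))
    recent <- cand[t - cand < min_size]
    cand <- sort(unique(c(ok[keep], recent, t)))
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- last[t + 1]
    if (s > 0) cps <- c(s + 1L, cps)
    t <- s
  }
  structure(cps, class = "changepoint_set", penalty = beta,
            segments = length(cps) + 1L)
}

#' @export
print.changepoint_set <- function(x, ...) {
  cat("changepoint_set: ", length(unclass(x)), " change point(s)",
      if (length(unclass(x))) paste0(" at ",
        paste(unclass(x), collapse = ", ")) else "", "\n", sep = "")
  invisible(x)
}

#' Overlap between change points and transition states
#'
#' Counts the change points lying within `tolerance` states of any
#' transition state.
#'
#' @param changepoints a `changepoint_set` (or integer vector of state
#'   indices).
#' @param taxonomy a `node_taxonomy` (or integer vector of transition state
#'   indices).
#' @param tolerance maximum index distance (default 1).
#' @return Integer count.
#' @export
changepoint_transition_overlap <- function(changepoints, taxonomy,
                                           tolerance = 1) {
  cps <- as.integer(unclass(changepoints))
  ts <- if (inherits(taxonomy, "node_taxonomy")) taxonomy$transition_states
        else as.integer(taxonomy)
  if (length(cps) == 0 || length(ts) == 0) return(0L)
  sum(vapply(cps, function(cp) any(abs(cp - ts) <= tolerance), logical(1)))
}
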