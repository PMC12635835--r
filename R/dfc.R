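#' Sliding-window parameters
#'
#' @param W window width in volumes (>= 2).
#' @param S step in volumes (>= 1).
#' @return An object of class `window_params`.
#' @export
window_params <- function(W = 18, S = 1) {
  if (S < 1) stop("S must be >= 1")
  if (W < 2) stop("W must be >= 2")
  structure(list(W = as.integer(W), S = as.integer(S)),
            class = "window_params")
}

#' Number of sliding windows
#'
#' `U = floor((T - W) / S) + 1`; for `S = 1` this is the familiar
#' `T - W + 1`.
#'
#' @param T_volumes number of volumes.
#' @param params a [window_params()].
#' @return Integer window count.
#' @export
n_windows <- function(T_volumes, params) {
  if (params$W > T_volumes) stop("window wider than the series (W > T)")
  as.integer((T_volumes - params$W) %/% params$S + 1L)
}

# 1-based start volumes of each window
window_starts <- function(T_volumes, params) {
  U <- n_windows(T_volumes, params)
  1L + (seq_len(U) - 1L) * params$S
}

# all windowed Pearson matrices of one subject via cumulative sums of
# X_t and the outer products X_t X_t^T; exact and O(N^2 T) overall
window_corrs <- function(X, starts, W, zero_variance, subject = NULL) {
  N <- nrow(X); T_volumes <- ncol(X)
  cs <- cbind(0, t(apply(X, 1, cumsum)))          # N x (T+1) sums
  cp <- array(0, c(N, N, T_volumes + 1))          # cumulative outer products
  for (t in seq_len(T_volumes))
    cp[, , t + 1] <- cp[, , t] + tcrossprod(X[, t])
  out <- array(NA_real_, c(N, N, length(starts)))
  for (w in seq_along(starts)) {
    a <- starts[w]; b <- a + W - 1L
    Sx <- cs[, b + 1] - cs[, a]
    Sxy <- cp[, , b + 1] - cp[, , a]
    Cov <- Sxy - tcrossprod(Sx) / W
    v <- pmax(diag(Cov), 0)
    if (any(v <= 0)) {
      tag <- if (is.null(subject)) "" else paste0(" (subject ", subject, ")")
      if (zero_variance == "error")
        stop("zero-variance region in window ", w, tag)
      warning("zero-variance region in window ", w, tag,
              "; affected correlations set to 0")
    }
    denom <- sqrt(outer(v, v))
    C <- ifelse(denom > 0, Cov / denom, 0)
    C <- pmin(pmax(C, -1), 1)
    diag(C) <- 1
    out[, , w] <- C
  }
  dimnames(out) <- list(rownames(X), rownames(X), NULL)
  out
}

#' Per-subject sliding-window functional connectivity
#'
#' Window `w` covers volumes `[1 + (w-1)S, (w-1)S + W]` (1-based, inclusive).
#' Each window yields the Pearson correlation matrix over regions.
#'
#' @param dataset a `dfc_dataset`.
#' @param params a [window_params()].
#' @param zero_variance what to do when a region has zero variance within a
#'   window: `"zero"` (default) sets the affected correlations to 0 with a
#'   warning, `"error"` aborts.
#' @return List of length `P`; each element an `N x N x U` array of
#'   correlation matrices.
#' @export
sliding_window_fc <- function(dataset, params,
                              zero_variance = c("zero", "error")) {
  zero_variance <- match.arg(zero_variance)
  stopifnot(inherits(dataset, "dfc_dataset"))
  T_volumes <- ncol(dataset$subjects[[1]])
  N <- nrow(dataset$subjects[[1]])
  starts <- window_starts(T_volumes, params)
  lapply(dataset$subjects, window_corrs, starts = starts, W = params$W,
         zero_variance = zero_variance)
}

#' Fisher-transformed average of correlation matrices
#'
#' Entrywise `tanh(mean(artanh(r)))` over subjects. Correlations at exactly
#' +/-1 are clipped to +/-(1 - 1e-7) first so the transform stays finite.
#'
#' @param mats list of same-shaped correlation matrices (one per subject).
#' @return The back-transformed mean matrix (diagonal restored to 1).
#' @export
fisher_average <- function(mats) {
  stopifnot(length(mats) >= 1)
  dims <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), dims), logical(1))))
    stop("all matrices must share the same shape")
  clip <- 1 - 1e-7
  acc <- 0
  for (m in mats) acc <- acc + atanh(pmin(pmax(m, -clip), clip))
  out <- tanh(acc / length(mats))
  diag(out) <- 1
  out
}

#' Subject-averaged sliding-window FC states
#'
#' Runs [sliding_window_fc()] subject by subject and Fisher-averages across
#' subjects per window, without retaining the per-subject arrays.
#'
#' @inheritParams sliding_window_fc
#' @return List with `states` (list of `U` unthresholded mean correlation
#'   matrices), `window_starts` (1-based) and `params`.
#' @export
average_states <- function(dataset, params,
                           zero_variance = c("zero", "error")) {
  zero_variance <- match.arg(zero_variance)
  T_volumes <- ncol(dataset$subjects[[1]])
  N <- nrow(dataset$subjects[[1]])
  starts <- window_starts(T_volumes, params)
  U <- length(starts)
  clip <- 1 - 1e-7
  acc <- array(0, c(N, N, U))
  for (p in seq_along(dataset$subjects)) {
    cors <- window_corrs(dataset$subjects[[p]], starts, params$W,
                         zero_variance, subject = p)
    acc <- acc + atanh(pmin(pmax(cors, -clip), clip))
  }
  acc <- tanh(acc / length(dataset$subjects))
  states <- lapply(seq_len(U), function(w) {
    m <- acc[, , w]
    diag(m) <- 1
    rownames(m) <- colnames(m) <- dataset$region_labels
    m
  })
  list(states = states, window_starts = starts, params = params)
}

#' Connection density of a thresholded state
#'
#' `kappa = 2 * eps / (N (N - 1))` where `eps` counts upper-triangle weights
#' at or above `tau`. The diagonal is excluded.
#'
#' @param mat symmetric connectivity matrix.
#' @param tau threshold.
#' @return Density in \[0, 1\].
#' @export
connection_density <- function(mat, tau) {
  N <- nrow(mat)
  if (is.null(N) || N < 2) stop("matrix must be at least 2 x 2")
  ut <- mat[upper.tri(mat)]
  sum(ut >= tau) / length(ut)
}

#' Select the global FC threshold
#'
#' Walks the grid `tau_start, tau_start + tau_step, ...` and returns the
#' first (minimal) value at which every state's connection density is
#' strictly below `kappa_max`.
#'
#' @param states list of unthresholded mean correlation matrices.
#' @param kappa_max density ceiling (default 0.5).
#' @param tau_start first candidate threshold (default 0.3).
#' @param tau_step grid step (default 0.1).
#' @return The selected threshold.
#' @export
select_threshold <- function(states, kappa_max = 0.5,
                             tau_start = 0.3, tau_step = 0.1) {
  if (length(states) == 0) stop("empty state list")
  tau <- tau_start
  repeat {
    dmax <- max(vapply(states, connection_density, numeric(1), tau = tau))
    if (dmax < kappa_max) return(tau)
    if (tau >= 1)
      stop("no threshold <= 1 achieves density < ", kappa_max,
           " (max density at tau = 1 is ", signif(dmax, 4), ")")
    tau <- min(tau + tau_step, 1)
  }
}

#' Apply the global threshold to the averaged states
#'
#' Entries below `tau` (including all negative correlations) become 0;
#' surviving entries keep their value. Idempotent.
#'
#' @param averaged result of [average_states()] (or a compatible list with
#'   `states`, `window_starts`, `params`).
#' @param tau threshold in \[0, 1\].
#' @return An object of class `state_sequence`: `states` (list of `U`
#'   thresholded symmetric matrices), `window_starts`, `params`, `tau`.
#' @export
apply_threshold <- function(averaged, tau) {
  stopifnot(tau >= 0)
  states <- lapply(averaged$states, function(m) {
    m[m < tau] <- 0
    diag(m) <- 1
    m
  })
  structure(list(states = states,
                 window_starts = averaged$window_starts,
                 params = averaged$params,
                 tau = tau),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("state_sequence: ", length(x$states), " states of ",
      nrow(x$states[[1]]), " x ", nrow(x$states[[1]]),
      " regions (W = ", x$params$W, ", S = ", x$params$S,
      ", tau = ", x$tau, ")\n", sep = "")
  invisible(x)
}

#' Dataset to thresholded state sequence in one call
#'
#' Convenience wrapper: [average_states()], [select_threshold()],
#' [apply_threshold()].
#'
#' @inheritParams sliding_window_fc
#' @inheritParams select_threshold
#' @return A `state_sequence` (the selected `tau` is stored in the result).
#' @export
compute_states <- function(dataset, params = window_params(),
                           kappa_max = 0.5, tau_start = 0.3, tau_step = 0.1,
                           zero_variance = c("zero", "error")) {
  avg <- average_states(dataset, params, zero_variance = zero_variance)
  tau <- select_threshold(avg$states, kappa_max, tau_start, tau_step)
  apply_threshold(avg, tau)
}

# upper-triangle vectorization shared by the distance and variance code;
# column-major over the upper triangle: (1,2), (1,3), (2,3), (1,4), ...
state_vectors <- function(states) {
  N <- nrow(states[[1]])
  M <- N * (N - 1L) / 2L
  t(vapply(states, function(m) m[upper.tri(m)], numeric(M)))
}
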