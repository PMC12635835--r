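#' Surrogate-test parameters
#'
#' @param n_surrogates number of surrogate datasets (>= 20; default 100 so
#'   the test default stays fast, 1000 for production-scale runs).
#' @param seed integer seed for the surrogate phase draws.
#' @param alpha significance level (default 0.05).
#' @return An object of class `surrogate_params`.
#' @export
surrogate_params <- function(n_surrogates = 100, seed = 1, alpha = 0.05) {
  if (n_surrogates < 20) stop("n_surrogates must be >= 20")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_surrogates < 1 / alpha - 1)
    stop("n_surrogates too small to resolve alpha = ", alpha)
  structure(list(n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed), alpha = alpha),
            class = "surrogate_params")
}

# phase-randomize one region x time matrix with a single phase function
# shared by all rows (regions); Hermitian symmetry keeps the output real and
# every row's amplitude spectrum is exactly preserved
phase_randomize_matrix <- function(X) {
  T_volumes <- ncol(X)
  half <- (T_volumes - 1) %/% 2
  psi <- rep(0, T_volumes)
  if (half >= 1) {
    ph <- stats::runif(half, 0, 2 * pi)
    psi[2:(half + 1)] <- ph
    psi[T_volumes - (1:half) + 1] <- -ph
  }
  if (T_volumes %% 2 == 0) {
    # Nyquist bin must stay real: phase shift of 0 or pi
    psi[T_volumes / 2 + 1] <- pi * stats::rbinom(1, 1, 0.5)
  }
  rot <- exp(1i * psi)
  t(apply(X, 1, function(x)
    Re(stats::fft(stats::fft(x) * rot, inverse = TRUE) / T_volumes)))
}

#' Phase-randomized surrogate dataset
#'
#' For every subject, one random phase function `psi(f) ~ U[0, 2pi)` is
#' added to the Fourier phases of all regions (Hermitian symmetry preserved,
#' DC untouched, Nyquist rotated by 0 or pi). Sharing the phase across
#' regions preserves all auto- and cross-correlations of the full series --
#' the static-FC null -- while destroying any time-localized connectivity
#' structure. Uses the current RNG state; seed externally for
#' reproducibility.
#'
#' @param dataset a `dfc_dataset`.
#' @return A `dfc_dataset` with phase-randomized subject matrices.
#' @export
phase_randomize <- function(dataset) {
  stopifnot(inherits(dataset, "dfc_dataset"))
  out <- dataset
  out$subjects <- lapply(dataset$subjects, function(X) {
    Y <- phase_randomize_matrix(X)
    dimnames(Y) <- dimnames(X)
    Y
  })
  out
}

#' dFC variance statistic
#'
#' Mean over region pairs of the temporal variance of each pair's FC series,
#' computed on the unthresholded averaged states.
#'
#' @param states list of (unthresholded) correlation matrices, an
#'   [average_states()] result, or a `state_sequence`.
#' @return The variance statistic `eta` (scalar, >= 0).
#' @export
dfc_variance <- function(states) {
  mats <- if (inherits(states, "state_sequence")) states$states
          else if (is.list(states) && !is.null(states$states)) states$states
          else states
  if (length(mats) < 2) stop("need at least 2 states")
  V <- state_vectors(mats)
  mean(apply(V, 2, stats::var))
}

# percentile p-value: fraction of null draws at least as extreme, with the
# observed value included (never exactly 0)
tail_p <- function(observed, null_sample, side = c("upper", "two")) {
  side <- match.arg(side)
  B <- length(null_sample)
  if (side == "upper") {
    (1 + sum(null_sample >= observed)) / (B + 1)
  } else {
    p_up <- (1 + sum(null_sample >= observed)) / (B + 1)
    p_lo <- (1 + sum(null_sample <= observed)) / (B + 1)
    min(1, 2 * min(p_up, p_lo))
  }
}

#' Surrogate significance test of dFC statistics
#'
#' Draws `n_surrogates` phase-randomized datasets and recomputes, per
#' surrogate, the requested statistics: the dFC variance `eta` (upper-tail
#' test: dynamics inflate variance), the six suspense correlations
#' (two-sided), and optionally the maximal walktrap modularity of the Mapper
#' graphs over the untuned `(n, o)` grid (upper-tail). The observed value is
#' significant at `alpha` when its percentile p-value does not exceed
#' `alpha`.
#'
#' @param dataset a `dfc_dataset` (observed data).
#' @param suspense a `suspense_trace` (required for the correlation
#'   statistic; `NULL` skips it).
#' @param params a [surrogate_params()].
#' @param window a [window_params()].
#' @param include character subset of `c("eta", "correlations",
#'   "modularity")`.
#' @param start_state first state of the correlation span (default 29).
#' @param knn nearest neighbours for the geodesic lens when modularity is
#'   included.
#' @param n_grid,o_grid untuned cover grid for the null modularity.
#' @return An object of class `null_report`: per statistic a list with
#'   `observed`, `null` (length `n_surrogates`), `percentile` (0-100),
#'   `p_value` and `significant`.
#' @export
null_test <- function(dataset, suspense = NULL,
                      params = surrogate_params(),
                      window = window_params(),
                      include = c("eta", "correlations"),
                      start_state = 29, knn = 30,
                      n_grid = 4:8, o_grid = seq(25, 45, by = 5)) {
  include <- match.arg(include, c("eta", "correlations", "modularity"),
                       several.ok = TRUE)
  if ("correlations" %in% include && is.null(suspense))
    stop("the correlation statistic needs a suspense trace")

  stat_of <- function(ds) {
    avg <- average_states(ds, window)
    out <- list()
    if ("eta" %in% include) out$eta <- dfc_variance(avg$states)
    if ("correlations" %in% include || "modularity" %in% include) {
      tau <- select_threshold(avg$states)
      seq_states <- apply_threshold(avg, tau)
      if ("correlations" %in% include) {
        Wse <- connectivity_weights(seq_states, ds$network_map)
        al <- align_suspense(suspense, seq_states$window_starts, window$W)
        out$correlations <- suppressWarnings(
          suspense_correlations(Wse, al, start_state = start_state))
      }
      if ("modularity" %in% include) {
        D <- manhattan_distances(seq_states)
        emb <- isomap_filter(D, k = knn)
        qs <- c()
        for (n in n_grid) for (o in o_grid) {
          g <- build_mapper(D, emb, cover_params(n, o))
          qs <- c(qs, suppressWarnings(detect_communities(g)$Q))
        }
        out$modularity <- max(qs)
      }
    }
    out
  }

  obs <- stat_of(dataset)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  B <- params$n_surrogates
  null_eta <- numeric(0)
  null_cor <- NULL
  null_q <- numeric(0)
  for (b in seq_len(B)) {
    sur <- phase_randomize(dataset)
    st <- stat_of(sur)
    if ("eta" %in% include) null_eta[b] <- st$eta
    if ("correlations" %in% include) {
      if (is.null(null_cor))
        null_cor <- matrix(NA_real_, B, 6,
                           dimnames = list(NULL, canonical_pairs()))
      null_cor[b, ] <- st$correlations
    }
    if ("modularity" %in% include) null_q[b] <- st$modularity
  }

  report <- list()
  if ("eta" %in% include) {
    p <- tail_p(obs$eta, null_eta, "upper")
    report$eta <- list(observed = obs$eta, null = null_eta,
                       percentile = 100 * (1 - p), p_value = p,
                       significant = p <= params$alpha)
  }
  if ("correlations" %in% include) {
    report$correlations <- lapply(canonical_pairs(), function(cn) {
      nv <- null_cor[, cn]
      ov <- obs$correlations[[cn]]
      if (is.na(ov) || all(is.na(nv)))
        return(list(observed = ov, null = nv, percentile = NA_real_,
                    p_value = NA_real_, significant = NA))
      p <- tail_p(ov, nv[!is.na(nv)], "two")
      list(observed = ov, null = nv,
           percentile = 100 * mean(nv[!is.na(nv)] <= ov),
           p_value = p, significant = p <= params$alpha)
    })
    names(report$correlations) <- canonical_pairs()
  }
  if ("modularity" %in% include) {
    p <- tail_p(obs$modularity, null_q, "upper")
    report$modularity <- list(observed = obs$modularity, null = null_q,
                              percentile = 100 * (1 - p), p_value = p,
                              significant = p <= params$alpha)
  }
  structure(c(report, list(params = params)), class = "null_report")
}

#' @export
print.null_report <- function(x, ...) {
  cat("null_report (", x$params$n_surrogates, " surrogates, alpha = ",
      x$params$alpha, ")\n", sep = "")
  if (!is.null(x$eta))
    cat("  eta: observed ", signif(x$eta$observed, 4), ", p = ",
        signif(x$eta$p_value, 3),
        if (isTRUE(x$eta$significant)) " *" else "", "\n", sep = "")
  if (!is.null(x$correlations)) {
    for (cn in names(x$correlations)) {
      r <- x$correlations[[cn]]
      cat("  rho[", cn, "]: ", signif(r$observed, 3), ", p = ",
          signif(r$p_value, 3),
          if (isTRUE(r$significant)) " *" else "", "\n", sep = "")
    }
  }
  if (!is.null(x$modularity))
    cat("  max Q: observed ", signif(x$modularity$observed, 4), ", p = ",
        signif(x$modularity$p_value, 3),
        if (isTRUE(x$modularity$significant)) " *" else "", "\n", sep = "")
  invisible(x)
}
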