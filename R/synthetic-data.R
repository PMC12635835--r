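#' Specify a stationary connectivity regime
#'
#' A regime is a block-structured correlation matrix over the three canonical
#' large-scale networks (salience, fronto-parietal, default): one coupling
#' value per network (within-network correlation) and one per unordered
#' network pair (between-network correlation). Volumes scheduled under a
#' regime are drawn i.i.d. from a zero-mean Gaussian with this correlation
#' structure.
#'
#' @param within named numeric of length 3 with names `salience`,
#'   `frontoparietal`, `default`: within-network correlation (dimensionless,
#'   in (-1, 1)).
#' @param between named numeric of length 3 with names
#'   `salience_frontoparietal`, `salience_default`, `frontoparietal_default`:
#'   between-network correlation.
#' @return An object of class `regime_spec`.
#' @export
regime_spec <- function(within, between) {
  wn <- c("salience", "frontoparietal", "default")
  bn <- c("salience_frontoparietal", "salience_default", "frontoparietal_default")
  if (!all(wn %in% names(within)))
    stop("`within` must be named: ", paste(wn, collapse = ", "))
  if (!all(bn %in% names(between)))
    stop("`between` must be named: ", paste(bn, collapse = ", "))
  if (any(abs(c(within[wn], between[bn])) >= 1))
    stop("couplings must lie strictly inside (-1, 1)")
  structure(list(within = within[wn], between = between[bn]),
            class = "regime_spec")
}

#' Default covariance regimes
#'
#' Three regimes emulating low, medium and high arousal phases. The
#' salience-frontoparietal coupling rises monotonically from `low` to `high`
#' while every coupling involving the default network falls, so the planted
#' suspense trace (a monotone function of the salience-frontoparietal
#' coupling, see [generate_suspense()]) correlates positively with the
#' salience/fronto-parietal weight series and negatively with the
#' default-involving ones.
#'
#' @return Named list of three [regime_spec()] objects (`low`, `mid`, `high`).
#' @export
default_regimes <- function() {
  list(
    low = regime_spec(
      within  = c(salience = 0.30, frontoparietal = 0.30, default = 0.45),
      between = c(salience_frontoparietal = 0.10, salience_default = 0.25,
                  frontoparietal_default = 0.25)),
    mid = regime_spec(
      within  = c(salience = 0.40, frontoparietal = 0.40, default = 0.30),
      between = c(salience_frontoparietal = 0.30, salience_default = 0.20,
                  frontoparietal_default = 0.20)),
    high = regime_spec(
      within  = c(salience = 0.50, frontoparietal = 0.50, default = 0.20),
      between = c(salience_frontoparietal = 0.45, salience_default = 0.05,
                  frontoparietal_default = 0.05))
  )
}

#' Default cyclic regime schedule
#'
#' Repeats the block sequence low -> mid -> high in blocks of `block_len`
#' volumes until `T_volumes` is reached. Because the only transitions are
#' low->mid, mid->high and high->low, the sliding-window state trajectory
#' interpolates along the three sides of a triangle in state space, giving it
#' the topology of a circle (one connected component, one loop). The default
#' block length of 48 makes the 193-volume default schedule one closed lap
#' (low, mid, high, low): the trajectory leaves the low phase and revisits
#' it, closing the loop exactly once, which keeps the secondary loops formed
#' by repeated noisy traversals well below the dominant class.
#'
#' @param T_volumes total number of volumes.
#' @param block_len volumes per regime block (default 48).
#' @return Character vector of length `T_volumes` with regime labels.
#' @export
cyclic_schedule <- function(T_volumes, block_len = 48) {
  stopifnot(T_volumes >= 1, block_len >= 1)
  labs <- rep(rep(c("low", "mid", "high"), each = block_len),
              length.out = T_volumes)
  labs
}

#' Configuration for the synthetic dFC generator
#'
#' Bundles and validates every generator parameter. The defaults are the
#' study conditions used throughout the package's tests: `P = 20` subjects,
#' `N = 12 + 10 + 21 = 43` regions across the three networks, `T = 193`
#' volumes at `TR = 2.47` s, the cyclic three-regime schedule, and Gaussian
#' observation noise with standard deviation 0.2.
#'
#' @param P number of subjects (>= 1).
#' @param N_per_network named integer vector: regions per network
#'   (`salience`, `frontoparietal`, `default`).
#' @param T_volumes number of volumes per subject.
#' @param TR repetition time in seconds.
#' @param regimes named list of [regime_spec()] objects.
#' @param regime_schedule character vector of length `T_volumes`; every label
#'   must name an entry of `regimes`.
#' @param noise_sd standard deviation of the independent observation noise
#'   added to every region/volume.
#' @param seed integer seed making the draw reproducible.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(P = 20,
                             N_per_network = c(salience = 12,
                                               frontoparietal = 10,
                                               default = 21),
                             T_volumes = 193,
                             TR = 2.47,
                             regimes = default_regimes(),
                             regime_schedule = cyclic_schedule(T_volumes),
                             noise_sd = 0.2,
                             seed = 7) {
  if (P < 1) stop("P must be >= 1")
  nn <- c("salience", "frontoparietal", "default")
  if (!all(nn %in% names(N_per_network)))
    stop("N_per_network must be named: ", paste(nn, collapse = ", "))
  N_per_network <- N_per_network[nn]
  if (any(N_per_network < 1)) stop("each network needs >= 1 region")
  if (T_volumes < 2) stop("T_volumes must be >= 2")
  if (TR <= 0) stop("TR must be positive")
  if (length(regime_schedule) != T_volumes)
    stop("regime_schedule length (", length(regime_schedule),
         ") must equal T_volumes (", T_volumes, ")")
  missing_lab <- setdiff(unique(regime_schedule), names(regimes))
  if (length(missing_lab))
    stop("scheduled regime(s) not defined: ", paste(missing_lab, collapse = ", "))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(P = as.integer(P), N_per_network = N_per_network,
                 T_volumes = as.integer(T_volumes), TR = TR,
                 regimes = regimes, regime_schedule = regime_schedule,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_config")
}

# Block correlation matrix implied by a regime over the given network sizes.
regime_correlation <- function(spec, N_per_network) {
  nets <- rep(names(N_per_network), N_per_network)
  N <- length(nets)
  S <- matrix(0, N, N)
  pair_key <- function(a, b) {
    ord <- c("salience", "frontoparietal", "default")
    p <- ord[sort(match(c(a, b), ord))]
    paste(p, collapse = "_")
  }
  for (i in seq_len(N)) for (j in seq_len(N)) {
    S[i, j] <- if (i == j) 1
      else if (nets[i] == nets[j]) spec$within[[nets[i]]]
      else spec$between[[pair_key(nets[i], nets[j])]]
  }
  S
}

#' Generate a synthetic multi-subject dFC dataset
#'
#' Draws, for every subject, an N x T activity matrix whose volumes are
#' sampled from the scheduled regime's block correlation matrix (zero-mean
#' Gaussian) plus independent observation noise. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return An object of class `dfc_dataset`: list with `subjects` (list of
#'   `P` region x time matrices), `region_labels`, `network_map` (named
#'   character, region -> network), `TR`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  Ns <- config$N_per_network
  N <- sum(Ns)
  nets <- rep(names(Ns), Ns)
  labels <- paste0(substr(nets, 1, 3), "_",
                   unlist(lapply(Ns, seq_len), use.names = FALSE))
  chols <- lapply(names(config$regimes), function(lab) {
    S <- regime_correlation(config$regimes[[lab]], Ns)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("regime '", lab, "' implies a non positive-definite covariance")
    ch
  })
  names(chols) <- names(config$regimes)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  sched <- config$regime_schedule
  subjects <- vector("list", config$P)
  for (p in seq_len(config$P)) {
    X <- matrix(0, N, config$T_volumes)
    # draw in volume order so the stream is schedule-independent per volume
    Z <- matrix(stats::rnorm(N * config$T_volumes), N)
    for (t in seq_len(config$T_volumes)) {
      X[, t] <- drop(crossprod(chols[[sched[t]]], Z[, t]))
    }
    if (config$noise_sd > 0)
      X <- X + config$noise_sd * matrix(stats::rnorm(N * config$T_volumes), N)
    rownames(X) <- labels
    subjects[[p]] <- X
  }
  structure(list(subjects = subjects,
                 region_labels = labels,
                 network_map = stats::setNames(nets, labels),
                 TR = config$TR),
            class = "dfc_dataset")
}

#' @export
print.dfc_dataset <- function(x, ...) {
  cat("dfc_dataset: ", length(x$subjects), " subject(s), ",
      nrow(x$subjects[[1]]), " regions x ", ncol(x$subjects[[1]]),
      " volumes (TR = ", x$TR, " s)\n", sep = "")
  cat("networks:", paste(sprintf("%s=%d", names(table(x$network_map)),
                                 as.integer(table(x$network_map))),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Generate the planted suspense rating trace
#'
#' The trace is a monotone (affine) function of the scheduled
#' salience-frontoparietal coupling, rescaled to the rating range \[0, 10\].
#' By construction its window-aligned correlation with the
#' salience-frontoparietal weight series is positive and its correlation with
#' every default-involving series is negative (the default regimes move those
#' couplings in opposite directions).
#'
#' @param config a [generator_config()].
#' @param schedule regime labels per volume; defaults to the config's
#'   schedule.
#' @return An object of class `suspense_trace`: list with `values`
#'   (length-T numeric in \[0, 10\]) and `TR`.
#' @export
generate_suspense <- function(config, schedule = config$regime_schedule) {
  stopifnot(inherits(config, "generator_config"))
  if (length(schedule) != config$T_volumes)
    stop("schedule length must equal T_volumes")
  coupling <- vapply(schedule, function(lab)
    config$regimes[[lab]]$between[["salience_frontoparietal"]], numeric(1))
  rng <- range(coupling)
  vals <- if (diff(rng) == 0) rep(5, length(coupling))
    else 10 * (coupling - rng[1]) / diff(rng)
  structure(list(values = unname(vals), TR = config$TR),
            class = "suspense_trace")
}

#' @export
print.suspense_trace <- function(x, ...) {
  cat("suspense_trace: ", length(x$values), " volumes, range [",
      round(min(x$values), 3), ", ", round(max(x$values), 3), "]\n", sep = "")
  invisible(x)
}
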