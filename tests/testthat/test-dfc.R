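test_that("window count matches brute-force enumeration for any (T, W, S)", {
  for (T_volumes in c(10, 37, 193)) {
    for (W in c(2, 5, 18)) {
      for (S in c(1, 2, 5)) {
        if (W > T_volumes) next
        # brute force: slide until the window no longer fits
        count <- 0L
        start <- 1L
        while (start + W - 1L <= T_volumes) {
          count <- count + 1L
          start <- start + S
        }
        expect_identical(n_windows(T_volumes, window_params(W, S)), count)
      }
    }
  }
  expect_identical(n_windows(193, window_params(18, 1)), 176L)
})

test_that("windowed correlations are exact Pearson values", {
  cfg <- small_cyclic_config()
  ds <- generate_dataset(cfg)
  wp <- window_params(10, 3)
  fc <- sliding_window_fc(ds, wp)
  X <- ds$subjects[[2]]
  # window 4 covers volumes 10..19 (1-based)
  ref <- cor(t(X[, 10:19]))
  expect_equal(unname(fc[[2]][, , 4]), unname(ref), tolerance = 1e-12)
  expect_true(all(abs(fc[[1]]) <= 1 + 1e-12))
  expect_equal(diag(fc[[1]][, , 1]), rep(1, nrow(X)), ignore_attr = TRUE)
})

test_that("self- and anti-correlated regions give +1 and -1", {
  X <- rbind(a = sin(1:40), b = -sin(1:40), c = cos(1:40))
  ds <- structure(list(subjects = list(X), region_labels = rownames(X),
                       network_map = c(a = "salience", b = "salience",
                                       c = "default"), TR = 1),
                  class = "dfc_dataset")
  fc <- sliding_window_fc(ds, window_params(12, 4))[[1]]
  expect_equal(fc[1, 1, ], rep(1, dim(fc)[3]))
  expect_equal(fc[1, 2, ], rep(-1, dim(fc)[3]), tolerance = 1e-12)
})

test_that("zero-variance windows follow the configured policy", {
  set.seed(30)
  X <- rbind(a = c(rep(1, 5), rnorm(15)), b = rnorm(20))
  ds <- structure(list(subjects = list(X), region_labels = c("a", "b"),
                       network_map = c(a = "salience", b = "default"),
                       TR = 1),
                  class = "dfc_dataset")
  expect_warning(fc <- sliding_window_fc(ds, window_params(5, 5)),
                 "zero-variance")
  expect_equal(fc[[1]][1, 2, 1], 0)
  expect_error(sliding_window_fc(ds, window_params(5, 5),
                                 zero_variance = "error"),
               "zero-variance")
})

test_that("Fisher averaging matches its closed form and is permutation
           invariant", {
  m <- function(r) matrix(c(1, r, r, 1), 2)
  expect_equal(fisher_average(list(m(0.37), m(0.37)))[1, 2], 0.37)
  expect_equal(fisher_average(list(m(0.5), m(-0.5)))[1, 2], 0)
  expect_equal(fisher_average(list(m(0.2), m(0.6)))[1, 2],
               tanh((atanh(0.2) + atanh(0.6)) / 2))
  expect_equal(fisher_average(list(m(1), m(1)))[1, 2], 1, tolerance = 1e-6)
  set.seed(1)
  mats <- lapply(1:5, function(i) m(runif(1, -0.9, 0.9)))
  expect_equal(fisher_average(mats), fisher_average(rev(mats)))
})

test_that("average_states equals the explicit per-window Fisher average", {
  cfg <- small_cyclic_config()
  ds <- generate_dataset(cfg)
  wp <- window_params(12, 7)
  avg <- average_states(ds, wp)
  fc <- sliding_window_fc(ds, wp)
  w <- 3
  ref <- fisher_average(lapply(fc, function(a) a[, , w]))
  expect_equal(unname(avg$states[[w]]), unname(ref), tolerance = 1e-12)
})

test_that("connection density follows its defining arithmetic", {
  M <- matrix(0, 4, 4)
  M[upper.tri(M)] <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3)
  M <- M + t(M); diag(M) <- 1
  expect_equal(connection_density(M, 0.5), 0.5)  # 3 of 6 survive
  expect_equal(connection_density(M, 0.05), 1)
  expect_equal(connection_density(M, 0.95), 0)
  expect_error(connection_density(matrix(1), 0.5), "2 x 2")
})

test_that("densities are non-increasing in tau and threshold selection walks
           the grid", {
  st <- default_states()
  raw <- fixture("default_avg", average_states(default_dataset(),
                                               window_params()))
  taus <- seq(0, 1, by = 0.1)
  dens <- vapply(taus, function(tv)
    max(vapply(raw$states, connection_density, numeric(1), tau = tv)),
    numeric(1))
  expect_true(all(diff(dens) <= 1e-12))

  # constructed state with densities 0.8 at 0.3, 0.6 at 0.4, 0.4 at 0.5
  M <- matrix(0, 5, 5)
  M[upper.tri(M)] <- c(rep(0.55, 4), rep(0.45, 2), rep(0.35, 2),
                       rep(0.1, 2))
  M <- M + t(M); diag(M) <- 1
  expect_equal(connection_density(M, 0.3), 0.8)
  expect_equal(connection_density(M, 0.4), 0.6)
  expect_equal(connection_density(M, 0.5), 0.4)
  expect_equal(select_threshold(list(M)), 0.5)
  expect_equal(select_threshold(list(diag(2))), 0.3)  # density 0 already
  expect_error(select_threshold(list()), "empty")
})

test_that("thresholding zeroes negatives and sub-threshold entries and is
           idempotent", {
  M <- matrix(c(1, 0.29, -0.9, 0.29, 1, 0.6, -0.9, 0.6, 1), 3)
  avg <- list(states = list(M), window_starts = 1L,
              params = window_params(3, 1))
  st <- apply_threshold(avg, 0.3)
  expect_equal(st$states[[1]][1, 2], 0)
  expect_equal(st$states[[1]][1, 3], 0)
  expect_equal(st$states[[1]][2, 3], 0.6)
  again <- apply_threshold(list(states = st$states,
                                window_starts = st$window_starts,
                                params = st$params), 0.3)
  expect_equal(again$states, st$states)
  nonneg <- matrix(c(1, 0.2, 0.2, 1), 2)
  st0 <- apply_threshold(list(states = list(nonneg), window_starts = 1L,
                              params = window_params(2, 1)), 0)
  expect_equal(st0$states[[1]], nonneg)
})
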