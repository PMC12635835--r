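tiny_states <- function(mats, W = 2, S = 1) {
  structure(list(states = mats,
                 window_starts = seq_along(mats),
                 params = window_params(W, S), tau = 0),
            class = "state_sequence")
}

labelled <- function(M, labels) { dimnames(M) <- list(labels, labels); M }

test_that("connectivity weights average the defining pair sets", {
  labels <- c("s1", "s2", "s3", "f1", "f2", "d1", "d2")
  nm <- stats::setNames(c("salience", "salience", "salience",
                          "frontoparietal", "frontoparietal",
                          "default", "default"), labels)
  M <- matrix(0, 7, 7); diag(M) <- 1
  # within-salience pairs: {0.3, 0.6, 0.9} -> 0.6
  M[1, 2] <- M[2, 1] <- 0.3
  M[1, 3] <- M[3, 1] <- 0.6
  M[2, 3] <- M[3, 2] <- 0.9
  # salience x frontoparietal: all 0.4
  M[1:3, 4:5] <- 0.4; M[4:5, 1:3] <- 0.4
  W <- connectivity_weights(tiny_states(list(labelled(M, labels))), nm)
  expect_equal(unname(W[1, "salience_salience"]), 0.6)
  expect_equal(unname(W[1, "salience_frontoparietal"]), 0.4)
  expect_equal(unname(W[1, "default_default"]), 0)

  zero <- labelled(diag(7), labels)
  Wz <- connectivity_weights(tiny_states(list(zero)), nm)
  expect_equal(unname(Wz[1, ]), rep(0, 6))

  nm_bad <- nm; nm_bad[6:7] <- "salience"
  expect_error(connectivity_weights(tiny_states(list(labelled(M, labels))),
                                    nm_bad), "< 2 regions")
})

test_that("the weight of a network union is a convex combination of the
           pairwise weights", {
  set.seed(6)
  labels <- paste0("r", 1:9)
  nm <- stats::setNames(rep(c("salience", "frontoparietal", "default"),
                            each = 3), labels)
  M <- matrix(0, 9, 9)
  M[upper.tri(M)] <- runif(36)
  M <- M + t(M); diag(M) <- 1
  W <- connectivity_weights(tiny_states(list(labelled(M, labels))), nm)
  # merge salience+frontoparietal into one 6-region block by hand
  idx <- 1:6
  sub <- M[idx, idx]
  union_w <- mean(sub[upper.tri(sub)])
  n1 <- 3; n2 <- 3
  p11 <- choose(n1, 2); p22 <- choose(n2, 2); p12 <- n1 * n2
  total <- p11 + p22 + p12
  expect_equal(union_w,
               unname(p11 * W[1, "salience_salience"] +
                      p22 * W[1, "frontoparietal_frontoparietal"] +
                      p12 * W[1, "salience_frontoparietal"]) / total)
})

test_that("suspense alignment follows the window-mean and center
           conventions", {
  trace <- 1:30
  starts <- c(1, 5, 9)
  expect_equal(align_suspense(trace, starts, W = 4), c(2.5, 6.5, 10.5))
  # a linear ramp's window mean equals its value at the window midpoint
  expect_equal(align_suspense(trace, starts, W = 5),
               trace[starts + 2])
  expect_equal(align_suspense(trace, starts, W = 1), trace[starts])
  expect_equal(align_suspense(rep(4, 30), starts, W = 6), rep(4, 3))
  expect_equal(align_suspense(trace, starts, W = 4, method = "center"),
               trace[starts + 1])
  expect_error(align_suspense(1:5, starts, W = 4), "windows need")
})

test_that("suspense correlations recover exact and planted relationships", {
  set.seed(2)
  U <- 60
  s <- cumsum(rnorm(U))
  W6 <- cbind(s, -s + 3, s * 2 + 1, rnorm(U), rep(1, U), -s)
  colnames(W6) <- c("salience_salience", "frontoparietal_frontoparietal",
                    "salience_frontoparietal", "default_default",
                    "salience_default", "frontoparietal_default")
  expect_warning(rho <- suspense_correlations(W6, s, start_state = 1),
                 "constant")
  expect_equal(unname(rho["salience_salience"]), 1)
  expect_equal(unname(rho["frontoparietal_frontoparietal"]), -1)
  expect_equal(unname(rho["salience_frontoparietal"]), 1)
  expect_true(is.na(rho["salience_default"]))
  expect_equal(unname(rho["frontoparietal_default"]), -1)
  # affine rescaling of the rating leaves correlations unchanged
  rho2 <- suppressWarnings(suspense_correlations(W6, 2.5 * s + 7,
                                                 start_state = 1))
  expect_equal(rho2, rho)
  # the start parameter restricts the span
  expect_equal(unname(suppressWarnings(
    suspense_correlations(W6, s, start_state = 30))["salience_salience"]), 1)
  expect_error(suspense_correlations(W6, s, start_state = 61,
                                     end_state = 60), "start_state")
})

test_that("change points recover noise-free piecewise-linear breaks", {
  y2 <- c(0.2 * (1:50), 10 - 0.5 * (1:25))
  # slope changes between samples 50 and 51; the kink sample lies on both
  # lines so either boundary is a zero-cost optimum
  cp <- detect_changepoints(y2)
  expect_length(cp, 1)
  expect_true(as.integer(cp) %in% c(50L, 51L))

  line <- 0.3 * (1:80) + 2
  expect_length(detect_changepoints(line), 0)

  y3 <- c(seq(1, 20, length.out = 30), rep(20, 25),
          seq(20, -15, length.out = 30))
  cp3 <- as.integer(detect_changepoints(y3))
  expect_length(cp3, 2)
  expect_true(all(abs(cp3 - c(31, 56)) <= 1))
})

test_that("the pruned detector equals the exhaustive dynamic program", {
  set.seed(12)
  for (r in 1:4) {
    n <- sample(40:60, 1)
    y <- c(seq(0, 5, length.out = floor(n / 2)),
           seq(5, -2, length.out = ceiling(n / 2))) + rnorm(n, sd = 0.25)
    got <- detect_changepoints(y)
    beta <- attr(got, "penalty")
    want <- oracle_changepoints(y, beta)
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("change-point / transition-state overlap counts within
           tolerance", {
  tax <- structure(list(transition_states = c(11L, 40L)),
                   class = "node_taxonomy")
  expect_equal(changepoint_transition_overlap(c(10L, 40L), tax), 2L)
  expect_equal(changepoint_transition_overlap(c(10L, 40L), tax,
                                              tolerance = 0), 1L)
  expect_equal(changepoint_transition_overlap(c(20L, 30L), tax), 0L)
  expect_equal(changepoint_transition_overlap(integer(0), tax), 0L)
  expect_equal(changepoint_transition_overlap(c(11L, 40L), c(11L, 40L)), 2L)
})
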