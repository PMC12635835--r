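#' Vietoris-Rips persistence of a finite metric space
#'
#' Computes the persistence diagram of the Vietoris-Rips filtration up to
#' dimension 1 over scales `0 < eps <= R`. Dimension-0 classes are born at 0;
#' classes alive at `R` are reported with `death = Inf` (the sentinel scale
#' is recorded in the diagram's `R` attribute). On a connected metric space
#' exactly one dimension-0 class is infinite.
#'
#' @param D symmetric distance matrix (e.g. a `state_distance`).
#' @param maxdim maximum homology dimension (only 1 is supported).
#' @param R maximum filtration scale; defaults to the largest pairwise
#'   distance (at which scale every 1-cycle has filled in).
#' @param cap refuse inputs with more points than this (the triangle count
#'   grows cubically); subsample first if exceeded.
#' @return An object of class `persistence_diagram`: a data.frame with
#'   columns `dimension`, `birth`, `death` and attribute `R`.
#' @export
rips_persistence <- function(D, maxdim = 1, R = NULL, cap = 2000) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square distance matrix")
  if (maxdim != 1) stop("only maxdim = 1 is supported")
  U <- nrow(D)
  if (U > cap)
    stop(U, " points exceeds the cap (", cap, "); subsample the states first")
  if (is.null(R)) R <- max(D)
  res <- rips_pairs_cpp(D, R)
  df <- rbind(
    data.frame(dimension = 0L,
               birth = rep(0, length(res$h0_death) + res$n_inf_h0),
               death = c(res$h0_death, rep(Inf, res$n_inf_h0))),
    {
      b1 <- c(res$h1_birth, res$h1_inf_birth)
      data.frame(dimension = rep(1L, length(b1)),
                 birth = b1,
                 death = c(res$h1_death,
                           rep(Inf, length(res$h1_inf_birth))))
    }
  )
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("persistence_diagram", "data.frame"), R = R)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat("persistence_diagram: ", sum(x$dimension == 0), " H0 and ",
      sum(x$dimension == 1), " H1 classes (R = ",
      signif(attr(x, "R"), 4), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}

#' Dominant Betti signature of a persistence diagram
#'
#' Per dimension, features are ranked by persistence (`death - birth`, with
#' infinite deaths scored at the filtration ceiling `R`); infinite classes
#' are always dominant. The dominant set is cut at the topmost multiplicative
#' gap: scanning from the most persistent class (at or after the infinite
#' classes), the first position where `persistence[i] / persistence[i+1]`
#' is at least 2. If no ratio reaches 2, the dominant set is every class
#' with persistence above half the maximum (so ties stay together).
#' Cutting at the topmost qualifying gap rather than the globally largest
#' one keeps the rule stable on real diagrams, whose tails contain
#' near-zero persistences with arbitrarily large mutual ratios.
#'
#' @param diagram a `persistence_diagram`.
#' @param rule dominance rule; only `"largest-gap"` is implemented.
#' @return An object of class `betti_signature`: list with counts `h0`,
#'   `h1` and `persistence` (named list of the dominant persistences per
#'   dimension).
#' @export
dominant_signature <- function(diagram, rule = "largest-gap") {
  rule <- match.arg(rule, "largest-gap")
  if (nrow(diagram) == 0) stop("empty persistence diagram")
  R <- attr(diagram, "R")
  pick <- function(dim) {
    feats <- diagram[diagram$dimension == dim, , drop = FALSE]
    if (nrow(feats) == 0) return(numeric(0))
    inf <- !is.finite(feats$death)
    pers <- ifelse(inf, R - feats$birth, feats$death - feats$birth)
    # infinite classes lead the ranking regardless of their scored value
    pers <- c(sort(pers[inf], decreasing = TRUE),
              sort(pers[!inf], decreasing = TRUE))
    n_inf <- sum(inf)
    if (length(pers) == 1) return(pers)
    ratios <- pers[-length(pers)] / pmax(pers[-1], .Machine$double.eps)
    # the cut may not split the infinite classes
    cand <- seq_along(ratios) >= max(1, n_inf)
    if (any(cand & ratios >= 2)) {
      cut <- which(cand & ratios >= 2)[1]
    } else {
      fin_max <- if (length(pers) > n_inf) max(pers[(n_inf + 1):length(pers)])
                 else 0
      cut <- max(n_inf, sum(pers > 0.5 * max(fin_max, .Machine$double.eps)))
      if (cut == 0) cut <- length(pers)  # all persistences equal/zero
    }
    pers[seq_len(cut)]
  }
  p0 <- pick(0L)
  p1 <- pick(1L)
  structure(list(h0 = length(p0), h1 = length(p1),
                 persistence = list(h0 = p0, h1 = p1)),
            class = "betti_signature")
}

#' @export
print.betti_signature <- function(x, ...) {
  cat("betti_signature: (#H0, #H1) = (", x$h0, ", ", x$h1, ")\n", sep = "")
  invisible(x)
}

#' Write a persistence diagram as CSV
#'
#' Columns `dimension`, `birth`, `death`; infinite deaths are written as the
#' literal `inf`.
#'
#' @param diagram a `persistence_diagram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path) {
  df <- as.data.frame(diagram)
  df$death <- vapply(df$death, function(d)
    if (is.finite(d)) sprintf("%.12g", d) else "inf", character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
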