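#' Distance-based regression of dissimilarity on body-weight difference
#'
#' Ordinary least squares of all pairwise community dissimilarities on the
#' corresponding absolute body-weight differences, with a permutation
#' F-test: each permutation shuffles the body-weight vector across samples
#' and recomputes the |weight difference| covariate, preserving the
#' dependence structure of the pairwise response (pairs are never permuted
#' independently).
#'
#' @param d distance matrix over samples.
#' @param weights body weight (g) per sample, aligned with \code{d} (or
#'   named by its sample ids).
#' @param permutations number of weight permutations (default 1000).
#' @param seed integer seed.
#' @return list: slope (dissimilarity per gram), intercept, F_observed,
#'   permutations, p_value, n_pairs.
#' @export
distanceRegression <- function(d, weights, permutations = 1000, seed = 1L) {
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  if (n < 4) stop("need at least 4 samples")
  if (!is.null(names(weights)) && !is.null(rownames(d))) {
    if (!all(rownames(d) %in% names(weights)))
      stop("weights missing for some samples in d")
    weights <- weights[rownames(d)]
  }
  if (length(weights) != n || anyNA(weights))
    stop("every sample in d needs a body weight")
  if (stats::sd(weights) == 0) stop("degenerate covariate: all weights equal")

  lower <- lower.tri(d)
  y <- d[lower]
  nPairs <- length(y)

  fitF <- function(w) {
    x <- as.matrix(stats::dist(w))[lower]
    vx <- sum((x - mean(x))^2)
    if (vx == 0) return(c(0, mean(y), 0))
    b <- sum((x - mean(x)) * (y - mean(y))) / vx
    a <- mean(y) - b * mean(x)
    ssReg <- b^2 * vx
    ssRes <- sum((y - a - b * x)^2)
    f <- if (ssReg == 0) 0
         else if (ssRes <= 0) Inf
         else (ssReg / 1) / (ssRes / (nPairs - 2))
    c(b, a, f)
  }
  obs <- fitF(weights)
  fPerm <- withSeed(seed, vapply(seq_len(permutations), function(i)
    fitF(sample(weights))[3], numeric(1)))
  p <- (sum(fPerm >= obs[3]) + 1) / (permutations + 1)
  list(slope = obs[1], intercept = obs[2], F_observed = obs[3],
       permutations = permutations, p_value = p, n_pairs = nPairs)
}

#' Per-habitat and pooled distance regressions
#'
#' Fits \code{\link{distanceRegression}} within each habitat (subsetting
#' the distance matrix to that habitat's samples) and pooled over all
#' weighted (non-water) samples. Habitats with fewer than 4 samples are
#' skipped with a warning.
#'
#' @param x a MetacomExperiment.
#' @param d optional precomputed distance matrix (defaults to Bray-Curtis
#'   on the counts in \code{x}).
#' @param permutations,seed passed to \code{\link{distanceRegression}}.
#' @return named list of regression results (one per habitat plus
#'   \code{"all"}).
#' @export
distanceRegressionByHabitat <- function(x, d = NULL, permutations = 1000,
                                        seed = 1L) {
  stopifnot(is(x, "MetacomExperiment"))
  if (is.null(d)) d <- brayCurtis(x)
  d <- .checkDistanceMatrix(d)
  w <- bodyWeights(x)
  hab <- habitats(x)
  out <- list()
  for (h in setdiff(unique(hab), "water")) {
    ids <- names(w)[hab == h & !is.na(w)]
    if (length(ids) < 4) {
      warning("habitat ", h, " has < 4 weighted samples; skipped")
      next
    }
    out[[h]] <- distanceRegression(d[ids, ids], w[ids], permutations,
                                   deriveSeed(seed, paste0("wreg_", h)))
  }
  ids <- names(w)[!is.na(w)]
  if (length(ids) >= 4)
    out[["all"]] <- distanceRegression(d[ids, ids], w[ids], permutations,
                                       deriveSeed(seed, "wreg_all"))
  out
}
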