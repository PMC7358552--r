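#' Chao1 richness estimator (bias-corrected)
#'
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1} the number
#' of singletons and \eqn{F_2} the number of doubletons; the +1 correction
#' keeps the estimator defined when no doubletons are observed.
#'
#' @param counts non-negative integer vector of OTU counts for one sample.
#' @return estimated richness (>= observed richness).
#' @examples
#' chao1(c(5, 3, 1, 1, 2))  # 5.5
#' @export
chao1 <- function(counts) {
  if (anyNA(counts) || any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) {
    warning("empty sample: Chao1 = 0")
    return(0)
  }
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity table
#'
#' @param x MetacomExperiment or samples-x-OTUs matrix.
#' @return data.frame with sample_id, chao1 and observed richness.
#' @export
alphaDiversity <- function(x) {
  m <- .asSampleMatrix(x)
  data.frame(sample_id = rownames(m),
             chao1 = apply(m, 1, chao1),
             observed = rowSums(m > 0),
             row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} on counts.
#' A pair of all-zero samples is assigned distance 0 with a warning.
#'
#' @param x MetacomExperiment or samples-x-OTUs count matrix (>= 2 samples).
#' @return symmetric hollow matrix with sample ids as dimnames.
#' @export
setGeneric("brayCurtis", function(x) standardGeneric("brayCurtis"))

.brayCurtisMatrix <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 samples")
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (anyNA(d)) {
    warning("pair(s) of all-zero samples: distance set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' @rdname brayCurtis
setMethod("brayCurtis", "matrix", function(x) .brayCurtisMatrix(x))

#' @rdname brayCurtis
setMethod("brayCurtis", "MetacomExperiment",
          function(x) .brayCurtisMatrix(sampleCounts(x)))

#' Principal coordinate analysis
#'
#' Gower double-centering and eigendecomposition of a distance matrix.
#' Axes with eigenvalue > 1e-10 are retained; the proportion of variance
#' explained uses the sum of positive eigenvalues as denominator.
#'
#' @param d symmetric hollow distance matrix.
#' @return list with \code{axes} (samples x retained axes),
#'   \code{eigenvalues} (descending) and \code{proportion_explained}.
#' @export
pcoaOrdination <- function(d) {
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > 1e-10]
  keep <- seq_along(pos)
  axes <- fit$points[, keep, drop = FALSE]
  colnames(axes) <- paste0("PCo", keep)
  rownames(axes) <- rownames(d)
  list(axes = axes,
       eigenvalues = pos,
       proportion_explained = pos / sum(eig[eig > 0]))
}

.checkGroups <- function(d, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("groups length must match samples")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs >= 2 members")
  groups
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA (pseudo-F from among/within sums of
#' squared distances, p by label permutation with +1 smoothing), via
#' \code{vegan::adonis2}.
#'
#' @param d distance matrix; \code{groups} factor of group labels.
#' @param groups group labels, one per sample.
#' @param permutations number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @return list: statistic_name, statistic (pseudo-F), R2, permutations,
#'   p_value.
#' @export
permanovaTest <- function(d, groups, permutations = 999, seed = 1L) {
  d <- .checkDistanceMatrix(d)
  groups <- .checkGroups(d, groups)
  df <- data.frame(groups = groups)
  fit <- withSeed(seed,
    vegan::adonis2(stats::as.dist(d) ~ groups, data = df,
                   permutations = permutations))
  list(statistic_name = "pseudo_F",
       statistic = fit$F[1],
       R2 = fit$R2[1],
       permutations = permutations,
       p_value = fit$`Pr(>F)`[1])
}

#' ANOSIM on a distance matrix
#'
#' Rank-based analysis of similarities (statistic R in [-1, 1]), via
#' \code{vegan::anosim}.
#'
#' @inheritParams permanovaTest
#' @return list: statistic_name ("anosim_R"), statistic, permutations,
#'   p_value.
#' @export
anosimTest <- function(d, groups, permutations = 999, seed = 1L) {
  d <- .checkDistanceMatrix(d)
  groups <- .checkGroups(d, groups)
  fit <- withSeed(seed,
    vegan::anosim(stats::as.dist(d), groups, permutations = permutations))
  list(statistic_name = "anosim_R",
       statistic = unname(fit$statistic),
       permutations = permutations,
       p_value = fit$signif)
}

#' Mantel and partial Mantel tests
#'
#' Pearson correlation of the upper-triangle entries of two distance
#' matrices, with significance by simultaneous row/column permutation of
#' \code{d1}. With a third matrix, the partial statistic is the correlation
#' of the residuals of \code{d1} and \code{d2} after regressing both on the
#' third matrix; if either residual vector is (numerically) constant the
#' partial correlation is reported as 0 with a warning.
#'
#' @param d1,d2 distance matrices with matching sample ids.
#' @param permutations number of permutations (default 10000).
#' @param partial optional third distance matrix to control for.
#' @param seed integer seed.
#' @return list: statistic_name, statistic (r), permutations, p_value.
#' @export
mantelTest <- function(d1, d2, permutations = 10000, partial = NULL,
                       seed = 1L) {
  d1 <- .checkDistanceMatrix(d1, "d1")
  d2 <- .checkDistanceMatrix(d2, "d2")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("sample id mismatch between d1 and d2")
    d2 <- d2[rownames(d1), rownames(d1)]
  } else if (nrow(d1) != nrow(d2)) {
    stop("sample id mismatch between d1 and d2")
  }
  if (is.null(partial)) {
    fit <- withSeed(seed,
      vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                    permutations = permutations))
    return(list(statistic_name = "mantel_r",
                statistic = unname(fit$statistic),
                permutations = permutations, p_value = fit$signif))
  }
  d3 <- .checkDistanceMatrix(partial, "partial")
  if (!is.null(rownames(d3)) && !is.null(rownames(d1))) {
    if (!setequal(rownames(d1), rownames(d3)))
      stop("sample id mismatch between d1 and partial")
    d3 <- d3[rownames(d1), rownames(d1)]
  }
  lower <- lower.tri(d1)
  z <- d3[lower]
  partialR <- function(y1, y2) {
    r1 <- stats::lsfit(z, y1)$residuals
    r2 <- stats::lsfit(z, y2)$residuals
    if (stats::sd(r1) < 1e-12 || stats::sd(r2) < 1e-12) return(NA_real_)
    stats::cor(r1, r2)
  }
  rObs <- partialR(d1[lower], d2[lower])
  if (is.na(rObs)) {
    warning("degenerate residuals in partial Mantel; statistic reported as 0")
    return(list(statistic_name = "partial_mantel_r", statistic = 0,
                permutations = permutations, p_value = NA_real_))
  }
  n <- nrow(d1)
  rPerm <- withSeed(seed, vapply(seq_len(permutations), function(i) {
    idx <- sample.int(n)
    dp <- d1[idx, idx]
    r <- partialR(dp[lower], d2[lower])
    if (is.na(r)) -Inf else r
  }, numeric(1)))
  p <- (sum(rPerm >= rObs) + 1) / (permutations + 1)
  list(statistic_name = "partial_mantel_r", statistic = rObs,
       permutations = permutations, p_value = p)
}

#' Spearman correlation of feature abundances with body weight
#'
#' Per-OTU Spearman correlation of relative abundance against body weight,
#' with Benjamini-Hochberg adjusted q-values. Constant features are
#' reported with NA correlation.
#'
#' @param x MetacomExperiment (water samples, which lack weights, are
#'   excluded) or samples-x-OTUs matrix with \code{weights} supplied.
#' @param weights body weights (required when \code{x} is a matrix).
#' @return data.frame: otu_id, rho, p_value, q_value.
#' @export
featureWeightCorrelation <- function(x, weights = NULL) {
  if (is(x, "MetacomExperiment")) {
    w <- bodyWeights(x)
    keep <- !is.na(w)
    m <- sampleCounts(x)[keep, , drop = FALSE]
    w <- w[keep]
  } else {
    m <- as.matrix(x)
    w <- weights
    if (is.null(w)) stop("weights required for matrix input")
    if (anyNA(w)) stop("all samples must have body weight")
  }
  if (nrow(m) < 3) stop("need at least 3 weighted samples")
  rel <- .relAbundance(m)
  res <- apply(rel, 2, function(v) {
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(v, w, method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  out <- data.frame(otu_id = colnames(rel),
                    rho = res[1, ], p_value = res[2, ], row.names = NULL)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
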