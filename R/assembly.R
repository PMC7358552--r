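#' Ecological process labels
#' @export
PROCESSES <- c("heterogeneous_selection", "homogeneous_selection",
               "homogenizing_dispersal", "dispersal_limitation",
               "undominated")

.pairSparse <- function(counts, tips) {
  if (is.null(names(counts)))
    stop("sample counts must be named by OTU id")
  nz <- counts[counts > 0]
  idx <- match(names(nz), tips)
  if (anyNA(idx))
    stop("OTU absent from tree: ", names(nz)[which(is.na(idx))[1]])
  list(idx = as.integer(idx), f = as.numeric(nz / sum(nz)))
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' \eqn{\beta MNTD = \frac{1}{2}[\sum_i f_i^x \min_{j \in y} d_{ij} +
#' \sum_j f_j^y \min_{i \in x} d_{ji}]} where f are relative abundances
#' over each community's nonzero taxa and d the cophenetic distance. Taxa
#' shared by both communities contribute zero (their nearest neighbour in
#' the other community is themselves).
#'
#' @param x,y named count vectors (names = OTU ids present as tree tips).
#' @param tree rooted \code{phylo} with branch lengths.
#' @param D optional precomputed cophenetic matrix (tips as dimnames).
#' @return non-negative real; 0 when x and y share all their taxa.
#' @export
bmntd <- function(x, y, tree, D = NULL) {
  if (is.null(D)) D <- stats::cophenetic(tree)
  sx <- .pairSparse(x, rownames(D))
  sy <- .pairSparse(y, rownames(D))
  cpp_bmntd(D, sx$idx - 1L, sx$f, sy$idx - 1L, sy$f)
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of observed \code{\link{bmntd}} against a null
#' distribution obtained by shuffling tip labels uniformly across all tips
#' of the tree (regional-pool randomization):
#' \eqn{\beta NTI = (\beta MNTD_{obs} - \mu_{null}) / \sigma_{null}}.
#' \eqn{|\beta NTI| > 2} flags selection (heterogeneous above +2,
#' homogeneous below -2).
#'
#' @inheritParams bmntd
#' @param nNull number of null randomizations (>= 99; default 999).
#' @param seed integer seed.
#' @return list: bnti, bmntd_obs, null_mean, null_sd. If the null has zero
#'   spread (e.g. a star tree) bnti is 0 with a warning.
#' @export
bnti <- function(x, y, tree, nNull = 999, seed = 1L, D = NULL) {
  if (nNull < 99) stop("nNull must be >= 99")
  if (is.null(D)) D <- stats::cophenetic(tree)
  sx <- .pairSparse(x, rownames(D))
  sy <- .pairSparse(y, rownames(D))
  obs <- cpp_bmntd(D, sx$idx - 1L, sx$f, sy$idx - 1L, sy$f)
  nulls <- withSeed(seed,
    cpp_bmntd_null(D, sx$idx - 1L, sx$f, sy$idx - 1L, sy$f, nNull))
  m <- mean(nulls)
  s <- stats::sd(nulls)
  if (s == 0) {
    warning("null betaMNTD distribution has zero spread; betaNTI set to 0")
    b <- 0
  } else {
    b <- (obs - m) / s
  }
  list(bnti = b, bmntd_obs = obs, null_mean = m, null_sd = s)
}

#' Raup-Crick metric on Bray-Curtis (RC_Bray)
#'
#' Positions the observed Bray-Curtis dissimilarity of a sample pair
#' within a null distribution of pairs assembled probabilistically from
#' the metacommunity: each null community preserves its sample's observed
#' richness and total count, drawing taxa without replacement with
#' probability proportional to occupancy frequency across all samples and
#' allocating reads multinomially proportional to metacommunity-wide
#' relative abundances. \eqn{RC = 2 (n_{below} + n_{ties}/2)/n_{null} - 1
#' \in [-1, 1]} (tie tolerance 1e-10).
#'
#' @param x,y named count vectors for the two samples.
#' @param table the metacommunity context: MetacomExperiment or
#'   samples-x-OTUs count matrix providing occupancy and abundance.
#' @param nNull number of null pairs (>= 99; default 999).
#' @param seed integer seed.
#' @return RC_Bray in [-1, 1].
#' @export
rcBray <- function(x, y, table, nNull = 999, seed = 1L) {
  if (nNull < 99) stop("nNull must be >= 99")
  m <- .asSampleMatrix(table)
  occ <- colSums(m > 0)
  relab <- colSums(m) / sum(m)
  ids <- colnames(m)
  xx <- yy <- numeric(length(ids))
  names(xx) <- names(yy) <- ids
  if (is.null(names(x)) || is.null(names(y)))
    stop("sample counts must be named by OTU id")
  xx[names(x)] <- x
  yy[names(y)] <- y
  rx <- sum(xx > 0); ry <- sum(yy > 0)
  pool <- sum(occ > 0)
  if (rx > pool || ry > pool)
    stop("sample richness exceeds the occupied pool size")
  if (rx == 0 || ry == 0) stop("empty sample")
  obs <- sum(abs(xx - yy)) / sum(xx + yy)
  nulls <- withSeed(seed,
    cpp_rc_null_bc(occ, relab, rx, sum(xx), ry, sum(yy), nNull))
  below <- sum(nulls < obs - 1e-10)
  ties <- sum(abs(nulls - obs) <= 1e-10)
  2 * ((below + 0.5 * ties) / nNull) - 1
}

#' Classify the assembly process of a sample pair
#'
#' Deterministic map from (betaNTI, RC_Bray): betaNTI > +2 heterogeneous
#' selection; betaNTI < -2 homogeneous selection; otherwise RC < -0.95
#' homogenizing dispersal, RC > 0.95 dispersal limitation, |RC| <= 0.95
#' undominated. Boundary ties go to the non-selection / undominated side.
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RC_Bray values in [-1, 1].
#' @return character vector over \code{\link{PROCESSES}}.
#' @examples
#' classifyProcess(c(2.5, 0, 0), c(0, -0.97, 0))
#' @export
classifyProcess <- function(bnti, rc) {
  stopifnot(length(bnti) == length(rc))
  if (any(rc < -1 - 1e-9 | rc > 1 + 1e-9)) stop("rc must be in [-1, 1]")
  ifelse(bnti > 2, "heterogeneous_selection",
    ifelse(bnti < -2, "homogeneous_selection",
      ifelse(rc < -0.95, "homogenizing_dispersal",
        ifelse(rc > 0.95, "dispersal_limitation", "undominated"))))
}

#' Pairwise turnover table (betaMNTD, betaNTI, RC_Bray, process)
#'
#' Computes the full null-model workup for a set of sample pairs. The
#' cophenetic matrix and metacommunity occupancy/abundance context are
#' computed once from \code{x}.
#'
#' @param x MetacomExperiment with a tree.
#' @param pairs optional 2-column matrix of sample ids; default all pairs.
#' @param nNull null randomizations per pair for both betaNTI and RC_Bray.
#' @param seed integer seed.
#' @return data.frame: sample_a, sample_b, group (habitat if shared, else
#'   "between"), bmntd_obs, bnti, rc_bray, process.
#' @export
pairwiseTurnover <- function(x, pairs = NULL, nNull = 999, seed = 1L) {
  stopifnot(is(x, "MetacomExperiment"))
  tree <- phyloTree(x)
  if (is.null(tree)) stop("missing input: phylogenetic tree")
  m <- sampleCounts(x)
  miss <- setdiff(colnames(m)[colSums(m) > 0], tree$tip.label)
  if (length(miss) > 0)
    stop("OTU absent from tree: ", miss[1])
  D <- stats::cophenetic(tree)
  hab <- habitats(x)
  if (is.null(pairs)) {
    ids <- rownames(m)
    pairs <- t(utils::combn(ids, 2))
  }
  occ <- colSums(m > 0)
  relab <- colSums(m) / sum(m)
  sparse <- lapply(rownames(m), function(s) .pairSparse(m[s, ], rownames(D)))
  names(sparse) <- rownames(m)
  richness <- rowSums(m > 0)
  totals <- rowSums(m)

  withSeed(seed, {
    res <- lapply(seq_len(nrow(pairs)), function(k) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      sa <- sparse[[a]]; sb <- sparse[[b]]
      obs <- cpp_bmntd(D, sa$idx - 1L, sa$f, sb$idx - 1L, sb$f)
      nulls <- cpp_bmntd_null(D, sa$idx - 1L, sa$f, sb$idx - 1L, sb$f, nNull)
      s <- stats::sd(nulls)
      bn <- if (s == 0) 0 else (obs - mean(nulls)) / s
      obsBC <- sum(abs(m[a, ] - m[b, ])) / sum(m[a, ] + m[b, ])
      nullBC <- cpp_rc_null_bc(occ, relab, richness[a], totals[a],
                               richness[b], totals[b], nNull)
      rc <- 2 * ((sum(nullBC < obsBC - 1e-10) +
                  0.5 * sum(abs(nullBC - obsBC) <= 1e-10)) / nNull) - 1
      data.frame(sample_a = a, sample_b = b,
                 group = if (hab[a] == hab[b]) hab[[a]] else "between",
                 bmntd_obs = obs, bnti = bn, rc_bray = rc,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$process <- classifyProcess(out$bnti, out$rc_bray)
    out
  })
}

#' Per-group ecological process profiles
#'
#' Classifies every within-group sample pair (and, optionally, the pooled
#' across-habitat pairs) and reports the fraction of pairs assigned to
#' each of the five assembly processes. Fractions are computed from exact
#' pair counts and sum to 1.
#'
#' @param x MetacomExperiment with a tree.
#' @param nNull null randomizations per pair.
#' @param seed integer seed.
#' @param includeBetween also profile the across-habitat pair set (group
#'   \code{"between"}).
#' @param turnover optional precomputed \code{\link{pairwiseTurnover}}
#'   table to aggregate instead of recomputing.
#' @return data.frame: group, n_pairs, one column per process (fractions).
#' @export
assemblyProfile <- function(x, nNull = 999, seed = 1L,
                            includeBetween = FALSE, turnover = NULL) {
  stopifnot(is(x, "MetacomExperiment"))
  hab <- habitats(x)
  if (is.null(turnover)) {
    ids <- colnames(x)
    keepPair <- function(a, b) hab[a] == hab[b] || includeBetween
    allPairs <- t(utils::combn(ids, 2))
    use <- vapply(seq_len(nrow(allPairs)), function(k)
      keepPair(allPairs[k, 1], allPairs[k, 2]), logical(1))
    small <- names(which(table(hab) < 2))
    if (length(small) > 0)
      warning("group(s) with < 2 samples skipped: ",
              paste(small, collapse = ", "))
    if (!any(use)) stop("no eligible sample pairs")
    turnover <- pairwiseTurnover(x, allPairs[use, , drop = FALSE],
                                 nNull, seed)
  }
  groups <- unique(turnover$group)
  rows <- lapply(groups, function(g) {
    sub <- turnover[turnover$group == g, ]
    counts <- table(factor(sub$process, levels = PROCESSES))
    frac <- as.numeric(counts) / nrow(sub)
    df <- data.frame(group = g, n_pairs = nrow(sub))
    df[PROCESSES] <- as.list(frac)
    df
  })
  do.call(rbind, rows)
}
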