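#' Rao quadratic entropy
#'
#' \eqn{Q = \sum_i \sum_j d_{ij} p_i p_j}: the expected dissimilarity
#' between two randomly drawn individuals. With the taxonomic distance
#' (\eqn{d_{ij} = 1} for \eqn{i \ne j}) Q reduces to the Gini-Simpson
#' index \eqn{1 - \sum_i p_i^2}.
#'
#' @param p relative-abundance vector summing to 1 (within 1e-8).
#' @param d pairwise taxon dissimilarity matrix in [0, 1], or NULL for the
#'   taxonomic distance.
#' @return Q >= 0.
#' @examples
#' raoEntropy(rep(0.25, 4))  # 0.75
#' @export
raoEntropy <- function(p, d = NULL) {
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  if (any(p < 0)) stop("p must be non-negative")
  if (is.null(d)) return(1 - sum(p^2))
  d <- .checkDistanceMatrix(d)
  if (nrow(d) != length(p)) stop("dim mismatch between p and d")
  drop(p %*% d %*% p)
}

# Q evaluated on many profiles (rows); fast path for taxonomic distance
.raoMany <- function(P, d = NULL) {
  if (is.null(d)) return(1 - rowSums(P^2))
  apply(P, 1, function(p) drop(p %*% d %*% p))
}

#' Hierarchical additive Rao diversity partition
#'
#' Decomposes total metacommunity diversity into
#' \deqn{\gamma_{Ecosystem} = \beta_{Inter-Habitats} +
#'   \bar\beta_{Intra-Habitats} + \bar\alpha_{Local-Community}.}
#' Local alpha is the Rao Q of each sample; habitat gamma is the Q of the
#' unweighted mean of the habitat's sample profiles; ecosystem gamma is the
#' Q of the unweighted mean of habitat profiles (each sample equal within
#' habitat, each habitat equal within ecosystem). Beta terms are the
#' differences between successive levels. With
#' \code{correction = "equivalent_numbers"} every level-mean Q is first
#' transformed to Jost equivalent numbers \eqn{1/(1-Q)} and the differences
#' are taken on that scale, which preserves the additive identity exactly
#' and guarantees non-negative beta components.
#'
#' @param x MetacomExperiment, or samples-x-OTUs matrix with
#'   \code{groups} supplied.
#' @param groups habitat label per sample (matrix input only).
#' @param distanceMode "taxonomic" (d = 1 off-diagonal) or "phylogenetic"
#'   (cophenetic distances scaled into [0,1] by their maximum).
#' @param correction "equivalent_numbers" (default) or "none".
#' @param tree phylogeny (matrix input with phylogenetic mode).
#' @return list: gamma_ecosystem, beta_inter_habitats, beta_intra_mean,
#'   alpha_local_mean, per_habitat (gamma_habitat, beta_intra,
#'   alpha_local_mean, beta_intra_percent), percents (alpha, beta_intra,
#'   beta_inter; sum to 100), correction, distance_mode.
#' @export
setGeneric("partitionDiversity",
  function(x, groups = NULL, distanceMode = c("taxonomic", "phylogenetic"),
           correction = c("equivalent_numbers", "none"), tree = NULL)
    standardGeneric("partitionDiversity"))

.partitionDiversity <- function(m, groups, distanceMode, correction, tree) {
  distanceMode <- match.arg(distanceMode, c("taxonomic", "phylogenetic"))
  correction <- match.arg(correction, c("equivalent_numbers", "none"))
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("groups length must match samples")
  habs <- unique(groups)
  if (length(habs) < 2) stop("need at least 2 habitats")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    zeroHabs <- unique(groups[tot == 0])
    stop("habitat with zero-total sample(s): ",
         paste(zeroHabs, collapse = ", "))
  }
  d <- NULL
  if (distanceMode == "phylogenetic") {
    if (is.null(tree)) stop("phylogenetic mode requires a tree")
    miss <- setdiff(colnames(m), tree$tip.label)
    if (length(miss) > 0)
      stop("OTU(s) missing from tree: ", paste(utils::head(miss, 3),
                                               collapse = ", "))
    d <- stats::cophenetic(tree)[colnames(m), colnames(m)]
    mx <- max(d)
    if (mx > 0) d <- d / mx
  }
  rel <- .relAbundance(m)
  alpha <- .raoMany(rel, d)                       # per-sample Q
  habProfiles <- t(vapply(habs, function(h)
    colMeans(rel[groups == h, , drop = FALSE]), numeric(ncol(rel))))
  gammaHab <- .raoMany(habProfiles, d)            # per-habitat Q
  alphaHab <- vapply(habs, function(h) mean(alpha[groups == h]), numeric(1))
  ecoProfile <- colMeans(habProfiles)
  gammaEco <- raoEntropy(ecoProfile, d)

  eq <- function(q) if (correction == "equivalent_numbers") 1 / (1 - q) else q
  a1 <- eq(alphaHab)        # within-habitat mean alpha, corrected scale
  a2 <- eq(gammaHab)
  a3 <- eq(gammaEco)
  betaIntra <- a2 - a1
  betaInter <- a3 - mean(a2)
  alphaMean <- mean(a1)
  perHab <- data.frame(habitat = habs,
                       gamma_habitat = a2,
                       beta_intra = betaIntra,
                       alpha_local_mean = a1,
                       beta_intra_percent = betaIntra / a3 * 100,
                       row.names = NULL)
  list(gamma_ecosystem = a3,
       beta_inter_habitats = betaInter,
       beta_intra_mean = mean(betaIntra),
       alpha_local_mean = alphaMean,
       per_habitat = perHab,
       percents = c(alpha = alphaMean / a3 * 100,
                    beta_intra = mean(betaIntra) / a3 * 100,
                    beta_inter = betaInter / a3 * 100),
       correction = correction,
       distance_mode = distanceMode)
}

#' @rdname partitionDiversity
setMethod("partitionDiversity", "matrix",
  function(x, groups, distanceMode, correction, tree) {
    if (is.null(groups)) stop("groups required for matrix input")
    .partitionDiversity(x, groups, distanceMode, correction, tree)
  })

#' @rdname partitionDiversity
setMethod("partitionDiversity", "MetacomExperiment",
  function(x, groups, distanceMode, correction, tree) {
    distanceMode <- match.arg(distanceMode, c("taxonomic", "phylogenetic"))
    if (is.null(tree)) tree <- phyloTree(x)
    .partitionDiversity(sampleCounts(x), habitats(x), distanceMode,
                        correction, tree)
  })
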