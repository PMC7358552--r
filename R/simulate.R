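#' Parameters for the synthetic metacommunity generator
#'
#' Builds and validates the parameter set controlling
#' \code{\link{simulateMetacommunity}}. Defaults emulate a field survey of
#' ~100 fish across four body habitats plus surrounding water.
#'
#' @param n_habitats number of habitats (2..5; labels are taken from
#'   \code{\link{HABITATS}} in order, so water is included only at 5).
#'   A single habitat is allowed for single-habitat calibration runs.
#' @param fish_per_habitat individuals sampled per habitat.
#' @param pool_size regional OTU pool size.
#' @param selection_strength strength of phylogenetically conserved habitat
#'   filtering (>= 0; 0 disables selection).
#' @param dispersal_rate fraction in [0,1] of each community drawn from the
#'   flat regional pool rather than the habitat-filtered pool.
#' @param weight_slope target increase in expected within-habitat
#'   Bray-Curtis dissimilarity per gram of body-weight difference (>= 0).
#' @param weight_range_g length-2 numeric, min and max body weight (g).
#' @param reads_per_sample sequencing depth per sample.
#' @param seed integer master seed.
#' @return a validated list of class \code{"SimulationParams"}.
#' @export
simulationParams <- function(n_habitats = 5L, fish_per_habitat = 20L,
                             pool_size = 300L, selection_strength = 10,
                             dispersal_rate = 0.1, weight_slope = 0.002,
                             weight_range_g = c(20, 200),
                             reads_per_sample = 5000L, seed = 1L) {
  stopifnot(length(n_habitats) == 1, length(weight_range_g) == 2)
  if (n_habitats < 1 || n_habitats > length(HABITATS))
    stop("n_habitats must be between 1 and ", length(HABITATS))
  if (fish_per_habitat < 1) stop("fish_per_habitat must be >= 1")
  if (pool_size < 2) stop("pool_size must be >= 2")
  if (selection_strength < 0) stop("selection_strength must be >= 0")
  if (dispersal_rate < 0 || dispersal_rate > 1)
    stop("dispersal_rate must be in [0, 1]")
  if (weight_slope < 0) stop("weight_slope must be >= 0")
  if (weight_range_g[1] <= 0 || weight_range_g[2] < weight_range_g[1])
    stop("weight_range_g must be positive and increasing")
  if (weight_slope * diff(weight_range_g) >= 1)
    stop("weight_slope x weight range must be < 1 to keep dissimilarities in [0,1]")
  if (reads_per_sample < 1) stop("reads_per_sample must be >= 1")
  p <- list(n_habitats = as.integer(n_habitats),
            fish_per_habitat = as.integer(fish_per_habitat),
            pool_size = as.integer(pool_size),
            selection_strength = selection_strength,
            dispersal_rate = dispersal_rate,
            weight_slope = weight_slope,
            weight_range_g = as.numeric(weight_range_g),
            reads_per_sample = as.integer(reads_per_sample),
            seed = as.integer(seed))
  class(p) <- "SimulationParams"
  p
}

#' Simulate a random ultrametric phylogeny over the OTU pool
#'
#' Coalescent-style rooted ultrametric tree with tips
#' \code{OTU_1..OTU_n}, all branch lengths positive.
#'
#' @param poolSize number of tips (>= 2).
#' @param seed integer seed.
#' @return a \code{phylo}.
#' @export
simulatePhylogeny <- function(poolSize, seed = 1L) {
  poolSize <- as.integer(poolSize)
  if (is.na(poolSize) || poolSize < 2) stop("poolSize must be >= 2")
  withSeed(seed,
    ape::rcoal(poolSize, tip.label = paste0("OTU_", seq_len(poolSize))))
}

#' Simulate a habitat-structured metacommunity
#'
#' Generative mechanism: (i) a continuous trait evolves along the phylogeny
#' by a Brownian walk, so habitat filtering is phylogenetically conserved;
#' (ii) each habitat has a trait optimum (spread across the trait
#' distribution) and an OTU's habitat pool weight is its regional abundance
#' times \code{exp(-selection_strength * z^2)} with \code{z} the
#' trait-to-optimum distance in trait SD units; (iii) each fish community is
#' a multinomial draw of \code{reads_per_sample} reads from the mixture
#' \code{(1 - dispersal_rate) * habitat pool + dispersal_rate * flat pool};
#' (iv) each fish receives a uniform body weight and a per-OTU log-linear
#' abundance tilt along the weight axis, calibrated so expected
#' within-habitat Bray-Curtis dissimilarity gains about \code{weight_slope}
#' per gram of weight difference. Water samples carry no weight.
#'
#' @param params a \code{\link{simulationParams}} object.
#' @param tree optional \code{phylo} over the pool; simulated if NULL.
#' @return list with elements \code{experiment}
#'   (\linkS4class{MetacomExperiment} incl. tree) and \code{truth}
#'   (habitat optima, per-fish weights, generative regime tag, parameters).
#' @export
simulateMetacommunity <- function(params, tree = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  S <- params$pool_size
  if (is.null(tree))
    tree <- simulatePhylogeny(S, deriveSeed(params$seed, "phylogeny"))
  if (length(tree$tip.label) != S)
    stop("tree must have exactly pool_size tips")
  H <- params$n_habitats
  habs <- utils::head(HABITATS, H)
  nf <- params$fish_per_habitat

  res <- withSeed(deriveSeed(params$seed, "metacommunity"), {
    traits <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    traits <- traits[tree$tip.label]
    tsd <- stats::sd(traits)
    if (!is.finite(tsd) || tsd == 0) tsd <- 1
    base <- exp(stats::rnorm(S, 0, 1))
    base <- base / sum(base)
    optima <- stats::quantile(traits, probs = (2 * seq_len(H) - 1) / (2 * H),
                              names = FALSE)
    habPool <- vapply(optima, function(opt) {
      w <- base * exp(-params$selection_strength * ((traits - opt) / tsd)^2)
      w / sum(w)
    }, numeric(S))
    mix <- (1 - params$dispersal_rate) * habPool +
      params$dispersal_rate / S            # flat regional component
    # weight-axis tilt: tau calibrated so d E[BC] / d|dw| ~ weight_slope
    tau <- params$weight_slope * 2 * sqrt(pi / 2)
    eta <- stats::rnorm(S, 0, tau)
    wmid <- mean(params$weight_range_g)
    n <- H * nf
    ids <- sprintf("%s_%02d", rep(habs, each = nf), rep(seq_len(nf), H))
    habitat <- rep(habs, each = nf)
    weights <- stats::runif(n, params$weight_range_g[1],
                            params$weight_range_g[2])
    weights[habitat == "water"] <- NA_real_
    counts <- matrix(0, S, n, dimnames = list(tree$tip.label, ids))
    for (k in seq_len(n)) {
      p <- mix[, match(habitat[k], habs)]
      if (!is.na(weights[k]))
        p <- p * exp(eta * (weights[k] - wmid))
      p <- p / sum(p)
      counts[, k] <- stats::rmultinom(1, params$reads_per_sample, p)
    }
    meta <- data.frame(
      sample_id = ids, habitat = habitat, body_weight_g = weights,
      site = sample(c("S1", "S2", "S3"), n, replace = TRUE),
      month = sample(c("June", "July", "August"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    list(counts = counts, meta = meta, optima = optima, weights = weights)
  })

  regime <- if (params$selection_strength == 0) "drift-dominated"
    else if (params$selection_strength >= 10 && params$dispersal_rate <= 0.2)
      "selection-dominated"
    else "mixed"
  truth <- list(habitat_optima = stats::setNames(res$optima, habs),
                fish_weights = stats::setNames(res$weights, res$meta$sample_id),
                regime = regime, params = unclass(params))
  list(experiment = MetacomExperiment(res$counts, res$meta, tree),
       truth = truth)
}
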