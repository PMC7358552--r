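#' Identify core OTUs within a habitat
#'
#' Default rule ("prevalence"): an OTU is core iff its relative abundance
#' strictly exceeds \code{abundanceThreshold} in strictly more than
#' \code{prevalenceThreshold} of the habitat's samples. The stricter
#' literal rule ("all_detected") additionally requires the abundance gate
#' to hold in every sample where the OTU is detected, with detection in
#' more than \code{prevalenceThreshold} of samples.
#'
#' @param x MetacomExperiment or samples-x-OTUs count matrix.
#' @param habitat habitat to analyse (ignored for matrix input, where all
#'   rows are used).
#' @param prevalenceThreshold fraction of samples, in (0, 1); default 0.8.
#' @param abundanceThreshold relative abundance, in (0, 1); default 0.01.
#' @param rule "prevalence" (default) or "all_detected".
#' @return list of class \code{"CoreSet"}: habitat, core_otu_ids,
#'   prevalence (per OTU, fraction of samples passing the abundance gate),
#'   core_abundance_fraction (mean per-sample summed relative abundance of
#'   the core set), n_samples.
#' @export
findCoreTaxa <- function(x, habitat = NULL, prevalenceThreshold = 0.8,
                         abundanceThreshold = 0.01,
                         rule = c("prevalence", "all_detected")) {
  rule <- match.arg(rule)
  if (prevalenceThreshold <= 0 || prevalenceThreshold >= 1)
    stop("prevalenceThreshold must be in (0, 1)")
  if (abundanceThreshold <= 0 || abundanceThreshold >= 1)
    stop("abundanceThreshold must be in (0, 1)")
  if (is(x, "MetacomExperiment")) {
    if (is.null(habitat)) stop("habitat required")
    m <- sampleCounts(x)[habitats(x) == habitat, , drop = FALSE]
    if (nrow(m) == 0) stop("no samples in habitat ", habitat)
  } else {
    m <- as.matrix(x)
    if (is.null(habitat)) habitat <- NA_character_
  }
  rel <- .relAbundance(m)
  pass <- rel > abundanceThreshold
  prevalence <- colMeans(pass)
  core <- prevalence > prevalenceThreshold
  if (rule == "all_detected") {
    detected <- m > 0
    everyDetected <- colSums(detected & !pass) == 0 & colSums(detected) > 0
    core <- (colMeans(detected) > prevalenceThreshold) & everyDetected
  }
  ids <- colnames(m)[core]
  frac <- if (length(ids) > 0)
    mean(rowSums(rel[, ids, drop = FALSE])) else 0
  structure(list(habitat = habitat, core_otu_ids = ids,
                 prevalence = prevalence,
                 core_abundance_fraction = frac,
                 n_samples = nrow(m)),
            class = "CoreSet")
}

#' Venn partition of core OTU sets across habitats
#'
#' For every non-empty habitat combination, the OTUs that are core in
#' exactly that combination. The partition cells are disjoint and their
#' counts sum to the size of the union of all core sets.
#'
#' @param coreSets list of \code{CoreSet} objects (>= 2), or a named list
#'   of character vectors of core OTU ids.
#' @return data.frame: combination (habitat names joined by "&"), n, otus
#'   (list column).
#' @export
coreOverlap <- function(coreSets) {
  sets <- lapply(coreSets, function(s)
    if (inherits(s, "CoreSet")) s$core_otu_ids else as.character(s))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- vapply(coreSets, function(s)
      if (inherits(s, "CoreSet")) s$habitat else NA_character_, character(1))
  if (length(sets) < 2) stop("need at least 2 core sets")
  universe <- unique(unlist(sets))
  if (length(universe) == 0)
    return(data.frame(combination = character(0), n = integer(0)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  signature <- apply(membership, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  cells <- split(universe, signature)
  data.frame(combination = names(cells),
             n = lengths(cells),
             otus = I(unname(cells)),
             row.names = NULL)
}
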