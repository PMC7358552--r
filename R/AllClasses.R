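#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib microAssembly, .registration = TRUE
NULL

#' Recognised body habitats
#'
#' The habitat vocabulary used throughout the package: four fish body
#' habitats plus the surrounding water.
#'
#' @export
HABITATS <- c("skin", "gill", "stomach", "hindgut", "water")

#' MetacomExperiment: a habitat-structured microbial metacommunity
#'
#' A \linkS4class{SummarizedExperiment} holding an OTU count matrix
#' (OTUs as rows, samples as columns, assay \code{"counts"}), per-sample
#' metadata in \code{colData} (\code{habitat}, \code{body_weight_g},
#' \code{site}, \code{month}) and, optionally, a rooted phylogeny over the
#' OTU pool in the \code{tree} slot.
#'
#' Invariants enforced by the validity method: counts are non-negative
#' integers; sample and OTU identifiers are unique; habitats come from
#' \code{\link{HABITATS}}; every non-water sample carries a positive body
#' weight; a supplied tree has unique tips and non-negative branch lengths.
#'
#' @slot tree a \code{phylo} object or \code{NULL}.
#' @export
setClass("MetacomExperiment",
  contains = "SummarizedExperiment",
  representation(tree = "ANY"),
  prototype(tree = NULL)
)

.validCounts <- function(m) {
  if (!is.numeric(m)) return("counts must be numeric")
  if (anyNA(m)) return("counts contain NA")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) return("counts must be integral")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry OTU rownames and sample colnames")
  if (anyDuplicated(rownames(m))) return("duplicate OTU id")
  if (anyDuplicated(colnames(m))) return("duplicate sample id")
  TRUE
}

.validTree <- function(tree, otus) {
  if (is.null(tree)) return(TRUE)
  if (!inherits(tree, "phylo")) return("tree must be a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) return("duplicate tip label in tree")
  if (is.null(tree$edge.length)) return("tree must have branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    return("tree branch lengths must be non-negative")
  TRUE
}

setValidity("MetacomExperiment", function(object) {
  m <- SummarizedExperiment::assay(object, "counts")
  ok <- .validCounts(m)
  if (!isTRUE(ok)) return(ok)
  cd <- SummarizedExperiment::colData(object)
  if (!"habitat" %in% colnames(cd)) return("colData must contain 'habitat'")
  hab <- as.character(cd$habitat)
  bad <- setdiff(unique(hab), HABITATS)
  if (length(bad) > 0)
    return(sprintf("unknown habitat '%s'; allowed: %s",
                   bad[1], paste(HABITATS, collapse = ", ")))
  if ("body_weight_g" %in% colnames(cd)) {
    w <- cd$body_weight_g
    if (any(!is.na(w) & w <= 0)) return("body_weight_g must be positive")
    if (any(is.na(w) & hab != "water"))
      return("body_weight_g required for all non-water samples")
  } else if (any(hab != "water")) {
    return("colData must contain 'body_weight_g' for non-water samples")
  }
  .validTree(object@tree, rownames(m))
})

#' Construct a MetacomExperiment
#'
#' @param counts numeric matrix of OTU counts, OTUs as rows and samples as
#'   columns (the on-disk orientation), with dimnames.
#' @param sampleData data.frame of per-sample metadata with columns
#'   \code{sample_id}, \code{habitat}, \code{body_weight_g} and optionally
#'   \code{site}, \code{month}. Rows are matched to count columns by
#'   \code{sample_id}.
#' @param tree optional \code{phylo} over the OTU pool.
#' @return a validated \linkS4class{MetacomExperiment}.
#' @examples
#' cnt <- matrix(rpois(12, 5), 4, 3,
#'               dimnames = list(paste0("OTU_", 1:4), paste0("F", 1:3)))
#' meta <- data.frame(sample_id = paste0("F", 1:3), habitat = "gill",
#'                    body_weight_g = c(40, 55, 80))
#' MetacomExperiment(cnt, meta)
#' @export
MetacomExperiment <- function(counts, sampleData, tree = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is.data.frame(sampleData))
    sampleData <- as.data.frame(sampleData)
  if (!"sample_id" %in% colnames(sampleData))
    stop("sampleData must have a 'sample_id' column")
  if (anyDuplicated(sampleData$sample_id))
    stop("duplicate sample id in sampleData")
  miss <- setdiff(colnames(counts), sampleData$sample_id)
  if (length(miss) > 0)
    stop("samples missing from sampleData: ", paste(miss, collapse = ", "))
  sampleData <- sampleData[match(colnames(counts), sampleData$sample_id), ,
                           drop = FALSE]
  for (col in c("site", "month"))
    if (!col %in% colnames(sampleData)) sampleData[[col]] <- NA_character_
  if (!"body_weight_g" %in% colnames(sampleData))
    sampleData$body_weight_g <- NA_real_
  cd <- S4Vectors::DataFrame(sampleData, row.names = sampleData$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("MetacomExperiment", se, tree = tree)
}

#' @describeIn MetacomExperiment OTU count matrix (OTUs x samples).
#' @param x a MetacomExperiment.
#' @export
otuCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn MetacomExperiment count matrix with samples as rows, the
#'   orientation used by the distance and diversity machinery.
#' @export
sampleCounts <- function(x) t(SummarizedExperiment::assay(x, "counts"))

#' @describeIn MetacomExperiment habitat label per sample (named character).
#' @export
habitats <- function(x) {
  h <- as.character(SummarizedExperiment::colData(x)$habitat)
  names(h) <- colnames(x)
  h
}

#' @describeIn MetacomExperiment body weight in grams per sample (named,
#'   NA for water samples).
#' @export
bodyWeights <- function(x) {
  w <- SummarizedExperiment::colData(x)$body_weight_g
  names(w) <- colnames(x)
  w
}

#' @describeIn MetacomExperiment phylogeny over the OTU pool, or NULL.
#' @export
phyloTree <- function(x) x@tree

setMethod("show", "MetacomExperiment", function(object) {
  m <- otuCounts(object)
  cat("MetacomExperiment:", nrow(m), "OTUs x", ncol(m), "samples\n")
  tab <- table(habitats(object))
  cat("  habitats:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("  total counts:", format(sum(m), big.mark = ","),
      if (is.null(object@tree)) "| no tree" else
        sprintf("| tree with %d tips", length(object@tree$tip.label)), "\n")
})
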