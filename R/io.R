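#' Read an OTU count table
#'
#' Reads a tab-delimited OTU table (OTUs as rows, samples as columns, first
#' column the OTU identifier; a leading \code{#OTU ID} header token is
#' accepted) or a BIOM file. If the header's first token indicates samples
#' as rows (\code{#Sample ID} / \code{sample_id}), the table is transposed
#' on input.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"biom"}.
#' @return numeric count matrix, OTUs as rows, samples as columns.
#' @export
readOtuTable <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  } else {
    header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    first <- sub("^#", "", trimws(header[1]))
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             comment.char = "", check.names = FALSE,
                             colClasses = "character")
    ids <- tab[[1]]
    if (anyDuplicated(ids))
      stop("duplicate ", if (grepl("sample", tolower(first))) "sample"
           else "OTU", " id in first column")
    if (anyDuplicated(colnames(tab)[-1]))
      stop("duplicate sample id in header")
    vals <- suppressWarnings(
      vapply(tab[-1], as.numeric, numeric(nrow(tab))))
    if (nrow(tab) == 1) vals <- matrix(vals, nrow = 1,
                                       dimnames = list(NULL, colnames(tab)[-1]))
    m <- as.matrix(vals)
    rownames(m) <- ids
    if (grepl("sample", tolower(first))) m <- t(m)  # samples-as-rows dialect
  }
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0) stop("empty OTU table")
  if (anyNA(m)) stop("non-numeric or NaN counts in OTU table")
  if (any(m < 0)) stop("negative counts in OTU table")
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer counts in OTU table")
  if (anyDuplicated(rownames(m))) stop("duplicate OTU id")
  if (anyDuplicated(colnames(m))) stop("duplicate sample id")
  storage.mode(m) <- "double"
  m
}

#' Write an OTU count table as TSV (OTUs as rows)
#'
#' @param counts OTU x sample matrix or a MetacomExperiment.
#' @param path output path.
#' @export
writeOtuTable <- function(counts, path) {
  if (is(counts, "MetacomExperiment")) counts <- otuCounts(counts)
  df <- data.frame(`#OTU ID` = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a TSV with header columns \code{sample_id}, \code{habitat},
#' \code{body_weight_g}, \code{site}, \code{month}. Habitats are validated
#' against \code{\link{HABITATS}}; weights must be positive and may be
#' missing only for water samples.
#'
#' @param path file path.
#' @return data.frame keyed by \code{sample_id}.
#' @export
readSampleData <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  need <- c("sample_id", "habitat", "body_weight_g", "site", "month")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id in metadata")
  df$habitat <- trimws(df$habitat)
  bad <- setdiff(unique(df$habitat), HABITATS)
  if (length(bad) > 0)
    stop(sprintf("unknown habitat '%s'; allowed habitats: %s", bad[1],
                 paste(HABITATS, collapse = ", ")))
  w <- suppressWarnings(as.numeric(df$body_weight_g))
  if (any(!is.na(df$body_weight_g) & is.na(w)))
    stop("non-numeric body weight")
  if (any(!is.na(w) & w <= 0)) stop("body weight must be positive")
  if (any(is.na(w) & df$habitat != "water"))
    stop("body weight required for all non-water samples")
  df$body_weight_g <- w
  df
}

#' Read a rooted phylogeny from a newick file
#'
#' Wraps \code{ape::read.tree} with the checks the downstream phylogenetic
#' machinery needs: unique tip labels and branch lengths on every edge.
#'
#' @param path newick file.
#' @return a \code{phylo}.
#' @export
readTreeFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip label")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("every branch must have a length (required for cophenetic distances)")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Read table + metadata (+ optional tree) into a MetacomExperiment
#'
#' @param tablePath OTU table path.
#' @param metadataPath metadata TSV path.
#' @param treePath optional newick path.
#' @param format OTU table format.
#' @return a \linkS4class{MetacomExperiment}.
#' @export
readMetacom <- function(tablePath, metadataPath, treePath = NULL,
                        format = c("tsv", "biom")) {
  counts <- readOtuTable(tablePath, format)
  meta <- readSampleData(metadataPath)
  tree <- if (!is.null(treePath)) readTreeFile(treePath) else NULL
  MetacomExperiment(counts, meta, tree)
}

#' Default rarefaction depth (reads per sample)
#' @export
RAREFACTION_DEPTH <- 23875L

#' Rarefy samples to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly
#' \code{depth} reads (hypergeometric rarefaction). Samples whose total is
#' below \code{depth} are dropped with a warning naming them; the dropped
#' ids are attached as attribute \code{"dropped"}.
#'
#' @param x a MetacomExperiment or samples-x-OTUs count matrix.
#' @param depth target reads per sample (default \code{RAREFACTION_DEPTH}).
#' @param seed integer seed; identical seeds give identical output.
#' @return same class as \code{x}, every retained sample summing to
#'   \code{depth}.
#' @export
setGeneric("rarefySamples",
           function(x, depth = RAREFACTION_DEPTH, seed = 1L)
             standardGeneric("rarefySamples"))

.rarefyMatrix <- function(m, depth, seed) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0) stop("depth must be a positive integer")
  tot <- rowSums(m)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  if (any(!keep)) {
    dropped <- rownames(m)[!keep]
    warning("dropping ", length(dropped), " sample(s) below depth ", depth,
            ": ", paste(dropped, collapse = ", "))
  } else {
    dropped <- character(0)
  }
  kept <- m[keep, , drop = FALSE]
  out <- withSeed(seed, {
    t(apply(kept, 1, function(row) {
      if (sum(row) == depth) return(row)
      reads <- rep.int(seq_along(row), row)
      tabulate(reads[sample.int(length(reads), depth)],
               nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(kept)
  storage.mode(out) <- "double"
  attr(out, "dropped") <- dropped
  out
}

#' @rdname rarefySamples
setMethod("rarefySamples", "matrix", function(x, depth, seed) {
  .rarefyMatrix(x, depth, seed)
})

#' @rdname rarefySamples
setMethod("rarefySamples", "MetacomExperiment", function(x, depth, seed) {
  m <- .rarefyMatrix(sampleCounts(x), depth, seed)
  keep <- rownames(m)
  out <- x[, keep]
  SummarizedExperiment::assay(out, "counts") <- t(m)
  out
})
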