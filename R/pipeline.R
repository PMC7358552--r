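#' Assemble a pipeline configuration
#'
#' Merges user settings (a list or a YAML file) over the package defaults.
#' Stage parameters live under \code{rarefaction}, \code{diversity},
#' \code{weight_regression}, \code{core}, \code{partition},
#' \code{processes} and \code{source_tracking}; input paths under
#' \code{paths} (\code{table}, \code{metadata}, \code{tree}); \code{seed}
#' is the master seed from which each stage derives its own stream.
#'
#' @param config list of overrides or path to a YAML file.
#' @return a complete configuration list.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    paths = list(table = NULL, metadata = NULL, tree = NULL),
    output_dir = NULL,
    seed = 1L,
    rarefaction = list(enabled = TRUE, depth = RAREFACTION_DEPTH),
    diversity = list(permutations = 999, mantel_permutations = 10000),
    weight_regression = list(permutations = 1000),
    core = list(prevalence_threshold = 0.8, abundance_threshold = 0.01),
    partition = list(distance_mode = "taxonomic",
                     correction = "equivalent_numbers"),
    processes = list(enabled = TRUE, n_null = 999,
                     include_between = FALSE),
    source_tracking = list(enabled = TRUE, sink_depth = 1000,
                           restarts = 10, burnin = 100,
                           draws_per_restart = 10, delay = 10))
  merge <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge(defaults, config)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.configHash <- function(config) {
  config$output_dir <- NULL   # hash analysis parameters, not locations
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full metacommunity analysis pipeline
#'
#' Executes rarefaction, diversity statistics, weight regression, core
#' taxa, Rao diversity partitioning, assembly-process quantification and
#' source tracking on one dataset, writing per-stage outputs and an
#' aggregated \code{report.json} to \code{output_dir}. Reruns with the
#' same configuration and seed are byte-identical.
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{pipelineConfig}}).
#' @param experiment optional \linkS4class{MetacomExperiment}; if NULL the
#'   inputs are read from \code{config$paths}.
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config = list(), experiment = NULL) {
  cfg <- pipelineConfig(config)
  outDir <- cfg$output_dir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(x, file) if (!is.null(outDir)) .writeJson(x, file.path(outDir, file))
  emitTsv <- function(df, file) if (!is.null(outDir))
    utils::write.table(df, file.path(outDir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  stage <- function(name, code) {
    message("[", name, "] running")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  if (is.null(experiment)) {
    if (is.null(cfg$paths$table) || is.null(cfg$paths$metadata))
      stop("missing input: config$paths$table and config$paths$metadata")
    experiment <- readMetacom(cfg$paths$table, cfg$paths$metadata,
                              cfg$paths$tree)
  }
  report <- list(provenance = list(
    config_hash = .configHash(cfg),
    seed = cfg$seed,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("microAssembly"))))

  # --- rarefaction ---------------------------------------------------
  if (isTRUE(cfg$rarefaction$enabled)) {
    experiment <- stage("rarefy", rarefySamples(
      experiment, cfg$rarefaction$depth, deriveSeed(cfg$seed, "rarefy")))
    report$rarefaction <- list(depth = cfg$rarefaction$depth,
                               n_samples = ncol(experiment))
  }
  hab <- habitats(experiment)

  # --- diversity -----------------------------------------------------
  report$diversity <- stage("diversity", {
    alpha <- alphaDiversity(experiment)
    emitTsv(alpha, "alpha.tsv")
    d <- brayCurtis(experiment)
    emitTsv(data.frame(sample_id = rownames(d), d, check.names = FALSE),
            "bc_distance.tsv")
    ord <- pcoaOrdination(d)
    emitTsv(data.frame(sample_id = rownames(ord$axes), ord$axes,
                       check.names = FALSE), "pcoa_axes.tsv")
    perm <- permanovaTest(d, hab, cfg$diversity$permutations,
                          deriveSeed(cfg$seed, "permanova"))
    anosim <- anosimTest(d, hab, cfg$diversity$permutations,
                         deriveSeed(cfg$seed, "anosim"))
    w <- bodyWeights(experiment)
    mantel <- NULL
    if (sum(!is.na(w)) >= 4) {
      ids <- names(w)[!is.na(w)]
      dw <- as.matrix(stats::dist(w[ids]))
      mantel <- mantelTest(d[ids, ids], dw,
                           cfg$diversity$mantel_permutations,
                           seed = deriveSeed(cfg$seed, "mantel"))
    }
    tests <- list(permanova = perm, anosim = anosim,
                  mantel_weight = mantel,
                  pcoa_proportion_explained =
                    ord$proportion_explained[seq_len(min(3, length(ord$proportion_explained)))])
    emit(tests, "tests.json")
    c(tests, list(mean_chao1 = mean(alpha$chao1)))
  })
  dBC <- brayCurtis(experiment)

  # --- weight regression ---------------------------------------------
  report$weight_regression <- stage("weightreg", {
    reg <- distanceRegressionByHabitat(
      experiment, dBC, cfg$weight_regression$permutations, cfg$seed)
    emit(reg, "regression.json")
    reg
  })

  # --- core taxa ------------------------------------------------------
  report$core_taxa <- stage("core", {
    sets <- list()
    for (h in unique(hab)) {
      cs <- findCoreTaxa(experiment, h,
                         cfg$core$prevalence_threshold,
                         cfg$core$abundance_threshold)
      sets[[h]] <- cs
      emitTsv(data.frame(otu_id = cs$core_otu_ids,
                         prevalence = cs$prevalence[cs$core_otu_ids]),
              paste0("core_", h, ".tsv"))
    }
    venn <- if (length(sets) >= 2) coreOverlap(sets) else NULL
    if (!is.null(venn))
      emit(list(partition = venn), "venn.json")
    list(core = lapply(sets, function(s)
           list(habitat = s$habitat, n_core = length(s$core_otu_ids),
                core_otu_ids = s$core_otu_ids,
                core_abundance_fraction = s$core_abundance_fraction)),
         venn = if (is.null(venn)) NULL else
           stats::setNames(as.list(venn$n), venn$combination))
  })

  # --- Rao partition --------------------------------------------------
  report$rao_partition <- stage("partition", {
    part <- partitionDiversity(experiment,
                               distanceMode = cfg$partition$distance_mode,
                               correction = cfg$partition$correction)
    emit(part, "partition.json")
    part
  })

  # --- assembly processes ---------------------------------------------
  if (isTRUE(cfg$processes$enabled)) {
    report$assembly_processes <- stage("processes", {
      if (is.null(phyloTree(experiment)))
        stop("missing input: phylogenetic tree")
      turnover <- pairwiseTurnover(
        experiment, nNull = cfg$processes$n_null,
        seed = deriveSeed(cfg$seed, "processes"))
      emitTsv(turnover, "pairwise_turnover.tsv")
      prof <- assemblyProfile(experiment, turnover = turnover)
      emit(prof, "profile.json")
      prof
    })
  }

  # --- source tracking ------------------------------------------------
  if (isTRUE(cfg$source_tracking$enabled) && length(unique(hab)) >= 2) {
    report$source_tracking <- stage("sourcetrack", {
      st <- leaveOneHabitatOut(
        experiment, seed = deriveSeed(cfg$seed, "sourcetrack"),
        sinkDepth = cfg$source_tracking$sink_depth,
        restarts = cfg$source_tracking$restarts,
        burnin = cfg$source_tracking$burnin,
        drawsPerRestart = cfg$source_tracking$draws_per_restart,
        delay = cfg$source_tracking$delay)
      for (h in names(st))
        emit(list(habitat = h, mean_proportions = as.list(st[[h]]$mean_proportions),
                  n_sinks = st[[h]]$n_sinks),
             paste0("sources_", h, ".json"))
      lapply(st, function(s)
        list(mean_proportions = as.list(s$mean_proportions),
             n_sinks = s$n_sinks))
    })
  }

  if (!is.null(outDir)) .writeJson(report, file.path(outDir, "report.json"))
  invisible(report)
}

#' Write a simulated metacommunity to disk
#'
#' Emits \code{table.tsv}, \code{metadata.tsv}, \code{tree.nwk} and
#' \code{truth.json} for a \code{\link{simulateMetacommunity}} result.
#'
#' @param sim result of \code{simulateMetacommunity}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mex <- sim$experiment
  writeOtuTable(mex, file.path(dir, "table.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(mex))
  utils::write.table(cd, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(phyloTree(mex), file.path(dir, "tree.nwk"))
  .writeJson(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
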