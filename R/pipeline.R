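# Top-level orchestration: YAML configuration, seed ledger, and the three
# analysis arms (fpr / spike / betadiv) run over declared grids.

.validatePipelineConfig <- function(cfg) {
  fail <- function(...) stop("invalid config: ", ..., call. = FALSE)
  if (!is.list(cfg)) fail("not a mapping")
  if (is.null(cfg$master_seed)) fail("master_seed is required")
  if (is.null(cfg$datasets) || !length(cfg$datasets))
    fail("at least one dataset is required")
  for (ds in cfg$datasets) {
    if (is.null(ds$name)) fail("every dataset needs a name")
    if (is.null(ds$path) == is.null(ds$synth))
      fail("dataset '", ds$name, "' needs exactly one of path or synth")
    if (!is.null(ds$synth) && is.null(ds$synth$seed))
      fail("synthetic dataset '", ds$name, "' needs a seed")
  }
  if (is.null(cfg$arms) || !length(cfg$arms)) fail("no arms requested")
  known <- c("fpr", "spike", "betadiv")
  bad <- setdiff(names(cfg$arms), known)
  if (length(bad)) fail("unknown arm(s): ", paste(bad, collapse = ", "))
  for (arm in intersect(names(cfg$arms), c("fpr", "spike"))) {
    a <- cfg$arms[[arm]]
    if (is.null(a$methods) || !length(a$methods))
      fail("arm '", arm, "' needs methods")
  }
  if ("betadiv" %in% names(cfg$arms) &&
      is.null(cfg$arms$betadiv$design_variable))
    fail("betadiv arm needs design_variable")
  invisible(cfg)
}

.loadPipelineDatasets <- function(cfg, baseDir = ".") {
  out <- list()
  for (ds in cfg$datasets) {
    out[[ds$name]] <- if (!is.null(ds$path)) {
      p <- ds$path
      if (!file.exists(p)) p <- file.path(baseDir, ds$path)
      readCountTable(p, format = if (grepl("\\.biom$", p)) "biom" else "tsv")
    } else {
      s <- ds$synth
      generateTable(synthConfig(
        nOtus = s$n_otus %||% 1000L,
        nSamples = s$n_samples %||% 100L,
        targetSparsity = s$target_sparsity %||% 0.85,
        libSizeLogMean = s$library_size_log_mean %||% 10,
        libSizeLogSd = s$library_size_log_sd %||% 1,
        tailExponent = s$otu_mean_tail_exponent %||% 1,
        dispersion = s$dispersion %||% 0.5,
        seed = s$seed))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.armGrid <- function(cfg, arm) {
  a <- cfg$arms[[arm]]
  spikeConfigs <- NULL
  if (arm == "spike") {
    sc <- a$schemes
    spikeConfigs <- if (is.null(sc)) defaultSpikeConfigs() else {
      rows <- list()
      if (!is.null(sc$multiplicative))
        rows[[1L]] <- data.frame(scheme = "multiplicative",
                                 magnitude = as.numeric(sc$multiplicative))
      if (!is.null(sc$additive))
        rows[[2L]] <- data.frame(scheme = "additive",
                                 magnitude = as.numeric(sc$additive))
      if (isTRUE(sc$mixed))
        rows[[3L]] <- data.frame(scheme = "mixed", magnitude = NA_real_)
      do.call(rbind, rows)
    }
  }
  experimentGrid(
    datasets = vapply(cfg$datasets, `[[`, "", "name"),
    caseProportions = as.numeric(a$case_proportions %||%
                                   c(0.10, 0.25, 0.50)),
    nIterations = as.integer(a$iterations %||% 150L),
    methods = as.character(a$methods %||% character(0)),
    spikeConfigs = spikeConfigs,
    masterSeed = as.integer(cfg$master_seed))
}

#' Run the full benchmarking pipeline from a configuration file
#'
#' Executes the requested analysis arms (`fpr`, `spike`, `betadiv`) over
#' the declared dataset/method grids, writing long-format result TSVs and
#' a JSON run manifest (config hash, master seed, per-arm status, grid
#' sizes, timestamps) sufficient to reproduce every output from the
#' recorded seeds. With `dryRun = TRUE` only grid bookkeeping is computed.
#'
#' @param config path to a YAML configuration file, or an equivalent list.
#' @param outDir output directory (default: `output_dir` from the config,
#'   else a temporary directory).
#' @param dryRun if `TRUE`, validate and report grid sizes without
#'   computing anything.
#' @param ... passed to the experiment runners (e.g. `nPerm`).
#' @return Invisibly, the manifest list; with `dryRun = TRUE`, a named
#'   vector of grid sizes.
#' @export
runPipeline <- function(config, outDir = NULL, dryRun = FALSE, ...) {
  baseDir <- "."
  if (is.character(config)) {
    baseDir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  cfg <- .validatePipelineConfig(config)
  grids <- list()
  for (arm in intersect(names(cfg$arms), c("fpr", "spike")))
    grids[[arm]] <- .armGrid(cfg, arm)
  sizes <- vapply(grids, gridSize, integer(1))
  if ("betadiv" %in% names(cfg$arms)) {
    a <- cfg$arms$betadiv
    nNorm <- length(a$normalizations %||%
                      c("none", "TSS", "CSS", "TMM", "DESeq"))
    nTrans <- if (is.null(a$transformations))
      nrow(defaultTransformations()) else length(a$transformations)
    nMet <- length(a$metrics %||% c("bray", "euclidean", "jsd"))
    sizes <- c(sizes, betadiv = as.integer(nNorm * nTrans * nMet *
                                             length(cfg$datasets)))
  }
  if (dryRun) return(sizes)
  if (is.null(outDir)) outDir <- cfg$output_dir %||% tempfile("abench")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tables <- .loadPipelineDatasets(cfg, baseDir)
  manifest <- list(
    tool = paste("ampliconbench",
                 as.character(utils::packageVersion("ampliconbench"))),
    master_seed = cfg$master_seed,
    config_hash = sum(utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    grid_sizes = as.list(sizes),
    arms = list())
  if (!is.null(grids$fpr)) {
    res <- runFPRExperiment(grids$fpr, tables, ...)
    f <- file.path(outDir, "fpr_results.tsv")
    utils::write.table(res, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$arms$fpr <- list(file = basename(f), rows = nrow(res),
                              errors = sum(res$status != "ok"))
  }
  if (!is.null(grids$spike)) {
    res <- runSpikeExperiment(grids$spike, tables, ...)
    f <- file.path(outDir, "spike_results.tsv")
    utils::write.table(res, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$arms$spike <- list(file = basename(f), rows = nrow(res),
                                errors = sum(res$status != "ok"))
  }
  if ("betadiv" %in% names(cfg$arms)) {
    a <- cfg$arms$betadiv
    tree <- if (!is.null(a$tree)) readNewick(
      if (file.exists(a$tree)) a$tree else file.path(baseDir, a$tree))
    meta <- if (!is.null(a$metadata)) readSampleMetadata(
      if (file.exists(a$metadata)) a$metadata
      else file.path(baseDir, a$metadata))
    allRes <- list()
    for (nm in names(tables)) {
      res <- betaGrid(
        tables[[nm]], metadata = meta,
        designVariable = a$design_variable,
        normalizations = a$normalizations %||%
          c("none", "TSS", "CSS", "TMM", "DESeq"),
        transformations = if (is.null(a$transformations))
          defaultTransformations() else as.character(a$transformations),
        metrics = a$metrics %||% c("bray", "euclidean", "jsd"),
        tree = tree, strata = a$strata,
        nPerm = a$n_perm %||% 999L,
        seed = as.integer(cfg$master_seed))
      res <- cbind(dataset = nm, res)
      allRes[[nm]] <- res
    }
    res <- do.call(rbind, allRes)
    f <- file.path(outDir, "betadiv_results.tsv")
    utils::write.table(res, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$arms$betadiv <- list(
      file = basename(f), rows = nrow(res),
      errors = sum(!res$status %in% "ok"))
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
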