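#' False positive rate at a nominal threshold
#'
#' Under permuted (null) labels every positive is false, so the FPR is the
#' fraction of OTUs with crude p strictly below `alpha` (fixed at 0.05 for
#' headline records).
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @param alpha significance threshold (strict inequality).
#' @return fraction in \[0,1\].
#' @export
falsePositiveRate <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  mean(p < alpha)
}

#' Spike-retrieval AUC
#'
#' Area under the ROC curve for discriminating spiked from non-spiked OTUs
#' by raw p-value, assuming spiked OTUs have lower p: the Mann-Whitney
#' probability that a random spiked OTU has a lower p than a random
#' non-spiked OTU, with ties counted 1/2 (mid-rank handling -- heavy
#' p-value ties are routine with permutation tests).
#'
#' @param p numeric vector of p-values.
#' @param truth logical vector; `TRUE` = spiked.
#' @return AUC in \[0,1\].
#' @export
aucSpike <- function(p, truth) {
  truth <- as.logical(truth)
  if (length(p) != length(truth)) stop("p and truth lengths differ")
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("need at least one spiked and one non-spiked OTU")
  r <- rank(p, ties.method = "average")
  # U = #{pairs with p_nonspiked > p_spiked} + ties/2
  (sum(r[!truth]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' P-value quantile of one OTU within a result
#'
#' The detection-sensitivity diagnostic: the mean rank of a spiked OTU's
#' p-value among all p-values of the dataset, divided by the number of
#' OTUs. Filtered or uncomputed p-values participate as 1 (missing-p rule),
#' so quantiles of exactly 1 are attainable.
#'
#' @param p numeric vector of p-values.
#' @param otuIndex index (or OTU id if `p` is named) of the OTU of interest.
#' @return quantile in (0, 1\].
#' @export
spikeQuantile <- function(p, otuIndex) {
  if (is.character(otuIndex)) otuIndex <- match(otuIndex, names(p))
  if (is.na(otuIndex) || otuIndex < 1L || otuIndex > length(p))
    stop("invalid OTU index")
  unname(rank(p, ties.method = "average")[otuIndex] / length(p))
}

#' Join per-OTU sparsity with p-values
#'
#' Raw material for the sparsity-vs-p diagnostic: one record per OTU, no
#' smoothing.
#'
#' @param result a [DAResult-class].
#' @param x the [OTUTable-class] the result was computed on.
#' @return `data.frame` with columns `otu_id`, `sparsity`, `p`.
#' @export
sparsityPTable <- function(result, x) {
  assertCountTable(x)
  if (!setequal(result@otuIds, rownames(x)))
    stop("OTU ids of result and table do not match")
  sp <- sparsity(x, "otu")[result@otuIds]
  data.frame(otu_id = result@otuIds, sparsity = unname(sp), p = result@p,
             stringsAsFactors = FALSE)
}

#' Describe an experiment grid
#'
#' @param datasets character vector of dataset names.
#' @param caseProportions case fractions (default the study design's 10, 25
#'   and 50%).
#' @param nIterations repeats per cell (the study design used 150).
#' @param methods DA method names (need not be registered for dry-run
#'   bookkeeping).
#' @param spikeConfigs optional `data.frame` with columns `scheme`,
#'   `magnitude` (one row per spike configuration; use NA magnitude for the
#'   mixed scheme) -- omit for FPR grids.
#' @param masterSeed integer master seed; per-iteration seeds are derived
#'   deterministically from it.
#' @return An [ExperimentGrid-class].
#' @export
experimentGrid <- function(datasets, caseProportions = c(0.10, 0.25, 0.50),
                           nIterations = 150L, methods,
                           spikeConfigs = NULL, masterSeed = 1L) {
  if (is.null(spikeConfigs))
    spikeConfigs <- data.frame(scheme = character(0), magnitude = numeric(0))
  new("ExperimentGrid", datasets = as.character(datasets),
      caseProportions = caseProportions,
      nIterations = as.integer(nIterations),
      methods = as.character(methods),
      spikeConfigs = spikeConfigs, masterSeed = as.integer(masterSeed))
}

#' Default spike-configuration grid
#'
#' The study design: multiplicative magnitudes 0.5, 2, 5, 10, 20; additive
#' magnitudes 0.5, 2, 5, 10; one mixed configuration -- ten spike
#' configurations in total.
#'
#' @param multiplicative,additive magnitude vectors.
#' @param mixed include the mixed scheme row.
#' @return `data.frame` with columns `scheme`, `magnitude`.
#' @export
defaultSpikeConfigs <- function(multiplicative = c(0.5, 2, 5, 10, 20),
                                additive = c(0.5, 2, 5, 10),
                                mixed = TRUE) {
  out <- rbind(
    data.frame(scheme = "multiplicative", magnitude = multiplicative),
    data.frame(scheme = "additive", magnitude = additive))
  if (mixed)
    out <- rbind(out, data.frame(scheme = "mixed", magnitude = NA_real_))
  out
}

#' Number of planned runs in a grid
#'
#' Dry-run bookkeeping: datasets x proportions x iterations x methods
#' (x spike configurations, when present), without executing anything.
#'
#' @param grid an [ExperimentGrid-class].
#' @return integer count.
#' @export
gridSize <- function(grid) {
  stopifnot(is(grid, "ExperimentGrid"))
  n <- length(grid@datasets) * length(grid@caseProportions) *
    grid@nIterations * length(grid@methods)
  if (nrow(grid@spikeConfigs)) n <- n * nrow(grid@spikeConfigs)
  as.integer(n)
}

#' Run a false-positive-rate experiment
#'
#' For each (dataset, case proportion, iteration): one label assignment is
#' drawn (seed derived deterministically from the master seed) and shared
#' by all methods -- identical between methods, as the protocol requires --
#' then each method is run and its FPR at alpha = 0.05 recorded. Failed
#' method runs are recorded with `status = "error"` and the missing-p rule
#' (all p = 1, hence FPR 0) rather than silently dropped.
#'
#' @param grid an [ExperimentGrid-class] (its `spikeConfigs` are ignored).
#' @param tables named list of raw [OTUTable-class] objects covering
#'   `grid@datasets`.
#' @param alpha threshold for the FPR (0.05 for headline records).
#' @param ... passed to [runDAMethod()] (e.g. `nPerm` for the permutation
#'   test).
#' @return long-format `data.frame` with columns `dataset`, `method`,
#'   `proportion`, `iteration`, `seed`, `fpr`, `status`.
#' @export
runFPRExperiment <- function(grid, tables, alpha = 0.05, ...) {
  stopifnot(is(grid, "ExperimentGrid"))
  .checkTables(grid, tables)
  rows <- list()
  counter <- 0L
  for (ds in grid@datasets) {
    x <- tables[[ds]]
    for (prop in grid@caseProportions) {
      for (it in seq_len(grid@nIterations)) {
        counter <- counter + 1L
        seed <- deriveSeed(grid@masterSeed, counter)
        labels <- assignLabels(x, prop, seed)
        for (meth in grid@methods) {
          res <- runDAMethod(meth, x, labels, seed = deriveSeed(seed, 1L),
                             ...)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = ds, method = meth, proportion = prop, iteration = it,
            seed = seed, fpr = falsePositiveRate(res@p, alpha),
            status = if (is.null(res@info$error)) "ok" else "error",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Run a spike-in retrieval experiment
#'
#' As [runFPRExperiment()], with the spike step inserted between labelling
#' and testing: per iteration one label assignment and one truth set are
#' drawn and shared by every method and spike configuration; each method's
#' p-values are scored against the truth set with [aucSpike()].
#'
#' @inheritParams runFPRExperiment
#' @param otusPerTertile spike targets per relative-abundance tertile
#'   (default 5).
#' @param mixedMagnitudes magnitude set used by the mixed scheme rows.
#' @return long-format `data.frame` with columns `dataset`, `method`,
#'   `proportion`, `scheme`, `magnitude`, `iteration`, `seed`, `auc`,
#'   `status`.
#' @export
runSpikeExperiment <- function(grid, tables, otusPerTertile = 5L,
                               mixedMagnitudes = c(2, 5, 10, 20), ...) {
  stopifnot(is(grid, "ExperimentGrid"))
  if (!nrow(grid@spikeConfigs)) stop("grid has no spike configurations")
  .checkTables(grid, tables)
  rows <- list()
  counter <- 0L
  for (ds in grid@datasets) {
    x <- tables[[ds]]
    for (prop in grid@caseProportions) {
      for (it in seq_len(grid@nIterations)) {
        counter <- counter + 1L
        seed <- deriveSeed(grid@masterSeed, counter)
        labels <- assignLabels(x, prop, seed)
        targets <- selectSpikeTargets(x, labels, otusPerTertile,
                                      seed = deriveSeed(seed, 2L),
                                      mode = "lenient")
        for (ci in seq_len(nrow(grid@spikeConfigs))) {
          scheme <- grid@spikeConfigs$scheme[ci]
          mag <- grid@spikeConfigs$magnitude[ci]
          sr <- switch(scheme,
            multiplicative = spikeMultiplicative(x, labels, targets, mag),
            additive = spikeAdditive(x, labels, targets, mag),
            mixed = spikeMixed(x, labels, targets, mixedMagnitudes,
                               seed = deriveSeed(seed, 3L)),
            stop("unknown spike scheme: ", scheme))
          truthVec <- rownames(x) %in% sr@truth$otu_id
          for (meth in grid@methods) {
            res <- runDAMethod(meth, spikedTable(sr), labels,
                               seed = deriveSeed(seed, 1L), ...)
            rows[[length(rows) + 1L]] <- data.frame(
              dataset = ds, method = meth, proportion = prop,
              scheme = scheme, magnitude = mag, iteration = it,
              seed = seed, auc = aucSpike(res@p, truthVec),
              status = if (is.null(res@info$error)) "ok" else "error",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

.checkTables <- function(grid, tables) {
  missing <- setdiff(grid@datasets, names(tables))
  if (length(missing))
    stop("tables missing for dataset(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
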