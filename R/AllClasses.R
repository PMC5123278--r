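#' @import methods
#' @importFrom S4Vectors metadata `metadata<-` DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' OTUTable: an OTU-by-sample count matrix
#'
#' `OTUTable` extends [SummarizedExperiment::SummarizedExperiment] and holds a
#' single assay named `"counts"`: OTUs in rows, samples in columns. Raw tables
#' (`isRaw = TRUE`) contain non-negative integer-valued counts; normalized or
#' transformed tables carry `isRaw = FALSE` so downstream methods can enforce
#' raw-count preconditions (e.g. the NB GLM and the spike engine).
#'
#' @slot isRaw logical scalar; `TRUE` for raw integer counts.
#'
#' @details Orientation is fixed package-wide: OTUs in rows, samples in
#' columns. Library size (sequencing depth) is the column sum. Provenance
#' (generator seed, subsetting seed, configuration) is stored in
#' `metadata(x)$provenance`.
#'
#' @seealso [OTUTable()], [librarySizes()], [sparsity()],
#'   [toRelativeAbundance()]
#' @export
setClass("OTUTable",
  contains = "SummarizedExperiment",
  representation(isRaw = "logical"),
  prototype(isRaw = TRUE)
)

.validOTUTable <- function(object) {
  msg <- NULL
  if (!"counts" %in% names(assays(object, withDimnames = FALSE)))
    return("assay 'counts' is missing")
  m <- assay(object, "counts", withDimnames = FALSE)
  if (nrow(m) < 1L) msg <- c(msg, "need at least 1 OTU")
  if (ncol(m) < 2L) msg <- c(msg, "need at least 2 samples")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "OTU ids (rownames) and sample ids (colnames) are required")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate OTU ids")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  if (any(!is.finite(m))) msg <- c(msg, "counts must be finite")
  else if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@isRaw) != 1L || is.na(object@isRaw))
    msg <- c(msg, "isRaw must be TRUE or FALSE")
  else if (isTRUE(object@isRaw) && any(is.finite(m) & m != round(m)))
    msg <- c(msg, "raw tables must contain integer-valued counts")
  if (is.null(msg)) TRUE else msg
}
setValidity("OTUTable", .validOTUTable)

#' Construct an OTUTable
#'
#' @param counts numeric matrix, OTUs in rows and samples in columns, with
#'   rownames (OTU ids) and colnames (sample ids).
#' @param isRaw logical; `TRUE` if `counts` are raw integer-valued counts.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata
#'   (rownames or a `sample_id` column matching `colnames(counts)`).
#' @param provenance optional list recorded in `metadata(x)$provenance`
#'   (seeds, configuration) so every derived object is reproducible.
#'
#' @return An [OTUTable-class] object.
#' @examples
#' m <- matrix(c(2L, 0L, 0L, 5L, 1L, 1L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' ot <- OTUTable(m)
#' librarySizes(ot)
#' @export
OTUTable <- function(counts, isRaw = TRUE, sampleData = NULL,
                     provenance = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  storage.mode(counts) <- if (isRaw) "double" else "double"
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% colnames(sampleData) &&
        is.null(rownames(sampleData)))
      rownames(sampleData) <- sampleData$sample_id
    idx <- match(colnames(counts), rownames(sampleData))
    if (anyNA(idx))
      stop("sampleData is missing samples: ",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
    S4Vectors::DataFrame(sampleData[idx, , drop = FALSE])
  }
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  out <- new("OTUTable", se, isRaw = isRaw)
  S4Vectors::metadata(out)$provenance <- provenance
  validObject(out)
  out
}

#' Case/control label assignment
#'
#' Records a random case/control split of the samples of an [OTUTable-class],
#' together with the case proportion and the seed that produced it, so that
#' identical assignments can be shared across methods within an iteration.
#'
#' @slot sampleIds character vector of sample ids.
#' @slot status factor with levels `control`, `case`, one entry per sample.
#' @slot caseProportion the requested case fraction.
#' @slot seed integer seed used to draw the assignment (NA if constructed
#'   manually).
#' @seealso [assignLabels()]
#' @export
setClass("LabelAssignment",
  representation(sampleIds = "character", status = "factor",
                 caseProportion = "numeric", seed = "integer")
)

.validLabelAssignment <- function(object) {
  msg <- NULL
  if (length(object@status) != length(object@sampleIds))
    msg <- c(msg, "status and sampleIds lengths differ")
  if (!identical(levels(object@status), c("control", "case")))
    msg <- c(msg, "status levels must be c('control','case')")
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicate sample ids")
  tab <- table(object@status)
  if (any(tab == 0L)) msg <- c(msg, "need at least one case and one control")
  if (is.null(msg)) TRUE else msg
}
setValidity("LabelAssignment", .validLabelAssignment)

#' Result of one spike-in
#'
#' Bundle of a spiked [OTUTable-class], the exact truth set (which OTUs were
#' spiked, from which relative-abundance tertile, with which magnitude and
#' scheme), the label assignment used, and the original library sizes (which
#' the spiked table preserves exactly after rescaling to original depth).
#'
#' @slot table the spiked [OTUTable-class].
#' @slot truth `data.frame` with columns `otu_id`, `tertile`, `magnitude`,
#'   `scheme`.
#' @slot labels the [LabelAssignment-class] used.
#' @slot originalLibrarySizes named numeric vector of pre-spike depths.
#' @seealso [spikeMultiplicative()], [spikeAdditive()], [spikeMixed()]
#' @export
setClass("SpikeResult",
  representation(table = "OTUTable", truth = "data.frame",
                 labels = "LabelAssignment",
                 originalLibrarySizes = "numeric")
)

#' Per-OTU result of one differential abundance test
#'
#' @slot method method name.
#' @slot otuIds character vector of OTU ids.
#' @slot p per-OTU p-values in \[0,1\]; OTUs for which the method returned no
#'   p-value are set to 1 (the universal missing-p rule).
#' @slot statistic per-OTU test statistic (NA where undefined).
#' @slot info list of runtime metadata (elapsed seconds, error flag, number
#'   of p-values filled in by the missing-p rule).
#' @seealso [runDAMethod()], [daPermutation()]
#' @export
setClass("DAResult",
  representation(method = "character", otuIds = "character",
                 p = "numeric", statistic = "numeric", info = "list")
)

.validDAResult <- function(object) {
  msg <- NULL
  if (length(object@p) != length(object@otuIds))
    msg <- c(msg, "p and otuIds lengths differ")
  if (length(object@statistic) != length(object@otuIds))
    msg <- c(msg, "statistic and otuIds lengths differ")
  if (anyNA(object@p) || any(object@p < 0 | object@p > 1))
    msg <- c(msg, "p-values must lie in [0,1] with no NA")
  if (is.null(msg)) TRUE else msg
}
setValidity("DAResult", .validDAResult)

#' Configuration for the synthetic OTU-table generator
#'
#' @slot nOtus,nSamples table dimensions.
#' @slot targetSparsity desired overall fraction of zero cells, in (0,1).
#' @slot libSizeLogMean,libSizeLogSd log-normal model of library sizes.
#' @slot tailExponent power-law decay exponent of ranked OTU mean abundances.
#' @slot dispersion gamma-Poisson overdispersion parameter (variance =
#'   mean + dispersion * mean^2).
#' @slot seed integer seed (mandatory).
#' @seealso [synthConfig()], [generateTable()]
#' @export
setClass("SynthConfig",
  representation(nOtus = "integer", nSamples = "integer",
                 targetSparsity = "numeric", libSizeLogMean = "numeric",
                 libSizeLogSd = "numeric", tailExponent = "numeric",
                 dispersion = "numeric", seed = "integer")
)

.validSynthConfig <- function(object) {
  msg <- NULL
  if (object@nOtus < 3L) msg <- c(msg, "nOtus must be >= 3 (tertiles)")
  if (object@nSamples < 4L) msg <- c(msg, "nSamples must be >= 4")
  if (!(object@targetSparsity > 0 && object@targetSparsity < 1))
    msg <- c(msg, "targetSparsity must lie in (0,1)")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@libSizeLogSd < 0) msg <- c(msg, "libSizeLogSd must be >= 0")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (is.null(msg)) TRUE else msg
}
setValidity("SynthConfig", .validSynthConfig)

#' Experiment grid description
#'
#' Declarative description of a benchmarking grid: which datasets, case
#' proportions, iterations, DA methods and (optionally) spike configurations
#' to run. Per-iteration seeds are derived deterministically from
#' `masterSeed`, and within one iteration every method sees the identical
#' label assignment (and, for spike grids, the identical truth set).
#'
#' @slot datasets character vector of dataset names.
#' @slot caseProportions numeric vector of case fractions.
#' @slot nIterations number of repeats per cell.
#' @slot methods character vector of DA method names.
#' @slot spikeConfigs `data.frame` with columns `scheme`, `magnitude`
#'   (NA magnitude for the mixed scheme) or a 0-row frame for FPR grids.
#' @slot masterSeed integer master seed.
#' @seealso [experimentGrid()], [gridSize()], [runFPRExperiment()],
#'   [runSpikeExperiment()]
#' @export
setClass("ExperimentGrid",
  representation(datasets = "character", caseProportions = "numeric",
                 nIterations = "integer", methods = "character",
                 spikeConfigs = "data.frame", masterSeed = "integer")
)

.validExperimentGrid <- function(object) {
  msg <- NULL
  if (any(object@caseProportions <= 0 | object@caseProportions >= 1))
    msg <- c(msg, "caseProportions must lie strictly in (0,1)")
  if (object@nIterations < 0L) msg <- c(msg, "nIterations must be >= 0")
  if (nrow(object@spikeConfigs) &&
      !all(c("scheme", "magnitude") %in% colnames(object@spikeConfigs)))
    msg <- c(msg, "spikeConfigs needs columns scheme, magnitude")
  if (is.null(msg)) TRUE else msg
}
setValidity("ExperimentGrid", .validExperimentGrid)
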