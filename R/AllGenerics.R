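#' @importFrom BiocGenerics counts
NULL

#' Extract the count matrix
#'
#' @param object an [OTUTable-class].
#' @return numeric matrix (OTUs x samples).
#' @export
setMethod("counts", "OTUTable", function(object) {
  assay(object, "counts")
})

#' OTU identifiers
#' @param x an [OTUTable-class].
#' @return character vector.
#' @export
otuIds <- function(x) rownames(x)

#' Sample identifiers
#' @param x an [OTUTable-class] or [LabelAssignment-class].
#' @return character vector.
#' @export
sampleIds <- function(x) {
  if (is(x, "LabelAssignment")) x@sampleIds else colnames(x)
}

#' Is the table raw counts?
#' @param x an [OTUTable-class].
#' @return logical scalar.
#' @export
isRaw <- function(x) x@isRaw

#' Case / control sample ids of a label assignment
#' @param x a [LabelAssignment-class].
#' @return character vector of sample ids.
#' @export
caseIds <- function(x) x@sampleIds[x@status == "case"]

#' @rdname caseIds
#' @export
controlIds <- function(x) x@sampleIds[x@status == "control"]

#' Status vector of a label assignment
#' @param x a [LabelAssignment-class].
#' @return factor with levels `control`, `case`, named by sample id.
#' @export
labelStatus <- function(x) stats::setNames(x@status, x@sampleIds)

#' Truth table of a spike result
#' @param x a [SpikeResult-class].
#' @return `data.frame` with columns `otu_id`, `tertile`, `magnitude`,
#'   `scheme`.
#' @export
spikeTruth <- function(x) x@truth

#' Spiked table of a spike result
#' @param x a [SpikeResult-class].
#' @return the spiked [OTUTable-class].
#' @export
spikedTable <- function(x) x@table

#' P-values of a DA result
#' @param x a [DAResult-class].
#' @return named numeric vector of per-OTU p-values.
#' @export
pValues <- function(x) stats::setNames(x@p, x@otuIds)

setMethod("show", "OTUTable", function(object) {
  m <- assay(object, "counts", withDimnames = FALSE)
  cat(sprintf("OTUTable: %d OTUs x %d samples (%s)\n",
              nrow(m), ncol(m),
              if (object@isRaw) "raw counts" else "normalized/transformed"))
  ls <- colSums(m)
  cat(sprintf("  library sizes: min %.4g / median %.4g / max %.4g\n",
              min(ls), stats::median(ls), max(ls)))
  cat(sprintf("  sparsity: %.3f\n", mean(m == 0)))
})

setMethod("show", "LabelAssignment", function(object) {
  tab <- table(object@status)
  cat(sprintf(
    "LabelAssignment: %d cases / %d controls (proportion %.2f, seed %s)\n",
    tab[["case"]], tab[["control"]], object@caseProportion,
    ifelse(is.na(object@seed), "manual", object@seed)))
})

setMethod("show", "SpikeResult", function(object) {
  cat(sprintf("SpikeResult: %d spiked OTUs (%s scheme)\n",
              nrow(object@truth),
              paste(unique(object@truth$scheme), collapse = "/")))
  print(object@table)
})

setMethod("show", "DAResult", function(object) {
  cat(sprintf("DAResult <%s>: %d OTUs, %d p < 0.05\n",
              object@method, length(object@p), sum(object@p < 0.05)))
})

setMethod("show", "ExperimentGrid", function(object) {
  cat(sprintf(
    "ExperimentGrid: %d dataset(s) x %d proportion(s) x %d iteration(s) x %d method(s)",
    length(object@datasets), length(object@caseProportions),
    object@nIterations, length(object@methods)))
  if (nrow(object@spikeConfigs))
    cat(sprintf(" x %d spike config(s)", nrow(object@spikeConfigs)))
  cat(sprintf("\n  planned runs: %d\n", gridSize(object)))
})
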