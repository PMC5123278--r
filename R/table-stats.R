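#' Per-sample library sizes
#'
#' Library size (sequencing depth) is the sum of counts in each sample, i.e.
#' the column sums of the OTU table.
#'
#' @param x an [OTUTable-class].
#' @return named numeric vector, one entry per sample.
#' @export
librarySizes <- function(x) {
  assertCountTable(x)
  colSums(counts(x))
}

#' Sparsity: fraction of zero cells
#'
#' Real 16S OTU tables typically have 80-95% zero cells; per-OTU sparsity
#' (the share of samples in which an OTU is absent) drives the behaviour of
#' several DA methods.
#'
#' @param x an [OTUTable-class].
#' @param level `"table"` for the overall zero fraction, `"otu"` for one
#'   fraction per OTU.
#' @return numeric scalar (`table`) or named vector (`otu`), values in
#'   \[0, 1\].
#' @export
sparsity <- function(x, level = c("table", "otu")) {
  assertCountTable(x)
  level <- match.arg(level)
  m <- counts(x)
  if (level == "table") mean(m == 0) else rowMeans(m == 0)
}

#' Convert counts to relative abundances (total sum scaling)
#'
#' Divides each sample by its library size so columns sum to one. The result
#' is flagged `isRaw = FALSE`.
#'
#' @param x an [OTUTable-class]; every library size must be > 0.
#' @return An [OTUTable-class] of relative abundances.
#' @export
toRelativeAbundance <- function(x) {
  assertCountTable(x)
  m <- counts(x)
  ls <- colSums(m)
  if (any(ls == 0))
    stop("zero-total sample(s): ",
         paste(colnames(m)[ls == 0], collapse = ", "))
  out <- sweep(m, 2L, ls, "/")
  OTUTable(out, isRaw = FALSE,
           provenance = S4Vectors::metadata(x)$provenance)
}
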