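#' Read an OTU count table from disk
#'
#' Reads the two interchange formats used throughout the package: tab
#' separated text (first column = OTU id, header row = sample ids, integer
#' cells) and dense-JSON BIOM.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"biom"` (dense JSON flavour, parsed with the
#'   biomformat package).
#' @return An [OTUTable-class] with `isRaw = TRUE`; row and column order are
#'   preserved from the file.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(2L, 0L, 0L, 5L, 1L, 1L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' writeCountTable(OTUTable(m), tf)
#' librarySizes(readCountTable(tf))
#' @export
readCountTable <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(OTUTable(m, isRaw = TRUE, provenance = list(source = path)))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate OTU ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop(sprintf("non-numeric or negative count at row '%s', column '%s'",
                   ids[bad[1L]], samples[j]))
    m[, j] <- v
  }
  OTUTable(m, isRaw = all(m == round(m)), provenance = list(source = path))
}

#' Write an OTU count table as TSV
#'
#' @param x an [OTUTable-class].
#' @param path output path.
#' @param idColumn header of the OTU id column (default `"#OTU ID"`).
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path, idColumn = "#OTU ID") {
  assertCountTable(x)
  m <- counts(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with a header; the first column (or a column named `sample_id`) holds
#' sample identifiers.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with rownames set to sample ids.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  idcol <- if ("sample_id" %in% colnames(df)) "sample_id" else colnames(df)[1L]
  if (anyDuplicated(df[[idcol]])) stop("duplicate sample ids in ", path)
  rownames(df) <- df[[idcol]]
  df
}

#' Read a rooted phylogenetic tree in Newick format
#'
#' Thin wrapper over [ape::read.tree()] adding the validity checks required
#' for UniFrac and agglomeration: finite, non-negative branch lengths and
#' unique tip labels. Zero-length branches are allowed (they occur in real
#' inference output); negative lengths are rejected.
#'
#' @param path path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
readNewick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validateTree(tr)
  tr
}

validateTree <- function(tr, otus = NULL) {
  if (!inherits(tr, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!is.null(otus)) {
    missing <- setdiff(otus, tr$tip.label)
    if (length(missing))
      stop("tree is missing tips for OTUs: ",
           paste(utils::head(missing, 10L), collapse = ", "),
           if (length(missing) > 10L) ", ...")
  }
  invisible(tr)
}
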