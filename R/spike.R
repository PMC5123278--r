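#' Randomly assign case/control status
#'
#' Uniform draw of `max(1, round(caseProportion * n))` case samples without
#' replacement; the remainder are controls. Random assignment guarantees the
#' null hypothesis of no true abundance difference.
#'
#' @param x an [OTUTable-class].
#' @param caseProportion case fraction, strictly in (0,1); the study design
#'   used 0.10, 0.25 and 0.50.
#' @param seed integer seed.
#' @return A [LabelAssignment-class]; deterministic given `seed`.
#' @export
assignLabels <- function(x, caseProportion, seed) {
  assertCountTable(x)
  if (!(caseProportion > 0 && caseProportion < 1))
    stop("caseProportion must lie strictly in (0,1)")
  ids <- colnames(x)
  n <- length(ids)
  nCase <- max(1L, as.integer(round(caseProportion * n)))
  if (nCase >= n)
    stop("rounding yields zero controls for caseProportion = ",
         caseProportion)
  cases <- withSeed(seed, sample(ids, nCase))
  status <- factor(ifelse(ids %in% cases, "case", "control"),
                   levels = c("control", "case"))
  new("LabelAssignment", sampleIds = ids, status = status,
      caseProportion = caseProportion, seed = as.integer(seed))
}

# Tertile membership by overall mean relative abundance: 1 = low, 3 = high.
# Ties broken by OTU id (lexicographic); when nOtus %% 3 != 0 the remainder
# goes to the lower tertiles.
otuTertiles <- function(x) {
  m <- counts(x)
  ra <- sweep(m, 2L, colSums(m), "/")
  meanRA <- rowMeans(ra)
  ord <- order(meanRA, rownames(m))  # ascending; ties lexicographic
  n <- nrow(m)
  base <- n %/% 3L
  extra <- n %% 3L
  sizes <- rep(base, 3L) + c(extra >= 1L, extra >= 2L, 0L)
  tert <- integer(n)
  tert[ord] <- rep(1:3, times = sizes)
  stats::setNames(tert, rownames(m))
}

#' Select spike-in target OTUs by relative-abundance tertile
#'
#' OTUs are ranked by overall mean relative abundance and split into three
#' tertiles (low/mid/high); from each tertile, `otusPerTertile` OTUs are
#' drawn uniformly among the eligible ones. Eligibility requires presence
#' (count > 0) in at least one assigned case sample, so a spike can actually
#' take effect.
#'
#' @param x a raw [OTUTable-class].
#' @param labels a [LabelAssignment-class] for `x`.
#' @param otusPerTertile number of OTUs per tertile (default 5).
#' @param seed integer seed.
#' @param mode `"strict"` errors when a tertile has too few eligible OTUs;
#'   `"lenient"` takes all of them and flags the shortfall in
#'   `attr(, "shortfall")`.
#' @return `data.frame` with columns `otu_id`, `tertile`; deterministic
#'   given `seed`.
#' @export
selectSpikeTargets <- function(x, labels, otusPerTertile = 5L, seed,
                               mode = c("strict", "lenient")) {
  assertCountTable(x, raw = TRUE)
  mode <- match.arg(mode)
  status <- matchLabels(x, labels)
  if (otusPerTertile < 1L) stop("otusPerTertile must be >= 1")
  m <- counts(x)
  eligible <- rowSums(m[, status == "case", drop = FALSE] > 0) > 0
  tert <- otuTertiles(x)
  shortfall <- FALSE
  picks <- withSeed(seed, {
    lapply(1:3, function(k) {
      pool <- names(tert)[tert == k & eligible]
      if (length(pool) < otusPerTertile) {
        if (mode == "strict")
          stop(sprintf(
            "tertile %d has only %d eligible OTU(s), %d requested (use mode = 'lenient' to take all)",
            k, length(pool), otusPerTertile))
        shortfall <<- TRUE
        take <- length(pool)
      } else take <- otusPerTertile
      if (take == 0L) character(0) else sample(pool, take)
    })
  })
  out <- data.frame(otu_id = unlist(picks),
                    tertile = rep(1:3, lengths(picks)),
                    stringsAsFactors = FALSE)
  attr(out, "shortfall") <- shortfall
  out
}

#' Rescale a sample to its original sequencing depth
#'
#' Largest-remainder apportionment: counts are scaled proportionally and
#' rounded so the output is integer and sums exactly to `depth`. Zeros map
#' to zeros; remainder ties are broken by OTU index (ascending).
#'
#' @param sampleCounts non-negative numeric vector with positive sum.
#' @param depth target total (positive integer).
#' @return integer-valued numeric vector summing exactly to `depth`.
#' @examples
#' rescaleToDepth(c(4, 0, 10), 7)  # c(2, 0, 5)
#' @export
rescaleToDepth <- function(sampleCounts, depth) {
  s <- sum(sampleCounts)
  if (s <= 0) stop("all-zero sample cannot be rescaled")
  if (depth <= 0) stop("depth must be positive")
  q <- sampleCounts * (depth / s)
  base <- floor(q)
  rem <- as.integer(round(depth - sum(base)))
  if (rem > 0L) {
    frac <- q - base
    bump <- order(-frac, seq_along(q))[seq_len(rem)]
    base[bump] <- base[bump] + 1
  }
  base
}

.spikeResult <- function(x, newCounts, truth, labels, originalLS) {
  tab <- OTUTable(newCounts, isRaw = TRUE,
                  provenance = c(S4Vectors::metadata(x)$provenance,
                                 list(spiked = TRUE)))
  new("SpikeResult", table = tab, truth = truth, labels = labels,
      originalLibrarySizes = originalLS)
}

# Shared core: multiply target rows in case columns by per-OTU magnitudes,
# then rescale every case sample back to its original depth.
.spikeMultCore <- function(x, labels, targets, magnitudes) {
  m <- counts(x)
  status <- matchLabels(x, labels)
  caseCols <- which(status == "case")
  origLS <- colSums(m)
  idx <- match(targets$otu_id, rownames(m))
  if (anyNA(idx)) stop("unknown target OTU id(s)")
  m[idx, caseCols] <- m[idx, caseCols, drop = FALSE] * magnitudes
  for (j in caseCols)
    m[, j] <- rescaleToDepth(m[, j], origLS[j])
  m
}

#' Multiplicative spike-in
#'
#' Counts of the target OTUs in case samples only are multiplied by
#' `magnitude`, after which each case sample is rescaled to its original
#' sequencing depth (largest-remainder rounding), so library sizes are
#' preserved exactly. Control samples are untouched.
#'
#' @param x a raw [OTUTable-class].
#' @param labels a [LabelAssignment-class].
#' @param targets `data.frame` from [selectSpikeTargets()] (columns
#'   `otu_id`, `tertile`).
#' @param magnitude positive multiplier; the study grid used
#'   0.5, 2, 5, 10, 20.
#' @return A [SpikeResult-class] with exact truth tracking.
#' @export
spikeMultiplicative <- function(x, labels, targets, magnitude) {
  assertCountTable(x, raw = TRUE)
  if (magnitude <= 0) stop("magnitude must be > 0")
  m <- .spikeMultCore(x, labels, targets, magnitude)
  truth <- data.frame(otu_id = targets$otu_id, tertile = targets$tertile,
                      magnitude = magnitude, scheme = "multiplicative",
                      stringsAsFactors = FALSE)
  .spikeResult(x, m, truth, labels, colSums(counts(x)))
}

#' Additive spike-in
#'
#' For each target OTU, `m` is its mean relative abundance over the samples
#' where it is non-zero (table-wide). Every non-zero count of that OTU in a
#' case sample `j` is increased by `round(m * magnitude * librarySize(j))`;
#' zero cells stay zero. Case samples are then rescaled to original depth.
#'
#' @inheritParams spikeMultiplicative
#' @param magnitude positive magnitude; the study grid used 0.5, 2, 5, 10.
#' @return A [SpikeResult-class].
#' @export
spikeAdditive <- function(x, labels, targets, magnitude) {
  assertCountTable(x, raw = TRUE)
  if (magnitude <= 0) stop("magnitude must be > 0")
  m <- counts(x)
  status <- matchLabels(x, labels)
  caseCols <- which(status == "case")
  origLS <- colSums(m)
  idx <- match(targets$otu_id, rownames(m))
  if (anyNA(idx)) stop("unknown target OTU id(s)")
  ra <- sweep(m, 2L, origLS, "/")
  for (k in seq_along(idx)) {
    i <- idx[k]
    nz <- m[i, ] > 0
    if (!any(nz)) stop("target OTU is entirely zero: ", targets$otu_id[k])
    mp <- mean(ra[i, nz])
    jj <- caseCols[m[i, caseCols] > 0]
    m[i, jj] <- m[i, jj] + round(mp * magnitude * origLS[jj])
  }
  for (j in caseCols)
    m[, j] <- rescaleToDepth(m[, j], origLS[j])
  truth <- data.frame(otu_id = targets$otu_id, tertile = targets$tertile,
                      magnitude = magnitude, scheme = "additive",
                      stringsAsFactors = FALSE)
  .spikeResult(x, m, truth, labels, origLS)
}

#' Mixed multiplicative spike-in
#'
#' Each target OTU receives one magnitude from `magnitudes`, assigned by a
#' seeded shuffle of the magnitude set followed by cycling, then
#' multiplicative spiking is applied per OTU. The truth set records the
#' per-OTU magnitude.
#'
#' @inheritParams spikeMultiplicative
#' @param magnitudes non-empty vector of positive magnitudes.
#' @param seed integer seed for the magnitude shuffle.
#' @return A [SpikeResult-class].
#' @export
spikeMixed <- function(x, labels, targets, magnitudes, seed) {
  assertCountTable(x, raw = TRUE)
  if (!length(magnitudes)) stop("magnitudes must be non-empty")
  if (any(magnitudes <= 0)) stop("magnitudes must be > 0")
  shuffled <- if (length(magnitudes) == 1L) magnitudes
              else withSeed(seed, sample(magnitudes))
  perOtu <- rep_len(shuffled, nrow(targets))
  m <- .spikeMultCore(x, labels, targets, perOtu)
  truth <- data.frame(otu_id = targets$otu_id, tertile = targets$tertile,
                      magnitude = perOtu, scheme = "mixed",
                      stringsAsFactors = FALSE)
  .spikeResult(x, m, truth, labels, colSums(counts(x)))
}
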