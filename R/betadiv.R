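# Beta-diversity optimization grid: library-size normalizations, count
# transformations, distance metrics and PERMANOVA R^2.
#
# The normalization arithmetic (CSS, TMM, median-of-ratios size factors) is
# implemented here; Bray-Curtis/Euclidean go through vegan, UniFrac through
# phyloseq, PERMANOVA through vegan::adonis2.

#' Median-of-ratios size factors (sparse-data variant)
#'
#' Per-OTU reference = geometric mean over the samples where the OTU is
#' non-zero (the "manually computed geometric means" variant that keeps
#' sparse OTUs usable). The factor of sample j is the median, over OTUs
#' with positive reference and positive count in j, of count/reference --
#' taken on the log scale (geometric interpolation at even counts, the
#' reference convention) -- and the factors are scaled to geometric mean 1.
#'
#' @param x a raw [OTUTable-class].
#' @return named numeric vector of per-sample size factors with geometric
#'   mean 1.
#' @export
deseqSizeFactors <- function(x) {
  assertCountTable(x, raw = TRUE)
  m <- counts(x)
  ref <- apply(m, 1L, function(r) {
    nz <- r > 0
    if (!any(nz)) return(0)
    exp(mean(log(r[nz])))
  })
  f <- vapply(seq_len(ncol(m)), function(j) {
    use <- ref > 0 & m[, j] > 0
    if (!any(use))
      stop("no usable OTUs for size-factor estimation in sample ",
           colnames(m)[j])
    exp(stats::median(log(m[use, j] / ref[use])))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' upper-quartile/library-size ratio is closest to the mean of those
#' ratios; each sample's factor is the inverse-variance-weighted mean of
#' per-OTU log2 ratios (M) against the reference after trimming 30% of the
#' M values and 5% of the absolute-intensity (A) values from each tail,
#' exponentiated and scaled to geometric mean 1.
#'
#' @param x a raw [OTUTable-class].
#' @param logratioTrim,sumTrim trim fractions for M and A.
#' @return named numeric vector of factors with geometric mean 1.
#' @export
tmmFactors <- function(x, logratioTrim = 0.3, sumTrim = 0.05) {
  assertCountTable(x, raw = TRUE)
  m <- counts(x)
  lib <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)),
                function(j) stats::quantile(m[, j], 0.75) / lib[j],
                numeric(1))
  refCol <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    .tmmPair(m[, j], m[, refCol], lib[j], lib[refCol],
             logratioTrim, sumTrim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

.tmmPair <- function(obs, ref, nO, nR, logratioTrim, sumTrim) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR))
    stop("TMM infeasible: no OTUs with positive counts in both sample and reference (extreme sparsity)")
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  if (!any(keep)) stop("TMM infeasible: trimming removed all OTUs")
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Data-driven CSS quantile
#'
#' Chooses the cumulative-sum-scaling quantile from the data, following the
#' published procedure: per quantile level, the median absolute deviation of
#' the samples' non-zero-count quantiles from the mean sorted-count
#' reference profile is computed; the chosen level is the first where the
#' relative change of that deviation exceeds `rel` (instability), floored
#' at 0.5.
#'
#' @param x a raw [OTUTable-class].
#' @param rel relative-instability threshold (reference default 0.1).
#' @return quantile level in \[0.5, 1\].
#' @export
cssQuantile <- function(x, rel = 0.1) {
  assertCountTable(x, raw = TRUE)
  m <- counts(x)
  smat <- apply(m, 2L, sort)
  ref <- rowMeans(smat)
  refS <- sort(ref)
  k <- which(refS > 0)[1L]
  if (is.na(k)) stop("degenerate table: reference profile is all zero")
  lo <- length(refS) - k + 1L
  if (lo < 2L) stop("degenerate table: too few positive reference levels")
  yy <- m
  yy[yy == 0] <- NA
  diffr <- vapply(seq_len(ncol(m)), function(j) {
    refS[k:length(refS)] -
      stats::quantile(yy[, j], probs = seq(0, 1, length.out = lo),
                      na.rm = TRUE)
  }, numeric(lo))
  diffr2 <- apply(abs(diffr), 1L, stats::median, na.rm = TRUE)
  relchg <- abs(diff(diffr2)) / diffr2[-1L]
  xq <- which(relchg > rel)[1L] / length(diffr2)
  if (is.na(xq) || xq <= 0.5) xq <- 0.5
  xq
}

#' Cumulative-sum-scaling factors
#'
#' The factor of sample j is the sum of its counts at or below the l-th
#' quantile of its non-zero counts, divided by a fixed global constant
#' (1000, the reference convention).
#'
#' @param x a raw [OTUTable-class].
#' @param quantile scaling quantile l; `NULL` (default) chooses it from the
#'   data via [cssQuantile()].
#' @param scalingConstant global divisor.
#' @return named numeric vector of per-sample factors; the chosen quantile
#'   is attached as `attr(, "quantile")`.
#' @export
cssFactors <- function(x, quantile = NULL, scalingConstant = 1000) {
  assertCountTable(x, raw = TRUE)
  if (is.null(quantile)) quantile <- cssQuantile(x)
  stopifnot(quantile > 0, quantile <= 1)
  m <- counts(x)
  f <- vapply(seq_len(ncol(m)), function(j) {
    nz <- m[, j][m[, j] > 0]
    if (!length(nz))
      stop("sample has no non-zero counts: ", colnames(m)[j])
    q <- stats::quantile(nz, probs = quantile)
    sum(nz[nz <= q])
  }, numeric(1)) / scalingConstant
  out <- stats::setNames(f, colnames(m))
  attr(out, "quantile") <- quantile
  out
}

#' Library-size normalization
#'
#' @param x a raw [OTUTable-class] with positive library sizes.
#' @param method `"none"` (baseline identity), `"TSS"` (total sum scaling /
#'   relative abundance), `"CSS"`, `"TMM"` or `"DESeq"` (median-of-ratios
#'   size factors). For CSS/TMM/DESeq the counts are divided by per-sample
#'   scaling factors from [cssFactors()], [tmmFactors()] (times library
#'   size) and [deseqSizeFactors()].
#' @param ... passed to the factor functions (e.g. `quantile` for CSS).
#' @return An [OTUTable-class] with `isRaw = FALSE` (identical table for
#'   `"none"`). TMM on extremely sparse tables errors explicitly (no
#'   overlapping non-zero OTUs with the reference sample).
#' @export
normalizeCounts <- function(x, method = c("none", "TSS", "CSS", "TMM",
                                          "DESeq"), ...) {
  assertCountTable(x, raw = TRUE)
  method <- match.arg(method)
  m <- counts(x)
  ls <- colSums(m)
  if (any(ls == 0))
    stop("zero-total sample(s): ", paste(colnames(m)[ls == 0],
                                         collapse = ", "))
  divisor <- switch(method,
    none = return(x),
    TSS = ls,
    CSS = cssFactors(x, ...),
    TMM = tmmFactors(x, ...) * ls,  # effective library sizes
    DESeq = deseqSizeFactors(x))
  out <- sweep(m, 2L, divisor, "/")
  OTUTable(out, isRaw = FALSE,
           provenance = c(S4Vectors::metadata(x)$provenance,
                          list(normalization = method)))
}

#' Count transformation
#'
#' `"log"` applies `log(v + c)` and, for pseudocounts `c < 1`, subtracts
#' `log(c)` from every value so zeros map to zero (for `c = 1`,
#' `log(0 + 1) = 0` already); `"sqrt"` and `"cbrt"` are the square and
#' cubic roots; `"identity"` passes through.
#'
#' @param x an [OTUTable-class] with non-negative values (raw or
#'   normalized).
#' @param method transformation kind.
#' @param pseudocount positive constant for `"log"`; the study grids used
#'   1, 0.01 and 1e-4 (one presentation also quotes 1e-5).
#' @return An [OTUTable-class] with `isRaw = FALSE`.
#' @export
transformCounts <- function(x, method = c("identity", "log", "sqrt",
                                          "cbrt"), pseudocount = 1) {
  assertCountTable(x)
  method <- match.arg(method)
  m <- counts(x)
  out <- switch(method,
    identity = m,
    log = {
      if (pseudocount <= 0) stop("pseudocount must be > 0")
      if (pseudocount < 1) log(m + pseudocount) - log(pseudocount)
      else log(m + pseudocount)
    },
    sqrt = sqrt(m),
    cbrt = m^(1 / 3))
  OTUTable(out, isRaw = FALSE,
           provenance = c(S4Vectors::metadata(x)$provenance,
                          list(transformation = method)))
}

#' Beta-diversity distance matrix
#'
#' @param x an [OTUTable-class] (raw, normalized or transformed;
#'   non-negative values).
#' @param metric `"bray"` (sum |x-y| / sum (x+y)), `"euclidean"`, `"jsd"`
#'   (Jensen-Shannon divergence of the samples' probability profiles,
#'   natural log, no square root), `"unifrac"` (unweighted: unshared branch
#'   length over total spanned branch length) or `"wunifrac"` (weighted,
#'   normalized to \[0,1\]).
#' @param tree rooted [ape::phylo] tree; required for the UniFrac metrics,
#'   tips must cover all OTUs of `x`.
#' @return A `dist` object (symmetric, zero diagonal, non-negative).
#' @export
betaDistance <- function(x, metric = c("bray", "euclidean", "jsd",
                                       "unifrac", "wunifrac"),
                         tree = NULL) {
  assertCountTable(x)
  metric <- match.arg(metric)
  m <- counts(x)
  if (any(m < 0)) stop("negative values are not allowed")
  d <- switch(metric,
    bray = vegan::vegdist(t(m), method = "bray"),
    euclidean = stats::dist(t(m)),
    jsd = .jsdDist(m),
    unifrac = .unifrac(m, tree, weighted = FALSE),
    wunifrac = .unifrac(m, tree, weighted = TRUE))
  stopifnot(all(is.finite(d)), all(d >= -1e-12))
  d
}

# Jensen-Shannon divergence between sample probability profiles;
# 0 * log 0 := 0.
.jsdDist <- function(m) {
  cs <- colSums(m)
  if (any(cs == 0)) stop("zero-total sample(s) cannot form probabilities")
  P <- sweep(m, 2L, cs, "/")
  n <- ncol(P)
  kl <- function(p, q) {
    use <- p > 0
    sum(p[use] * log(p[use] / q[use]))
  }
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      mid <- (P[, i] + P[, j]) / 2
      d[i, j] <- d[j, i] <- 0.5 * kl(P[, i], mid) + 0.5 * kl(P[, j], mid)
    }
  }
  stats::as.dist(d)
}

.unifrac <- function(m, tree, weighted) {
  if (is.null(tree)) stop("a phylogenetic tree is required for UniFrac")
  validateTree(tree, otus = rownames(m))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(m, taxa_are_rows = TRUE),
    phyloseq::phy_tree(ape::keep.tip(tree, rownames(m))))
  phyloseq::UniFrac(ps, weighted = weighted, normalized = TRUE)
}

#' PERMANOVA R-squared and permutation p-value
#'
#' Distance-based permutational multivariate ANOVA (vegan `adonis2`):
#' `R^2 = SS_among / SS_total` from the Gower-centered decomposition, with
#' the pseudo-F permutation p obtained from label shuffles restricted
#' within `strata` when given. R^2 is deterministic given the distance
#' matrix and grouping; only the p-value is Monte-Carlo.
#'
#' @param d a `dist` object.
#' @param groups grouping vector (>= 2 groups).
#' @param strata optional blocking vector restricting permutations.
#' @param nPerm number of permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return list with elements `r_squared`, `p`, `n_perm`.
#' @export
permanovaR2 <- function(d, groups, strata = NULL, nPerm = 999L,
                        seed = NULL) {
  if (!inherits(d, "dist")) stop("d must be a 'dist' object")
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  df <- data.frame(group = groups)
  perm <- permute::how(nperm = nPerm)
  if (!is.null(strata))
    permute::setBlocks(perm) <- factor(strata)
  fit <- withSeed(seed,
                  vegan::adonis2(d ~ group, data = df, permutations = perm))
  list(r_squared = fit$R2[1L], p = fit$`Pr(>F)`[1L],
       n_perm = nPerm)
}

#' Full beta-diversity optimization grid
#'
#' Factorial sweep over normalizations x transformations x distance
#' metrics, each cell scored by PERMANOVA R^2 of the design variable.
#' Normalization-independent metrics (`jsd`, `unifrac`, `wunifrac`) are
#' computed once per transformation (under `none`) and replicated across
#' the normalization rows, flagged `replicated = TRUE`. A failing cell
#' (e.g. TMM infeasible under extreme sparsity) is recorded with
#' `status = "error"`, never dropped silently.
#'
#' @param x a raw [OTUTable-class].
#' @param metadata `data.frame` of per-sample variables (rownames = sample
#'   ids) or `NULL` to use `colData(x)`.
#' @param designVariable column name of the grouping variable.
#' @param normalizations character vector of [normalizeCounts()] methods.
#' @param transformations `data.frame` with columns `method`,
#'   `pseudocount` (NA where unused), or a character vector of methods.
#' @param metrics character vector of [betaDistance()] metrics.
#' @param tree tree for the UniFrac metrics.
#' @param strata optional column name of a blocking variable.
#' @param nPerm,seed passed to [permanovaR2()].
#' @return long-format `data.frame` with one row per grid cell: columns
#'   `normalization`, `transformation`, `pseudocount`, `metric`,
#'   `r_squared`, `p`, `n_perm`, `replicated`, `status`.
#' @export
betaGrid <- function(x, metadata = NULL, designVariable,
                     normalizations = c("none", "TSS", "CSS", "TMM",
                                        "DESeq"),
                     transformations = defaultTransformations(),
                     metrics = c("bray", "euclidean", "jsd", "unifrac",
                                 "wunifrac"),
                     tree = NULL, strata = NULL, nPerm = 999L,
                     seed = NULL) {
  assertCountTable(x, raw = TRUE)
  if (is.null(metadata))
    metadata <- as.data.frame(SummarizedExperiment::colData(x))
  if (!designVariable %in% colnames(metadata))
    stop("design variable not found in metadata: ", designVariable)
  meta <- metadata[colnames(x), , drop = FALSE]
  if (anyNA(meta[[designVariable]]))
    stop("missing values in design variable")
  groups <- meta[[designVariable]]
  strataVec <- if (is.null(strata)) NULL else meta[[strata]]
  if (is.character(transformations))
    transformations <- data.frame(method = transformations,
                                  pseudocount = NA_real_)
  normIndependent <- c("jsd", "unifrac", "wunifrac")
  rows <- list()
  cache <- new.env(parent = emptyenv())
  cellSeed <- 0L
  for (ni in seq_along(normalizations)) {
    norm <- normalizations[ni]
    normTab <- tryCatch(normalizeCounts(x, norm), error = function(e) e)
    for (ti in seq_len(nrow(transformations))) {
      tmeth <- transformations$method[ti]
      pc <- transformations$pseudocount[ti]
      for (metric in metrics) {
        cellSeed <- cellSeed + 1L
        replicated <- metric %in% normIndependent && norm != "none"
        row <- data.frame(normalization = norm, transformation = tmeth,
                          pseudocount = pc, metric = metric,
                          r_squared = NA_real_, p = NA_real_,
                          n_perm = nPerm, replicated = replicated,
                          status = "ok", stringsAsFactors = FALSE)
        key <- paste(tmeth, pc, metric, sep = "|")
        if (replicated && !is.null(cache[[key]])) {
          prev <- cache[[key]]
          row$r_squared <- prev$r_squared
          row$p <- prev$p
          row$status <- prev$status
          rows[[length(rows) + 1L]] <- row
          next
        }
        res <- tryCatch({
          base <- if (metric %in% normIndependent) normalizeCounts(x, "none")
                  else normTab
          if (inherits(base, "error")) stop(conditionMessage(base))
          tt <- if (tmeth == "log")
            transformCounts(base, "log", pseudocount = pc)
          else transformCounts(base, tmeth)
          d <- betaDistance(tt, metric, tree = tree)
          permanovaR2(d, groups, strata = strataVec, nPerm = nPerm,
                      seed = if (is.null(seed)) NULL
                             else deriveSeed(seed, cellSeed))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$status <- paste("error:", conditionMessage(res))
        } else {
          row$r_squared <- res$r_squared
          row$p <- res$p
        }
        if (metric %in% normIndependent)
          cache[[key]] <- list(r_squared = row$r_squared, p = row$p,
                               status = row$status)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Default transformation grid
#'
#' Natural log with pseudocounts 1, 0.01 and 1e-4, square root, cubic root,
#' and the identity baseline.
#'
#' @param pseudocounts pseudocounts for the log rows.
#' @return `data.frame` with columns `method`, `pseudocount`.
#' @export
defaultTransformations <- function(pseudocounts = c(1, 0.01, 1e-4)) {
  rbind(data.frame(method = "identity", pseudocount = NA_real_),
        data.frame(method = "log", pseudocount = pseudocounts),
        data.frame(method = "sqrt", pseudocount = NA_real_),
        data.frame(method = "cbrt", pseudocount = NA_real_))
}

#' Agglomerate phylogenetically close OTUs
#'
#' Computes pairwise cophenetic (tree path) distances between OTUs, takes
#' the given empirical quantile (type 1, an observed distance) of that
#' distance distribution as threshold, forms clusters as connected
#' components of the strictly-under-threshold graph (single-linkage
#' closure; pairs at distance exactly 0 always merge), sums counts within
#' each cluster and names it after the member OTU with the highest total
#' count (ties broken lexicographically) -- the archetype.
#'
#' @param x a raw [OTUTable-class].
#' @param tree rooted [ape::phylo] tree covering all OTUs of `x`.
#' @param quantile distance-distribution quantile in (0,1) used as merge
#'   threshold (reference analysis used 0.001).
#' @return list with elements `table` (the agglomerated
#'   [OTUTable-class]) and `map` (`data.frame` with columns `otu_id`,
#'   `archetype`).
#' @export
agglomerateOtus <- function(x, tree, quantile = 0.001) {
  assertCountTable(x, raw = TRUE)
  if (!(quantile > 0 && quantile < 1))
    stop("quantile must lie strictly in (0,1)")
  validateTree(tree, otus = rownames(x))
  sub <- ape::keep.tip(tree, rownames(x))
  cd <- ape::cophenetic.phylo(sub)[rownames(x), rownames(x)]
  dvals <- cd[lower.tri(cd)]
  thr <- stats::quantile(dvals, probs = quantile, type = 1)
  # single-linkage closure: connected components of the strictly-below-
  # threshold graph; exact-zero pairs always merge
  n <- nrow(cd)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  pairs <- which((cd < thr | cd == 0) & upper.tri(cd), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  m <- counts(x)
  tot <- rowSums(m)
  groups <- split(seq_len(n), comp)
  arch <- vapply(groups, function(idx) {
    ids <- rownames(m)[idx]
    ids[order(-tot[idx], ids)][1L]
  }, character(1))
  newM <- do.call(rbind, lapply(groups, function(idx)
    colSums(m[idx, , drop = FALSE])))
  rownames(newM) <- arch
  map <- data.frame(otu_id = rownames(m),
                    archetype = arch[match(comp, as.integer(names(groups)))],
                    stringsAsFactors = FALSE)
  list(table = OTUTable(newM, isRaw = TRUE,
                        provenance = c(S4Vectors::metadata(x)$provenance,
                                       list(agglomerated = TRUE,
                                            quantile = quantile))),
       map = map)
}
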