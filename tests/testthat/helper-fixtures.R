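# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles deliberately use naive loops, independent of the package's
# implementation paths.

toyTable <- function() {
  m <- matrix(c(2, 0,
                0, 5,
                1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
  OTUTable(m)
}

# Random raw table with controllable sparsity, dimnames OTU%d / s%d.
randomTable <- function(nOtu, nSamp, seed, maxCount = 50, zeroProp = 0.3) {
  set.seed(seed)
  m <- matrix(rpois(nOtu * nSamp, lambda = maxCount / 5), nOtu, nSamp)
  m[matrix(runif(nOtu * nSamp) < zeroProp, nOtu, nSamp)] <- 0
  # keep every column non-empty
  for (j in seq_len(nSamp)) if (sum(m[, j]) == 0) m[1, j] <- 1
  dimnames(m) <- list(paste0("OTU", seq_len(nOtu)),
                      paste0("s", seq_len(nSamp)))
  OTUTable(m)
}

manualLabels <- function(sampleIds, caseIds, proportion = 0.5) {
  status <- factor(ifelse(sampleIds %in% caseIds, "case", "control"),
                   levels = c("control", "case"))
  new("LabelAssignment", sampleIds = sampleIds, status = status,
      caseProportion = proportion, seed = NA_integer_)
}

# Brute-force AUC by explicit pair counting (ties = 1/2).
oracleAUC <- function(p, truth) {
  sp <- p[truth]; ns <- p[!truth]
  tot <- 0
  for (a in sp) for (b in ns)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(ns))
}

# Brute-force permutation test: enumerate every case subset of the given
# size, statistic log(mean case / mean control)^2 on relative abundances.
oraclePermTest <- function(m, caseCols) {
  ra <- sweep(m, 2, colSums(m), "/")
  n <- ncol(m)
  k <- length(caseCols)
  stat <- function(cs) {
    mc <- mean(ra[1, cs]); mn <- mean(ra[1, setdiff(seq_len(n), cs)])
    if (mc == 0 && mn == 0) return(0)
    signif(log(mc / mn)^2, 10)  # same tie-snapping convention
  }
  obs <- stat(caseCols)
  splits <- combn(n, k, simplify = FALSE)
  mean(vapply(splits, function(cs) stat(cs) >= obs, logical(1)))
}

# Brute-force PERMANOVA R^2 from the sum-of-squares decomposition:
# SS_total = sum_{i<j} d_ij^2 / n; SS_within = sum over groups of
# within-group pair d^2 / group size; R^2 = 1 - SS_within / SS_total.
oracleR2 <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  sst <- sum(dm[lower.tri(dm)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  1 - ssw / sst
}

# Independent re-implementation of the additive spike formula, without the
# package's vectorized path: for each target, m = mean relative abundance
# over its non-zero samples; each non-zero case cell gains
# round(m * magnitude * librarySize).
oracleAdditive <- function(m, caseCols, targetRows, magnitude) {
  ls <- colSums(m)
  out <- m
  for (i in targetRows) {
    nzAll <- which(m[i, ] > 0)
    mp <- mean(m[i, nzAll] / ls[nzAll])
    for (j in caseCols) {
      if (m[i, j] > 0)
        out[i, j] <- m[i, j] + round(mp * magnitude * ls[j])
    }
  }
  out
}

# Largest-remainder rescaling oracle (naive).
oracleRescale <- function(x, depth) {
  q <- x * depth / sum(x)
  base <- floor(q)
  rem <- depth - sum(base)
  frac <- q - base
  ord <- order(-frac, seq_along(x))
  if (rem > 0) base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  base
}
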