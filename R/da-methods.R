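# Built-in differential relative abundance tests and the method registry.
#
# The classical tests run through the standard R machinery (stats::t.test,
# stats::wilcox.test, MASS::glm.nb) exactly as a practitioner would invoke
# them; the permutation test is implemented here in full. All methods obey
# the universal missing-p rule: an OTU for which a method returns no p-value
# gets p = 1.

.daResult <- function(method, otuIds, p, statistic = NULL, info = list()) {
  filled <- sum(is.na(p) | is.nan(p))
  p[is.na(p) | is.nan(p)] <- 1
  p <- pmin(pmax(p, 0), 1)
  if (is.null(statistic)) statistic <- rep(NA_real_, length(otuIds))
  info$nFilled <- filled
  new("DAResult", method = method, otuIds = otuIds, p = as.numeric(p),
      statistic = as.numeric(statistic), info = info)
}

.splitGroups <- function(x, labels, values) {
  status <- matchLabels(x, labels)
  list(case = which(status == "case"), control = which(status == "control"))
}

#' Welch t test on relative abundances
#'
#' Counts are transformed to relative abundances, then each OTU is compared
#' between cases and controls with the two-sided Welch t test
#' (Satterthwaite degrees of freedom). Degenerate OTUs (constant data,
#' all-zero) fall back to p = 1 via the missing-p rule.
#'
#' @param x a raw or relative-abundance [OTUTable-class].
#' @param labels a [LabelAssignment-class].
#' @return A [DAResult-class]; `statistic` holds the t statistic.
#' @export
daTTest <- function(x, labels) {
  assertCountTable(x)
  v <- counts(if (isRaw(x)) toRelativeAbundance(x) else x)
  .tTestCore(v, x, labels, "t")
}

#' Log t test
#'
#' As [daTTest()], but each cell is log-transformed first with a pseudocount
#' (default 1) on the count scale: the Welch t test is applied to
#' `log(count + pseudocount)` directly, without re-scaling to relative
#' abundances afterwards.
#'
#' @inheritParams daTTest
#' @param pseudocount positive constant added before the log.
#' @return A [DAResult-class].
#' @export
daLogTTest <- function(x, labels, pseudocount = 1) {
  assertCountTable(x)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  v <- log(counts(x) + pseudocount)
  .tTestCore(v, x, labels, "log_t")
}

.tTestCore <- function(v, x, labels, name) {
  g <- .splitGroups(x, labels)
  n <- nrow(v)
  p <- rep(NA_real_, n)
  stat <- rep(NA_real_, n)
  if (length(g$case) >= 2L && length(g$control) >= 2L) {
    for (i in seq_len(n)) {
      res <- tryCatch(stats::t.test(v[i, g$case], v[i, g$control]),
                      error = function(e) NULL)
      if (!is.null(res)) {
        p[i] <- res$p.value
        stat[i] <- unname(res$statistic)
      }
    }
  }
  .daResult(name, rownames(v), p, stat)
}

#' Wilcoxon rank-sum test on relative abundances
#'
#' Two-sided Mann-Whitney/Wilcoxon test via [stats::wilcox.test()] with its
#' default behaviour: exact distribution for small tie-free groups,
#' tie-corrected normal approximation otherwise. With heavily tied sparse
#' data the attainable p-values are bounded away from 0, which limits the
#' maximum power of this test.
#'
#' @inheritParams daTTest
#' @return A [DAResult-class]; `statistic` holds the rank-sum statistic W.
#' @export
daWilcoxon <- function(x, labels) {
  assertCountTable(x)
  v <- counts(if (isRaw(x)) toRelativeAbundance(x) else x)
  g <- .splitGroups(x, labels)
  n <- nrow(v)
  p <- rep(NA_real_, n)
  stat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      suppressWarnings(stats::wilcox.test(v[i, g$case], v[i, g$control])),
      error = function(e) NULL)
    if (!is.null(res)) {
      p[i] <- res$p.value
      stat[i] <- unname(res$statistic)
    }
  }
  .daResult("wilcoxon", rownames(v), p, stat)
}

#' Negative binomial GLM with library-size offset
#'
#' Per OTU, fits `count ~ status` with `MASS::glm.nb` using
#' `offset(log(librarySize))`, i.e. mean model
#' `log mu = b0 + b1 * I(case) + log(librarySize)`; per-OTU dispersion is
#' estimated by maximum likelihood. The two-sided Wald p-value on `b1` is
#' reported; non-convergence or an all-zero OTU yields p = 1.
#'
#' @inheritParams daTTest
#' @param x a raw [OTUTable-class] (the model is defined on counts).
#' @return A [DAResult-class]; `statistic` holds the estimated log fold
#'   change `b1` (natural log), so `exp(statistic)` is the fold-change
#'   estimate.
#' @export
daNbGlm <- function(x, labels) {
  assertCountTable(x, raw = TRUE)
  m <- counts(x)
  status <- matchLabels(x, labels)
  grp <- factor(status, levels = c("control", "case"))
  offs <- log(colSums(m))
  n <- nrow(m)
  p <- rep(NA_real_, n)
  stat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- m[i, ]
    if (all(y == 0)) next
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ grp + offset(offs))),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    if (is.null(co) || !"grpcase" %in% rownames(co)) next
    p[i] <- co["grpcase", "Pr(>|z|)"]
    stat[i] <- co["grpcase", "Estimate"]
  }
  .daResult("nb_glm", rownames(m), p, stat)
}

#' Permutation test with statistic log(mean cases / mean controls)^2
#'
#' On relative abundances, the per-OTU statistic is
#' `S = log(mean in cases / mean in controls)^2`. Its null distribution is
#' estimated from `nPerm` random case/control re-assignments (the same
#' permutations are reused across all OTUs), and
#' `p = #\{S_perm >= S_obs\} / nPerm` -- no +1 smoothing, so p = 0 is
#' attainable. If exactly one group mean is zero, `S = +Inf` (ranked above
#' every finite value); if both are zero, `S = 0`. The statistic is
#' symmetric in the group labels since `log(x)^2 = log(1/x)^2`.
#'
#' @inheritParams daTTest
#' @param nPerm number of permutations (the reference protocol used 1e4).
#' @param seed integer seed for the permutation stream.
#' @param exact if `TRUE`, enumerate all distinct case subsets of the given
#'   size instead of sampling (feasible only for small designs); `nPerm`
#'   and `seed` are then ignored.
#' @return A [DAResult-class]; `statistic` holds S.
#' @export
daPermutation <- function(x, labels, nPerm = 10000L, seed = NULL,
                          exact = FALSE) {
  assertCountTable(x)
  ra <- counts(if (isRaw(x)) toRelativeAbundance(x) else x)
  status <- matchLabels(x, labels)
  n <- ncol(ra)
  nCase <- sum(status == "case")
  # snap to 10 significant digits so mathematically tied statistics (e.g.
  # the observed split and its complement) compare as equal regardless of
  # summation order
  sFromMeans <- function(mc, mn) {
    s <- signif(log(mc / mn)^2, 10)
    s[mc == 0 & mn == 0] <- 0
    s
  }
  obs <- sFromMeans(rowMeans(ra[, status == "case", drop = FALSE]),
                    rowMeans(ra[, status == "control", drop = FALSE]))
  if (exact) {
    sets <- utils::combn(n, nCase)
    P <- ncol(sets)
    caseInd <- matrix(0, n, P)
    caseInd[cbind(as.vector(sets),
                  rep(seq_len(P), each = nCase))] <- 1
  } else {
    P <- as.integer(nPerm)
    if (P < 1L) stop("nPerm must be >= 1")
    # draw permutations over the id-sorted sample order so the stream is
    # tied to sample ids, not column positions
    ord <- order(colnames(ra))
    caseInd <- withSeed(seed, {
      vapply(seq_len(P), function(k) {
        ind <- numeric(n)
        ind[sample.int(n, nCase)] <- 1
        ind
      }, numeric(n))
    })
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    caseInd <- caseInd[pos, , drop = FALSE]
  }
  mc <- (ra %*% caseInd) / nCase
  mn <- (ra %*% (1 - caseInd)) / (n - nCase)
  sPerm <- sFromMeans(mc, mn)
  p <- rowMeans(sPerm >= obs)
  .daResult("permutation", rownames(ra), p, obs,
            info = list(nPerm = ncol(caseInd), exact = exact))
}
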