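#' Create a synthetic-generator configuration
#'
#' Defaults describe a "large" 16S survey: 1000 OTUs x 100 samples, target
#' sparsity 0.85 (the middle of the 80-95% range typical of real OTU
#' tables), log-normal library sizes spanning more than an order of
#' magnitude, power-law ranked OTU abundances and gamma-Poisson
#' overdispersion.
#'
#' @param nOtus,nSamples table dimensions.
#' @param targetSparsity desired overall zero fraction, in (0,1).
#' @param libSizeLogMean,libSizeLogSd mean and sd of log library size.
#' @param tailExponent power-law exponent of the ranked OTU mean abundances
#'   (mean of OTU with rank r is proportional to r^-tailExponent).
#' @param dispersion gamma-Poisson dispersion phi (variance =
#'   mean + phi * mean^2).
#' @param seed mandatory integer seed.
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(nOtus = 1000L, nSamples = 100L,
                        targetSparsity = 0.85,
                        libSizeLogMean = 10, libSizeLogSd = 1,
                        tailExponent = 1, dispersion = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("SynthConfig", nOtus = as.integer(nOtus),
      nSamples = as.integer(nSamples), targetSparsity = targetSparsity,
      libSizeLogMean = libSizeLogMean, libSizeLogSd = libSizeLogSd,
      tailExponent = tailExponent, dispersion = dispersion,
      seed = as.integer(seed))
}

#' Generate a synthetic OTU count table
#'
#' Gamma-Poisson (negative binomial) counts with power-law OTU means and
#' log-normal library-size factors. For OTU i (rank r_i) in sample j the
#' expected count is `mu_ij = c * r_i^-tail * L_j` with `L_j` log-normal; a
#' single global scale `c` is solved numerically so the expected zero
#' fraction `mean (1 + phi mu)^(-1/phi)` matches `targetSparsity`. Sparsity
#' thus arises from small means plus overdispersion, with no explicit
#' zero-inflation knob.
#'
#' @param cfg a [SynthConfig-class].
#' @return A raw [OTUTable-class]; deterministic given `cfg@seed`, with the
#'   configuration recorded in its provenance.
#' @examples
#' ot <- generateTable(synthConfig(nOtus = 50, nSamples = 10, seed = 1))
#' sparsity(ot)
#' @export
generateTable <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  withSeed(cfg@seed, {
    a <- seq_len(cfg@nOtus)^(-cfg@tailExponent)
    a <- a / sum(a)
    L <- exp(stats::rnorm(cfg@nSamples, cfg@libSizeLogMean,
                          cfg@libSizeLogSd))
    phi <- cfg@dispersion
    # expected zero fraction as a function of the global scale (log scale
    # search keeps the bracket wide)
    ezero <- function(logc) {
      mu <- exp(logc) * outer(a, L)
      mean((1 + phi * mu)^(-1 / phi))
    }
    f <- function(logc) ezero(logc) - cfg@targetSparsity
    lo <- -40; hi <- 40
    if (f(lo) < 0 || f(hi) > 0)
      stop("infeasible configuration: cannot reach target sparsity ",
           cfg@targetSparsity, " with this table shape")
    logc <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
    mu <- exp(logc) * outer(a, L)
    if (mean(colSums(mu)) < 1)
      stop("infeasible configuration: target sparsity ",
           cfg@targetSparsity,
           " implies essentially empty samples for this table shape")
    m <- matrix(stats::rnbinom(length(mu), size = 1 / phi, mu = mu),
                nrow = cfg@nOtus,
                dimnames = list(sprintf("OTU%04d", seq_len(cfg@nOtus)),
                                sprintf("sample%03d", seq_len(cfg@nSamples))))
    OTUTable(m, isRaw = TRUE,
             provenance = list(generator = "gamma-poisson",
                               seed = cfg@seed,
                               config = list(nOtus = cfg@nOtus,
                                             nSamples = cfg@nSamples,
                                             targetSparsity = cfg@targetSparsity,
                                             libSizeLogMean = cfg@libSizeLogMean,
                                             libSizeLogSd = cfg@libSizeLogSd,
                                             tailExponent = cfg@tailExponent,
                                             dispersion = cfg@dispersion)))
  })
}

#' Permute every OTU independently across samples
#'
#' Builds a null dataset that retains the biological marginal distribution
#' of every OTU (mean, variance, sparsity are exactly preserved) while
#' breaking within-sample structure: each row is resampled across samples
#' without replacement, rows independently. One seed drives a per-OTU
#' stream.
#'
#' @param x a raw [OTUTable-class].
#' @param seed integer seed.
#' @return A raw [OTUTable-class] of the same dimensions.
#' @export
permuteWithinOtus <- function(x, seed) {
  assertCountTable(x, raw = TRUE)
  m <- counts(x)
  withSeed(seed, {
    for (i in seq_len(nrow(m)))
      m[i, ] <- m[i, sample.int(ncol(m))]
  })
  OTUTable(m, isRaw = TRUE,
           provenance = c(S4Vectors::metadata(x)$provenance,
                          list(withinOtuPermutationSeed = as.integer(seed))))
}

#' Randomly subset samples
#'
#' Selects `n` distinct samples uniformly without replacement. All-zero OTU
#' rows are retained unless `dropEmpty = TRUE`, so OTU ids remain comparable
#' across subsets. The seed is recorded in the output provenance.
#'
#' @param x an [OTUTable-class].
#' @param n number of samples to keep (2 <= n <= ncol).
#' @param seed integer seed.
#' @param dropEmpty drop OTUs with all-zero rows after subsetting.
#' @return An [OTUTable-class] with `n` samples.
#' @export
subsetSamples <- function(x, n, seed, dropEmpty = FALSE) {
  assertCountTable(x)
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (n > ncol(x)) stop("n exceeds the number of samples")
  keep <- withSeed(seed, sample(colnames(x), n))
  m <- counts(x)[, keep, drop = FALSE]
  if (dropEmpty) m <- m[rowSums(m) > 0, , drop = FALSE]
  OTUTable(m, isRaw = isRaw(x),
           provenance = c(S4Vectors::metadata(x)$provenance,
                          list(subsetSeed = as.integer(seed),
                               subsetN = n)))
}
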