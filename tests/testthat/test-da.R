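# Helper: two-OTU table where row 1 carries the signal and row 2 fills each
# column to a constant depth, so relative abundances of row 1 are counts/depth.
signalTable <- function(values, depth = 100) {
  stopifnot(all(values <= depth))
  m <- rbind(sig = values, fill = depth - values)
  colnames(m) <- paste0("s", seq_along(values))
  OTUTable(m)
}

test_that("Welch t test: identical groups give p = 1, separation gives small p", {
  ot <- signalTable(c(10, 20, 30, 10, 20, 30))
  la <- manualLabels(sampleIds(ot), paste0("s", 1:3))
  res <- daTTest(ot, la)
  expect_equal(unname(pValues(res)["sig"]), 1)  # constant difference -> t.test errors -> missing rule
  ot2 <- signalTable(c(1, 2, 3, 10, 11, 12))
  res2 <- daTTest(ot2, la)
  expect_lt(pValues(res2)[["sig"]], 0.01)
  # cross-check against a direct Welch computation on relative abundances
  ref <- t.test(c(1, 2, 3) / 100, c(10, 11, 12) / 100)
  expect_equal(pValues(res2)[["sig"]], ref$p.value)
  # all-zero OTU -> p = 1
  m <- rbind(zero = rep(0, 6), fill = rep(50, 6))
  colnames(m) <- paste0("s", 1:6)
  res3 <- daTTest(OTUTable(m), la)
  expect_equal(unname(pValues(res3)["zero"]), 1)
})

test_that("log t test operates on log(count + 1) and can flip group order", {
  ot <- signalTable(c(30, 0, 0, 3, 3, 3))
  la <- manualLabels(sampleIds(ot), paste0("s", 1:3))
  raw <- daTTest(ot, la)
  lg <- daLogTTest(ot, la)
  # raw case mean (0.1) above control (0.03); log scale reverses the order
  expect_gt(raw@statistic[1], 0)
  expect_lt(lg@statistic[1], 0)
  # matches a direct t test on log(count + 1)
  ref <- t.test(log(c(30, 0, 0) + 1), log(c(3, 3, 3) + 1))
  expect_equal(pValues(lg)[["sig"]], ref$p.value)
  # identical groups -> p = 1
  same <- signalTable(c(5, 7, 9, 5, 7, 9))
  expect_equal(unname(pValues(daLogTTest(same, la))["sig"]), 1)
  expect_error(daLogTTest(ot, la, pseudocount = 0), "pseudocount")
})

test_that("Wilcoxon: exact small-sample p and tie-limited power", {
  ot <- signalTable(c(1, 2, 3, 4, 5, 6))
  la <- manualLabels(sampleIds(ot), paste0("s", 1:3))
  res <- daWilcoxon(ot, la)
  # most extreme ranking of 3 vs 3: two-sided exact p = 2 * 1/20 = 0.1
  expect_equal(pValues(res)[["sig"]], 0.1)
  # all-tied OTU -> p = 1 via the missing rule
  same <- signalTable(rep(4, 6))
  expect_equal(unname(pValues(daWilcoxon(same, la))["sig"]), 1)
  # 18 zeros in 10 vs 10: even the most extreme arrangement cannot reach
  # p < 0.05 (ties bound the attainable power)
  vals <- c(7, 9, rep(0, 18))
  ot2 <- signalTable(vals, depth = 50)
  la2 <- manualLabels(sampleIds(ot2), paste0("s", 1:10))
  p <- pValues(daWilcoxon(ot2, la2))[["sig"]]
  expect_gt(p, 0.05)
})

test_that("NB GLM: offset absorbs depth and the Wald test is calibrated", {
  set.seed(41)
  # depth-confounded null: cases sequenced twice as deep, counts scale with
  # depth -> the log-library-size offset must absorb the difference
  n <- 30
  depth <- c(rep(1000, n / 2), rep(2000, n / 2))
  lam <- 0.02
  m <- rbind(sig = rnbinom(n, mu = lam * depth, size = 2),
             fill = round(depth * 0.98))
  colnames(m) <- paste0("s", 1:n)
  ot <- OTUTable(m)
  la <- manualLabels(colnames(m), paste0("s", (n / 2 + 1):n))
  res <- daNbGlm(ot, la)
  expect_lt(abs(res@statistic[1]), log(1.5))  # |b1| well below the log(2) depth effect
  expect_gt(pValues(res)[["sig"]], 0.05)
  # all-zero OTU -> p = 1
  m0 <- rbind(zero = rep(0, n), fill = rep(10, n))
  colnames(m0) <- paste0("s", 1:n)
  expect_equal(unname(pValues(daNbGlm(OTUTable(m0), la))["zero"]), 1)
})

test_that("permutation test equals the brute-force oracle on exhaustive splits", {
  set.seed(17)
  for (k in 1:5) {
    m <- rbind(sig = rpois(6, 5) * rbinom(6, 1, 0.8),
               fill = rpois(6, 30) + 10)
    colnames(m) <- paste0("s", 1:6)
    ot <- OTUTable(m)
    cs <- sort(sample(6, 3))
    la <- manualLabels(colnames(m), paste0("s", cs))
    got <- daPermutation(ot, la, exact = TRUE)
    expect_equal(pValues(got)[["sig"]], oraclePermTest(m, cs))
  }
})

test_that("permutation statistic: equal means give p = 1, labels symmetric", {
  ot <- signalTable(c(5, 10, 15, 15, 10, 5))
  la <- manualLabels(sampleIds(ot), paste0("s", 1:3))
  res <- daPermutation(ot, la, exact = TRUE)
  expect_equal(res@statistic[1], 0)     # log(1)^2
  expect_equal(pValues(res)[["sig"]], 1)  # every permuted S >= 0
  # swapping case/control leaves S unchanged
  la2 <- manualLabels(sampleIds(ot), paste0("s", 4:6))
  res2 <- daPermutation(ot, la2, exact = TRUE)
  expect_equal(res2@statistic, res@statistic)
  # all-zero OTU -> S = 0, p = 1
  m <- rbind(zero = rep(0, 6), fill = rep(9, 6))
  colnames(m) <- paste0("s", 1:6)
  r0 <- daPermutation(OTUTable(m), la, exact = TRUE)
  expect_equal(unname(pValues(r0)["zero"]), 1)
  # deterministic given seed in sampled mode
  ot3 <- randomTable(10, 12, seed = 3)
  la3 <- assignLabels(ot3, 0.5, seed = 1)
  a <- daPermutation(ot3, la3, nPerm = 200, seed = 5)
  b <- daPermutation(ot3, la3, nPerm = 200, seed = 5)
  expect_identical(a@p, b@p)
})

test_that("built-in methods are invariant to row and column order", {
  ot <- randomTable(15, 10, seed = 23)
  la <- assignLabels(ot, 0.5, seed = 2)
  m <- counts(ot)
  shuf <- OTUTable(m[sample(nrow(m)), sample(ncol(m))])
  for (f in list(daTTest, daWilcoxon,
                 function(x, l) daPermutation(x, l, exact = TRUE),
                 function(x, l) daPermutation(x, l, nPerm = 300,
                                              seed = 9))) {
    a <- f(ot, la)
    b <- f(shuf, la)
    expect_equal(pValues(a)[otuIds(ot)], pValues(b)[otuIds(ot)])
  }
})

test_that("registry: dispatch, missing-p fill, plugins, errors", {
  ot <- randomTable(10, 8, seed = 29)
  la <- assignLabels(ot, 0.5, seed = 3)
  res <- runDAMethod("wilcoxon", ot, la)
  expect_length(pValues(res), 10)
  expect_true(all(res@p >= 0 & res@p <= 1))
  expect_error(runDAMethod("no_such_method", ot, la), "unknown DA method")
  expect_setequal(daMethods()$name,
                  c("t", "log_t", "wilcoxon", "nb_glm", "permutation"))
  # in-process plugin returning p for 8 of 10 OTUs: missing ones get p = 1
  registerDAMethod("partial", fun = function(x, labels, ...) {
    data.frame(otu_id = rownames(x)[1:8], p = rep(0.2, 8))
  })
  on.exit(unregisterDAMethod("partial"), add = TRUE)
  pr <- runDAMethod("partial", ot, la)
  expect_equal(sum(pr@p == 1), 2)
  expect_equal(sum(pr@p == 0.2), 8)
  # duplicate registration rejected; builtins protected
  expect_error(registerDAMethod("wilcoxon", fun = identity), "already")
  expect_error(unregisterDAMethod("wilcoxon"), "builtin")
  # failing plugin yields all p = 1 with an error flag, not a crash
  registerDAMethod("broken", fun = function(x, labels, ...) stop("boom"))
  on.exit(unregisterDAMethod("broken"), add = TRUE)
  br <- runDAMethod("broken", ot, la)
  expect_true(all(br@p == 1))
  expect_match(br@info$error, "boom")
})

test_that("subprocess plugin exchanges TSV files per the contract", {
  skip_on_os("windows")
  plugin <- tempfile(fileext = ".R")
  writeLines(c(
    "args <- commandArgs(trailingOnly = TRUE)",
    "tab <- read.table(args[1], header = TRUE, sep = '\t', comment.char = '')",
    "out <- data.frame(otu_id = tab[[1]], p = 0.25)",
    "write.table(out, args[3], sep = '\t', quote = FALSE, row.names = FALSE)"
  ), plugin)
  registerDAMethod("external", command = c("Rscript", plugin))
  on.exit(unregisterDAMethod("external"), add = TRUE)
  ot <- randomTable(6, 6, seed = 31)
  la <- assignLabels(ot, 0.5, seed = 1)
  res <- runDAMethod("external", ot, la)
  expect_true(all(res@p == 0.25))
  # subprocess failure -> all p = 1 plus error flag
  registerDAMethod("externalBad", command = c("Rscript", "-e", "q(status=1);"))
  on.exit(unregisterDAMethod("externalBad"), add = TRUE)
  bad <- runDAMethod("externalBad", ot, la)
  expect_true(all(bad@p == 1))
  expect_match(bad@info$error, "plugin")
})
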