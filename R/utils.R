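# Internal helpers: local seed scoping and deterministic seed derivation.

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber a user's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Counter-based derivation of per-run seeds from a master seed: a small
# multiplicative hash keeps every derived seed a valid 32-bit R integer and
# makes runs reproducible without global RNG state.
deriveSeed <- function(masterSeed, counter) {
  s <- (as.double(masterSeed) * 48271 + as.double(counter) * 16807) %%
    2147483647
  as.integer(s) + 1L
}

assertCountTable <- function(x, raw = FALSE, arg = "x") {
  if (!is(x, "OTUTable"))
    stop(arg, " must be an OTUTable", call. = FALSE)
  if (raw && !isRaw(x))
    stop(arg, " must hold raw counts (isRaw = TRUE)", call. = FALSE)
  invisible(x)
}

matchLabels <- function(x, labels) {
  if (!is(labels, "LabelAssignment"))
    stop("labels must be a LabelAssignment", call. = FALSE)
  if (!setequal(labels@sampleIds, colnames(x)))
    stop("label sample ids do not match the table's samples", call. = FALSE)
  stats::setNames(labels@status, labels@sampleIds)[colnames(x)]
}
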