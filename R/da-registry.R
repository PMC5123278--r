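# Method registry: built-ins plus user-registered plugins. External tools
# (DESeq2, edgeR, baySeq, metagenomeSeq, ALDEx2, ...) are reached through
# the plugin contract, never reimplemented here.

.daRegistry <- new.env(parent = emptyenv())

.registerBuiltins <- function() {
  builtin <- function(name, scale, fun)
    assign(name, list(name = name, inputScale = scale, fun = fun,
                      isBuiltin = TRUE), envir = .daRegistry)
  builtin("t", "relative", function(x, labels, ...) daTTest(x, labels))
  builtin("log_t", "log_relative",
          function(x, labels, ...) daLogTTest(x, labels, ...))
  builtin("wilcoxon", "relative",
          function(x, labels, ...) daWilcoxon(x, labels))
  builtin("nb_glm", "raw", function(x, labels, ...) daNbGlm(x, labels))
  builtin("permutation", "relative",
          function(x, labels, ...) daPermutation(x, labels, ...))
}

.onLoad <- function(libname, pkgname) {
  .registerBuiltins()
}

#' List registered DA methods
#'
#' @return `data.frame` with columns `name`, `input_scale`, `builtin`.
#' @export
daMethods <- function() {
  specs <- mget(ls(.daRegistry), envir = .daRegistry)
  data.frame(name = vapply(specs, `[[`, "", "name"),
             input_scale = vapply(specs, `[[`, "", "inputScale"),
             builtin = vapply(specs, `[[`, TRUE, "isBuiltin"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Register an external DA method
#'
#' Two plugin flavours are supported. An in-process plugin supplies `fun`, a
#' function `(x, labels, ...)` returning either a [DAResult-class] or a
#' `data.frame` with columns `otu_id` and `p`. A subprocess plugin supplies
#' `command`: the command is invoked as
#' `command <counts.tsv> <labels.tsv> <out.tsv>` with the count table and a
#' two-column label table (`sample_id`, `status`) written to temporary TSV
#' files, and must write a two-column TSV (`otu_id`, `p`) to the output
#' path. OTUs the plugin omits get p = 1; a failing subprocess yields a
#' result with all p = 1 and `info$error` set (never a silent drop).
#'
#' @param name unique method name.
#' @param fun optional R function (see above).
#' @param command optional command line (character vector: program then
#'   fixed arguments).
#' @param inputScale declared input scale, one of `"raw"`, `"relative"`,
#'   `"log_relative"` (informational; the raw table is always handed over).
#' @return `name`, invisibly.
#' @export
registerDAMethod <- function(name, fun = NULL, command = NULL,
                             inputScale = "raw") {
  if (exists(name, envir = .daRegistry))
    stop("method name already registered: ", name)
  if (is.null(fun) == is.null(command))
    stop("supply exactly one of fun or command")
  if (!is.null(command)) {
    cmd <- command
    fun <- function(x, labels, ...) .runCommandPlugin(name, cmd, x, labels)
  }
  assign(name, list(name = name, inputScale = inputScale, fun = fun,
                    isBuiltin = FALSE), envir = .daRegistry)
  invisible(name)
}

#' @rdname registerDAMethod
#' @export
unregisterDAMethod <- function(name) {
  if (exists(name, envir = .daRegistry)) {
    spec <- get(name, envir = .daRegistry)
    if (isTRUE(spec$isBuiltin)) stop("cannot unregister a builtin method")
    rm(list = name, envir = .daRegistry)
  }
  invisible(name)
}

.runCommandPlugin <- function(name, command, x, labels) {
  dir <- tempfile("daplugin")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  tf <- file.path(dir, "counts.tsv")
  lf <- file.path(dir, "labels.tsv")
  of <- file.path(dir, "out.tsv")
  writeCountTable(x, tf)
  utils::write.table(
    data.frame(sample_id = labels@sampleIds,
               status = as.character(labels@status)),
    lf, sep = "\t", quote = FALSE, row.names = FALSE)
  code <- tryCatch(
    system2(command[1L], c(command[-1L], tf, lf, of),
            stdout = FALSE, stderr = FALSE),
    error = function(e) -1L)
  if (!identical(as.integer(code), 0L) || !file.exists(of))
    return(.daResult(name, rownames(x), rep(NA_real_, nrow(x)),
                     info = list(error = "plugin subprocess failed")))
  out <- utils::read.table(of, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  p <- rep(NA_real_, nrow(x))
  idx <- match(out[[1L]], rownames(x))
  p[idx[!is.na(idx)]] <- as.numeric(out[[2L]])[!is.na(idx)]
  .daResult(name, rownames(x), p)
}

#' Run a registered DA method
#'
#' Dispatches by name, converts to the method's declared input scale where
#' needed (handled inside the built-ins), fills every missing/NaN p-value
#' with 1 and records the elapsed runtime in `info$elapsed`.
#'
#' @param method registered method name (see [daMethods()]).
#' @param x a raw [OTUTable-class].
#' @param labels a [LabelAssignment-class].
#' @param ... passed through to the method (e.g. `nPerm`, `seed` for the
#'   permutation test).
#' @return A [DAResult-class].
#' @export
runDAMethod <- function(method, x, labels, ...) {
  if (!exists(method, envir = .daRegistry))
    stop("unknown DA method: ", method, " (see daMethods())")
  spec <- get(method, envir = .daRegistry)
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(spec$fun(x, labels, ...), error = function(e) {
    .daResult(method, rownames(x), rep(NA_real_, nrow(x)),
              info = list(error = conditionMessage(e)))
  })
  if (is.data.frame(res)) {
    p <- rep(NA_real_, nrow(x))
    idx <- match(res$otu_id, rownames(x))
    p[idx[!is.na(idx)]] <- res$p[!is.na(idx)]
    res <- .daResult(method, rownames(x), p)
  }
  if (!is(res, "DAResult")) stop("method returned neither DAResult nor data.frame")
  res@method <- method
  res@info$elapsed <- proc.time()[["elapsed"]] - t0
  res
}
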