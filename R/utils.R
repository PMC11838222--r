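#' @keywords internal
#' @useDynLib pathwaycnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Internal helpers shared across modules: seeded RNG scoping, seed
## derivation, and lightweight logging.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves `.Random.seed`, seeds the Mersenne-Twister generator with `seed`,
#' evaluates `expr`, and restores the previous RNG state on exit, so that
#' package internals never disturb the caller's random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Derive a stream of child seeds from one master seed
#'
#' SplitMix-style integer mixing so that each pipeline stage draws from an
#' independent, reproducible stream.  All arithmetic is done in double
#' precision modulo 2^31 - 1 so results are identical across platforms and
#' always fit a 32-bit R integer.
#'
#' @param seed master seed (non-negative integer).
#' @param stream stage name (character) or stream index.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  if (is.character(stream)) {
    ## polynomial rolling hash: collision-free in practice for the short
    ## stage names and indexed streams used across the package
    h <- 0
    for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
    stream <- h
  }
  z <- (as.numeric(seed) %% m + 1)
  z <- (z * 48271) %% m          # Lehmer step
  z <- (z + as.numeric(stream) * 2246822519) %% m
  z <- (z * 69621) %% m          # second multiplicative mix
  z <- (z + 362437) %% m
  as.integer(z)
}

#' @keywords internal
pcn_log <- function(..., verbose = getOption("pathwaycnn.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[pathwaycnn] ", ...)
  invisible(NULL)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash an R object via its canonical serialization
#'
#' Used to stamp run outputs with a configuration fingerprint.  The object is
#' serialized (version 2, platform-independent) to a temporary file and
#' digested with MD5.
#'
#' @param x any serializable R object.
#' @return a 32-character hex string.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
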