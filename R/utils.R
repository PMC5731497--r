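#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rnorm
#' @importFrom utils read.table write.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package functions never leak global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Uppercase, U->T, and validate a DNA string against the ACGT alphabet
# (ambiguity codes handled by the caller's policy).
normalize_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("sequence must be a single character string")
  if (nchar(seq) == 0L) stop("empty sequence")
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
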