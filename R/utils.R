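#' Derive a reproducible child seed from a master seed
#'
#' Stochastic stages that need several independent random streams (dilution
#' replicates, per-lambda sweeps, per-passage traces) derive one child seed
#' per stream from a single master seed so that any stream can be re-run in
#' isolation. The derivation is a single MINSTD congruential step,
#' `(48271 * seed + index) mod (2^31 - 1)`, which keeps every derived seed a
#' valid 32-bit integer.
#'
#' @param seed Master seed (non-negative integer).
#' @param index Stream index (non-negative integer).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647
  as.integer((48271 * (as.numeric(seed) %% m) + as.numeric(index)) %% m)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[b]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
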