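# Internal helpers shared across modules.

#' Derive a stage-specific random seed from a single run seed
#'
#' All randomness in the package is routed through one user-facing seed; each
#' pipeline stage draws its own substream seed from it so that stages can be
#' re-run independently and still reproduce the full pipeline byte for byte.
#' The derivation is a fixed multiplicative congruential step modulo the
#' Mersenne prime 2^31 - 1, so derived seeds always fit a 32-bit integer.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name (e.g. "cohort", "reads", "qpcr").
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  # fold the stage name into an offset; all arithmetic stays below 2^53
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(seed) %% m)
  s <- (s * 16807 + offs) %% m
  s <- (s * 16807 + 1) %% m
  as.integer(if (s == 0) 1 else s)
}

# run code with a local RNG state derived from `seed`, restoring the caller's
# stream afterwards (so library calls never perturb user simulations)
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between equal-length strings (vectorised over x)
hamming <- function(x, y) {
  stopifnot(all(nchar(x) == nchar(y)))
  xs <- strsplit(x, "", fixed = TRUE)
  ys <- strsplit(y, "", fixed = TRUE)
  mapply(function(a, b) sum(a != b), xs, ys, USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)
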