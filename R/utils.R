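# Shared low-level helpers: Phred conversions, seeded RNG, input checks.

PHRED_OFFSET <- 33L

#' Convert a Phred quality string to integer scores
#'
#' @param qual A character vector of Phred+33 encoded quality strings.
#' @return A list of integer vectors, one per input string.
#' @examples
#' phred_from_string("II!")
#' @export
phred_from_string <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q) || q == "*") return(integer(0))
    utf8ToInt(q) - PHRED_OFFSET
  })
}

#' Convert integer Phred scores to a quality string
#'
#' @param phred Integer vector of Phred scores (0-93).
#' @return A single quality string (Phred+33).
#' @export
phred_to_string <- function(phred) {
  stopifnot(all(phred >= 0), all(phred <= 93))
  intToUtf8(as.integer(phred) + PHRED_OFFSET)
}

#' Phred score to error probability
#' @param q Numeric vector of Phred scores.
#' @return Error probabilities `10^(-q/10)`.
#' @export
phred_to_error <- function(q) 10^(-q / 10)

#' Error probability to Phred score
#' @param p Numeric vector of error probabilities.
#' @return Phred scores `-10 log10(p)`.
#' @export
error_to_phred <- function(p) -10 * log10(p)

# Deterministically derive a sub-seed from a base seed and one or more keys.
# Kept below 2^31 so it is always a valid R integer. Plain modular hashing on
# doubles (exact below 2^53).
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in c(...)) {
    kv <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    h <- (h * 48271 + kv) %% m
  }
  as.integer(h)
}

# Run code with a local, restored RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# Coordinate conventions used throughout:
#  * regions (BED-style) are 0-based half-open [start, end)
#  * alignment, pileup and VCF positions are 1-based
# Conversion happens only at read/write boundaries and is marked where done.
region_width <- function(regions) regions$end - regions$start
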