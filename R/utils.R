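# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes and the concrete bases each one matches
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Derive a child RNG seed from a master seed
#'
#' All randomness in the package flows from one user-supplied seed; each
#' stage (reference generation, cohort sampling, read simulation,
#' permutation null) derives its own child seed with this documented
#' splitting scheme, so stages can be re-run independently yet
#' reproducibly.
#'
#' @param seed master seed (integer).
#' @param key integer stream key; distinct keys give distinct streams.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(1, 1)
#' split_seed(1, 2)
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(key))
  # affine hash kept within exact double-precision integer range
  as.integer(((abs(seed) %% 100003) * 20011 + (key %% 100003) * 7919 + 13) %%
               2147483647)
}

.stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# coerce a sequence argument (character or Biostrings object) to a plain
# uppercase character string
.as_seq_string <- function(x, arg = "sequence") {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L) {
    .stop_format("'%s' must be a single character string or DNAString", arg)
  }
  toupper(x)
}

# split a sequence string into a raw vector for fast per-base comparison
.seq_raw <- function(s) charToRaw(s)

# number of leading positions at which two equal-length raw vectors agree
.match_prefix_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

.check_prob <- function(p, arg) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    .stop_format("'%s' must be probabilities in [0, 1]", arg)
  }
  invisible(p)
}

# random DNA string of length n under the current RNG state
.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

.is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
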