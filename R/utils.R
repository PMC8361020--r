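# Internal helpers shared across modules.

# Symmetric (edge-repeating) reflection of out-of-range indices into 1..n.
# Used by every sliding-window filter so that boundary voxels see a full
# neighborhood.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period
  ifelse(j < n, j + 1L, period - j)
}

# Run code with a local RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so generators are pure functions of
# their arguments.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    stop("a deterministic seed is required", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split a nucleotide string into its codons (length must be divisible by 3).
codon_split <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
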