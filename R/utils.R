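# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulators never perturb the session stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a user seed; stays well below 2^31.
derive_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000003L) * 1000L + as.integer(k) %% 1000L
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc_fraction = 0.5) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

is_dna <- function(x, allow_n = TRUE) {
  pattern <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  grepl(pattern, x)
}

revcomp <- function(x) {
  x <- as.character(x)
  if (length(x) == 0) return(character(0))
  if (length(x) > 50L) {
    return(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
  }
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Substitute base at 0-based position `pos` (scalar).
sub_base <- function(seq, pos, alt) {
  substr(seq, pos + 1L, pos + 1L) <- alt
  seq
}

# Random base different from `base`.
other_base <- function(base) {
  sample(setdiff(DNA_BASES, base), 1L)
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance requires equal lengths")
  sum(charToRaw(a) != charToRaw(b))
}

# Extract the plain sequence string from an amplicon design list or string.
amp_seq <- function(amplicon) {
  s <- if (is.list(amplicon)) amplicon$sequence else amplicon
  s <- toupper(as.character(s))
  if (length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop("amplicon must be a single non-empty DNA sequence")
  }
  if (!is_dna(s)) stop("amplicon contains non-DNA characters")
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
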