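# Shared fixtures and independent oracles, all built in code.

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# A fixed 250-nt design used by most read-level tests.
fixture_design <- function(seed = 1L, length = 250L) {
  make_amplicon(length, 0.5, seed = seed)
}

# Delete `len` template bases starting at 0-based `start`.
delete_at <- function(seq, start, len) {
  paste0(substr(seq, 1L, start), substr(seq, start + len + 1L, nchar(seq)))
}

# Substitute the base at 0-based `pos` with a different fixed base.
substitute_at <- function(seq, pos) {
  ref_base <- substr(seq, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  substr(seq, pos + 1L, pos + 1L) <- alt
  seq
}

# The hand-enumerated 10-read case: 3 reads with a 2-nt cut-site deletion,
# 2 with a substitution at cut - 8, 5 exact.
hand_read_case <- function(design) {
  cs <- cut_site(design$guide, design)
  del_read <- delete_at(design$sequence, cs - 1L, 2L)
  sub_read <- substitute_at(design$sequence, cs - 8L)
  c(rep(del_read, 3), rep(sub_read, 2), rep(design$sequence, 5))
}

# Independent Spearman oracle: counting ranks + hand Pearson on ranks.
brute_spearman <- function(x, y) {
  brute_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- brute_rank(x)
  ry <- brute_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Biostrings global alignment score with the package's gap convention
# (gap of length L costs 6 + (L - 1), i.e. gapOpening 5 + gapExtension 1*L).
oracle_align_score <- function(read, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(read, ref, substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 1,
                                      type = "global")
  Biostrings::score(pa)
}

# Random read derived from a reference by a few substitutions and indels.
mutate_read <- function(ref, n_sub = 2L, p_del = 0.5, p_ins = 0.3) {
  read <- ref
  for (k in seq_len(n_sub)) {
    p <- sample(nchar(read), 1)
    substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
  }
  if (runif(1) < p_del && nchar(read) > 6L) {
    s <- sample(nchar(read) - 4L, 1)
    l <- sample(1:4, 1)
    read <- paste0(substr(read, 1, s), substr(read, s + l + 1, nchar(read)))
  }
  if (runif(1) < p_ins) {
    s <- sample(nchar(read), 1)
    read <- paste0(substr(read, 1, s),
                   paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = ""),
                   substr(read, s + 1, nchar(read)))
  }
  read
}

# Exhaustive both-strand scan of a genome for a flank with <= max_mm
# substitutions (the map_flank oracle).
brute_scan <- function(flank, genome, max_mm) {
  L <- nchar(flank)
  glen <- nchar(genome)
  rc <- dualwindow:::revcomp(genome)
  hits <- data.frame(start = integer(0), strand = character(0))
  for (s in 0:(glen - L)) {
    if (dualwindow:::hamming(substr(genome, s + 1, s + L), flank) <= max_mm) {
      hits <- rbind(hits, data.frame(start = s, strand = "+"))
    }
    if (dualwindow:::hamming(substr(rc, s + 1, s + L), flank) <= max_mm) {
      hits <- rbind(hits, data.frame(start = glen - s - L, strand = "-"))
    }
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}
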