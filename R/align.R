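#' Alignment scoring parameters
#'
#' Defaults keep NHEJ alleles alignable while rejecting unrelated sequence:
#' match +2, mismatch -1, gap open -6 (including the first gapped base), gap
#' extend -1, and a 60% identity floor below which a read is discarded as
#' unalignable.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring terms.
#' @param identity_floor Minimum fraction of identical alignment columns.
#' @return A list of scoring parameters.
#' @export
default_scoring <- function(match = 2, mismatch = -1, gap_open = 6,
                            gap_extend = 1, identity_floor = 0.6) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, identity_floor = identity_floor)
}

# Parse an alignment (gapped read/ref strings) into modification events with
# 0-based reference coordinates. Insertions are anchored at inter-base
# positions; deletions/substitutions carry reference intervals/positions.
alignment_events <- function(aligned_read, aligned_ref) {
  r <- strsplit(aligned_read, "", fixed = TRUE)[[1]]
  f <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  n <- length(r)
  events <- list()
  refpos <- 0L
  i <- 1L
  while (i <= n) {
    if (f[i] == "-") {
      j <- i
      while (j <= n && f[j] == "-") j <- j + 1L
      events[[length(events) + 1L]] <- list(
        kind = "insertion", ref_start = refpos, ref_length = 0L,
        alt = paste(r[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (r[i] == "-") {
      j <- i
      while (j <= n && r[j] == "-" && f[j] != "-") j <- j + 1L
      len <- j - i
      events[[length(events) + 1L]] <- list(
        kind = "deletion", ref_start = refpos, ref_length = len, alt = "")
      refpos <- refpos + len
      i <- j
    } else {
      if (r[i] != f[i]) {
        events[[length(events) + 1L]] <- list(
          kind = "substitution", ref_start = refpos, ref_length = 1L,
          alt = r[i], ref = f[i])
      }
      refpos <- refpos + 1L
      i <- i + 1L
    }
  }
  events
}

# Shift indels to their leftmost score-equivalent placement so that window
# overlap tests are deterministic under placement ambiguity.
left_normalize_events <- function(events, ref) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  lapply(events, function(ev) {
    if (ev$kind == "deletion") {
      s <- ev$ref_start
      L <- ev$ref_length
      while (s > 0L && rc[s] == rc[s + L]) s <- s - 1L
      ev$ref_start <- s
    } else if (ev$kind == "insertion") {
      p <- ev$ref_start
      a <- strsplit(ev$alt, "", fixed = TRUE)[[1]]
      L <- length(a)
      while (p > 0L && rc[p] == a[L]) {
        a <- c(rc[p], a[-L])
        p <- p - 1L
      }
      ev$ref_start <- p
      ev$alt <- paste(a, collapse = "")
    }
    ev
  })
}

#' Globally align one read to the reference amplicon
#'
#' Needleman-Wunsch alignment with affine gap penalties (Gotoh algorithm,
#' compiled); indels are then shifted to their leftmost score-equivalent
#' placement. Reads whose fraction of identical alignment columns falls
#' below `scoring$identity_floor` are flagged as discarded.
#'
#' @param read DNA string.
#' @param amplicon Reference amplicon (string or design list).
#' @param scoring See [default_scoring()].
#' @return An object of class `amplicon_alignment` with fields `score`,
#'   `identity`, `discarded`, `aligned_read`, `aligned_ref`, `events` and
#'   `ref`.
#' @export
align_read <- function(read, amplicon, scoring = default_scoring()) {
  ref <- amp_seq(amplicon)
  read <- toupper(as.character(read))
  if (length(read) != 1L || !nzchar(read)) stop("read must be a non-empty string")
  if (!is_dna(read)) stop("read contains non-DNA characters")
  if (read == ref) {
    aln <- list(score = scoring$match * nchar(ref),
                aligned_read = read, aligned_ref = ref)
    events <- list()
    identity <- 1
  } else {
    aln <- .nw_align_cpp(read, ref, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
    r <- charToRaw(aln$aligned_read)
    f <- charToRaw(aln$aligned_ref)
    identity <- sum(r == f) / length(r)
    events <- left_normalize_events(
      alignment_events(aln$aligned_read, aln$aligned_ref), ref)
  }
  structure(list(read = read, ref = ref, score = aln$score,
                 identity = identity,
                 discarded = identity < scoring$identity_floor,
                 aligned_read = aln$aligned_read,
                 aligned_ref = aln$aligned_ref,
                 events = events),
            class = "amplicon_alignment")
}

# Align a read set against the amplicon, collapsing identical reads first.
# Returns a list with unique sequences, their multiplicities, and one
# alignment per unique sequence.
align_read_set <- function(reads, amplicon, scoring = default_scoring()) {
  reads <- as.character(reads)
  if (length(reads) == 0L) stop("empty read set")
  u <- unique(reads)
  count <- tabulate(match(reads, u), nbins = length(u))
  alignments <- lapply(u, align_read, amplicon = amplicon, scoring = scoring)
  list(seq = u, count = count, alignments = alignments,
       discarded = vapply(alignments, `[[`, logical(1), "discarded"),
       n_reads = length(reads))
}

# Does any event modify the window [lo, hi)? Substitutions involving N are
# not counted as modifications.
events_modify_window <- function(events, lo, hi) {
  for (ev in events) {
    hit <- switch(ev$kind,
      insertion = ev$ref_start > lo && ev$ref_start < hi,
      deletion = ev$ref_start < hi && (ev$ref_start + ev$ref_length) > lo,
      substitution = ev$ref_start >= lo && ev$ref_start < hi &&
        ev$alt != "N" && (ev$ref %||% "") != "N")
    if (isTRUE(hit)) return(TRUE)
  }
  FALSE
}

#' Classify an aligned read against a quantification window
#'
#' A read is modified iff it has an insertion anchored strictly inside the
#' window interval, a deletion whose reference interval overlaps the window,
#' or a substitution at a position inside the window. Events outside the
#' window never set the flag; substitutions involving N are ignored.
#'
#' @param alignment An [align_read()] result (not discarded).
#' @param window A [quant_window()].
#' @return Logical: is the read modified in the window?
#' @export
classify_read <- function(alignment, window) {
  if (!inherits(alignment, "amplicon_alignment")) {
    stop("alignment must come from align_read()")
  }
  if (alignment$discarded) stop("cannot classify a discarded alignment")
  b <- window_bounds(window, nchar(alignment$ref))
  events_modify_window(alignment$events, b[["lo"]], b[["hi"]])
}
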