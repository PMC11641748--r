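# Scenario specification for the amplicon read simulator.

#' Default NHEJ indel spectrum
#'
#' 80% deletions with lengths 1-10 drawn from a truncated geometric
#' (p = 0.5), 20% insertions with lengths 1-3 uniform; every indel's
#' reference interval (or anchor) covers the cut site.
#'
#' @param p_deletion Probability an edit is a deletion.
#' @param deletion_max Maximum deletion length (nt).
#' @param deletion_geom_p Geometric parameter for deletion lengths.
#' @param insertion_lengths Candidate insertion lengths (uniform).
#' @return A list describing the spectrum.
#' @export
default_indel_spectrum <- function(p_deletion = 0.8, deletion_max = 10L,
                                   deletion_geom_p = 0.5,
                                   insertion_lengths = 1:3) {
  list(p_deletion = p_deletion, deletion_max = as.integer(deletion_max),
       deletion_geom_p = deletion_geom_p,
       insertion_lengths = as.integer(insertion_lengths))
}

#' Simulation scenario for one amplicon sample
#'
#' Describes the mixture structure of a sample: the true Cas9-edited read
#' fraction, SNP carriers near (but not at) the cut site, an optional
#' divergent homologous allele (substitution-only), optional co-amplified
#' paralog sequences, and uniform substitution sequencing error.
#'
#' @param edit_fraction True edited read fraction `e` in `[0, 1]`.
#' @param n_reads Number of reads to simulate.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed; same seed, same reads.
#' @param indel_spectrum See [default_indel_spectrum()].
#' @param snps `NULL` or a data.frame with columns `offset` (nt from the cut
#'   site; the two narrow-window positions -1 and 0 are excluded), `alt`
#'   (substituted base) and `freq` (carrier frequency in `[0, 1]`).
#' @param homolog `NULL` or a list with `freq` in `[0, 1]` and either
#'   `substitutions` (data.frame `offset`, `alt`) applied to the reference
#'   or a full `sequence`.
#' @param paralogs `NULL` or a list of lists with `weight` and `sequence`
#'   (full alternative amplicon).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(edit_fraction = 0, n_reads = 1000L,
                          error_rate = 0.001, seed = 1L,
                          indel_spectrum = default_indel_spectrum(),
                          snps = NULL, homolog = NULL, paralogs = NULL) {
  if (edit_fraction < 0 || edit_fraction > 1) stop("edit_fraction must be in [0, 1]")
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be positive")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (!is.null(snps)) {
    stopifnot(is.data.frame(snps),
              all(c("offset", "alt", "freq") %in% names(snps)))
    if (any(snps$freq < 0 | snps$freq > 1)) stop("SNP carrier frequencies must be in [0, 1]")
    if (any(snps$offset %in% c(-1L, 0L))) {
      warning("SNP offsets -1/0 fall inside the 2-nt window; the SNP scenario assumes offsets outside it")
    }
  }
  hf <- 0
  if (!is.null(homolog)) {
    hf <- homolog$freq
    if (is.null(hf) || hf < 0 || hf > 1) stop("homolog frequency must be in [0, 1]")
    if (is.null(homolog$sequence) && is.null(homolog$substitutions)) {
      stop("homolog needs either a sequence or a substitutions table")
    }
  }
  pw <- 0
  if (!is.null(paralogs)) {
    pw <- sum(vapply(paralogs, function(p) p$weight, numeric(1)))
    if (any(vapply(paralogs, function(p) p$weight, numeric(1)) < 0)) {
      stop("paralog weights must be non-negative")
    }
  }
  if (hf + pw > 1) stop("homolog frequency + paralog weights exceed 1")
  structure(list(edit_fraction = edit_fraction, n_reads = n_reads,
                 error_rate = error_rate, seed = as.integer(seed),
                 indel_spectrum = indel_spectrum, snps = snps,
                 homolog = homolog, paralogs = paralogs),
            class = "scenario_spec")
}

# Apply substitutions/deletion/insertion (0-based ref coords) to a sequence;
# used to derive homolog/paralog templates.
apply_variants <- function(seq, subs = NULL, deletion = NULL, insertion = NULL) {
  if (!is.null(subs)) {
    for (i in seq_len(nrow(subs))) {
      seq <- sub_base(seq, subs$pos[i], subs$alt[i])
    }
  }
  if (!is.null(deletion)) { # c(start, length)
    s <- deletion[1]; L <- deletion[2]
    seq <- paste0(substr(seq, 1L, s), substr(seq, s + L + 1L, nchar(seq)))
  }
  if (!is.null(insertion)) { # list(pos = inter-base, alt = bases)
    p <- insertion$pos
    seq <- paste0(substr(seq, 1L, p), insertion$alt,
                  substr(seq, p + 1L, nchar(seq)))
  }
  seq
}

# Draw one NHEJ indel at the cut site. Returns list(kind, start, length, alt)
# in 0-based template coordinates. Placements are chosen so that the
# left-normalized (canonical leftmost) representation of the indel still
# covers the cut: a deletion start is picked where no further left shift is
# possible (the base before the gap differs from the last deleted base) and
# an insertion's final base is drawn to differ from the base 5' of the
# anchor. Without this, indels planted at the cut inside repeated context
# would canonicalize away from the narrow window and the simulated editing
# rate would not be recoverable.
sample_indel <- function(spectrum, cut, seq) {
  seq_length <- nchar(seq)
  base_at <- function(pos0) substr(seq, pos0 + 1L, pos0 + 1L) # 0-based
  if (runif(1) < spectrum$p_deletion) {
    len <- 0L
    while (len < 1L || len > spectrum$deletion_max) {
      len <- rgeom(1, spectrum$deletion_geom_p) + 1L
    }
    for (L in len:(len + 5L)) {
      lo <- max(0L, cut - L)
      hi <- min(cut, seq_length - L)
      if (lo > hi) next
      cand <- lo:hi
      stable <- vapply(cand, function(s) {
        s == 0L || base_at(s - 1L) != base_at(s + L - 1L)
      }, logical(1))
      cand <- cand[stable]
      if (length(cand) > 0L) {
        centered <- cut - ceiling(L / 2)
        start <- cand[which.min(abs(cand - centered))]
        return(list(kind = "deletion", start = as.integer(start),
                    length = as.integer(L), alt = ""))
      }
    }
    # repeated context everywhere around the cut; accept a centered placement
    start <- max(0L, min(cut - ceiling(len / 2), seq_length - len))
    list(kind = "deletion", start = as.integer(start),
         length = as.integer(len), alt = "")
  } else {
    len <- sample(spectrum$insertion_lengths, 1L)
    anchor <- min(cut, seq_length)
    alt <- sample(DNA_BASES, len, replace = TRUE)
    if (anchor > 0L) {
      alt[len] <- sample(setdiff(DNA_BASES, base_at(anchor - 1L)), 1L)
    }
    list(kind = "insertion", start = as.integer(anchor), length = len,
         alt = paste(alt, collapse = ""))
  }
}
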