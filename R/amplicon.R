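#' Guide specification
#'
#' Describes an SpCas9 guide relative to a reference amplicon: the 20-nt
#' protospacer, its NGG PAM, the strand it sits on and its 0-based start
#' coordinate on the amplicon (always given in plus-strand amplicon
#' coordinates, also for minus-strand guides). `cut_offset` is the blunt cut
#' position in nucleotides from the protospacer 5' end; the default 17
#' corresponds to the canonical SpCas9 cut 3 bp upstream of the PAM.
#'
#' @param protospacer 20-nt DNA string (guide orientation).
#' @param pam 3-nt DNA string matching NGG (guide orientation).
#' @param strand `"+"` or `"-"` relative to the amplicon.
#' @param protospacer_start 0-based start of the protospacer region on the
#'   amplicon (plus-strand coordinates).
#' @param cut_offset integer in (0, 20); nucleotides from the protospacer
#'   5' end to the blunt cut.
#' @return An object of class `guide_spec`.
#' @export
guide_spec <- function(protospacer, pam, strand = "+", protospacer_start,
                       cut_offset = 17L) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) != 20L || !is_dna(protospacer, allow_n = FALSE)) {
    stop("protospacer must be a 20-nt ACGT string")
  }
  if (!grepl("^[ACGT]GG$", pam)) stop("PAM must match NGG")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  protospacer_start <- as.integer(protospacer_start)
  cut_offset <- as.integer(cut_offset)
  if (protospacer_start < 0L) stop("protospacer_start must be >= 0")
  if (cut_offset <= 0L || cut_offset >= 20L) {
    stop("cut_offset must lie strictly between 0 and 20")
  }
  structure(list(protospacer = protospacer, pam = pam, strand = strand,
                 protospacer_start = protospacer_start,
                 cut_offset = cut_offset),
            class = "guide_spec")
}

#' Validate a guide against its amplicon
#'
#' Requires an exact protospacer + PAM match at the stated position and
#' strand. For minus-strand guides the amplicon segment
#' `[protospacer_start, protospacer_start + 20)` must equal the reverse
#' complement of the protospacer and the PAM segment lies immediately 5' of
#' it in amplicon coordinates.
#'
#' @param guide A [guide_spec()].
#' @param amplicon Amplicon sequence (string or design list).
#' @return Invisibly `TRUE`; errors name the first mismatching segment.
#' @export
validate_guide <- function(guide, amplicon) {
  seq <- amp_seq(amplicon)
  s <- guide$protospacer_start
  len <- nchar(seq)
  if (guide$strand == "+") {
    if (s + 23L > len) stop("guide (protospacer + PAM) extends past amplicon end")
    found <- substr(seq, s + 1L, s + 20L)
    if (found != guide$protospacer) {
      stop(sprintf("protospacer mismatch at %d (+): amplicon has %s, guide has %s",
                   s, found, guide$protospacer))
    }
    pam_found <- substr(seq, s + 21L, s + 23L)
    if (substr(pam_found, 2L, 3L) != "GG" || pam_found != guide$pam) {
      stop(sprintf("PAM mismatch at %d (+): amplicon has %s, guide has %s",
                   s + 20L, pam_found, guide$pam))
    }
  } else {
    if (s - 3L < 0L || s + 20L > len) {
      stop("guide (protospacer + PAM) extends past amplicon end")
    }
    found <- revcomp(substr(seq, s + 1L, s + 20L))
    if (found != guide$protospacer) {
      stop(sprintf("protospacer mismatch at %d (-): amplicon has %s, guide has %s",
                   s, found, guide$protospacer))
    }
    pam_found <- revcomp(substr(seq, s - 2L, s))
    if (pam_found != guide$pam) {
      stop(sprintf("PAM mismatch at %d (-): amplicon has %s, guide has %s",
                   s - 3L, pam_found, guide$pam))
    }
  }
  invisible(TRUE)
}

#' Predicted Cas9 cut site
#'
#' Returns the blunt cut position as a 0-based inter-base coordinate on the
#' amplicon. For a plus-strand guide this is `protospacer_start +
#' cut_offset`; for a minus-strand guide the arithmetic mirrors to
#' `protospacer_start + (20 - cut_offset)`.
#'
#' @inheritParams validate_guide
#' @return Integer inter-base coordinate.
#' @export
cut_site <- function(guide, amplicon) {
  validate_guide(guide, amplicon)
  if (guide$strand == "+") {
    guide$protospacer_start + guide$cut_offset
  } else {
    guide$protospacer_start + (20L - guide$cut_offset)
  }
}

#' Quantification window
#'
#' A window of total width `width` nucleotides centered on the inter-base cut
#' coordinate: the half-open reference interval
#' `[cut_site - width/2, cut_site + width/2)`, clipped to the amplicon when
#' applied. The narrow/wide analysis uses widths 2 and 20.
#'
#' @param cut_site 0-based inter-base cut coordinate.
#' @param width Even positive total width in nt.
#' @return An object of class `quant_window`.
#' @export
quant_window <- function(cut_site, width) {
  width <- as.integer(width)
  if (width <= 0L || width %% 2L != 0L) stop("window width must be a positive even integer")
  structure(list(cut_site = as.integer(cut_site), width = width),
            class = "quant_window")
}

# Window bounds clipped to [0, ref_length), 0-based half-open.
window_bounds <- function(window, ref_length) {
  half <- window$width %/% 2L
  c(lo = max(0L, window$cut_site - half),
    hi = min(as.integer(ref_length), window$cut_site + half))
}

#' Construct a synthetic reference amplicon with a planted guide
#'
#' Generates a random amplicon of the requested length and GC content with a
#' single 20-nt protospacer followed by an NGG PAM planted at least 25 nt
#' from both ends, and returns the matching [guide_spec()]. The protospacer
#' is guaranteed to occur exactly once on the plus strand.
#'
#' @param length Amplicon length in nt (>= 80).
#' @param gc_fraction GC content in `[0, 1]`.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param cut_offset Passed to [guide_spec()].
#' @return List with `id`, `sequence` and `guide`.
#' @export
make_amplicon <- function(length, gc_fraction = 0.5, seed = 1L,
                          cut_offset = 17L) {
  length <- as.integer(length)
  if (length < 80L) {
    stop("amplicon length must be at least 80 nt to leave 25-nt flanks around the guide")
  }
  with_seed(seed, {
    for (attempt in 1:25) {
      seq <- random_dna(length, gc_fraction)
      start <- sample(25L:(length - 25L - 23L), 1L)
      # force the PAM to NGG
      seq <- sub_base(seq, start + 21L, "G")
      seq <- sub_base(seq, start + 22L, "G")
      protospacer <- substr(seq, start + 1L, start + 20L)
      pam <- substr(seq, start + 21L, start + 23L)
      n_occ <- length(gregexpr(protospacer, seq, fixed = TRUE)[[1]])
      if (attr(gregexpr(protospacer, seq, fixed = TRUE)[[1]], "match.length")[1] == -1L) {
        n_occ <- 0L
      }
      if (n_occ == 1L) {
        guide <- guide_spec(protospacer, pam, "+", start, cut_offset)
        return(list(id = sprintf("amplicon_seed%d", as.integer(seed)),
                    sequence = seq, guide = guide))
      }
    }
    stop("failed to plant a unique protospacer; try another seed")
  })
}
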