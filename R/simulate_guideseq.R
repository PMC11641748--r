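# Desk-scale GUIDE-seq simulator: a small genome with planted protospacer
# sites and dsODN-junction reads.

#' Standard GUIDE-seq dsODN tag
#'
#' The 34-nt double-stranded oligodeoxynucleotide used as the integration
#' tag.
#'
#' @return A DNA string.
#' @export
guideseq_dsodn <- function() {
  "GTTTAATTGAGTTGTCATATGTTAATAACGGTAT"
}

#' Simulate a GUIDE-seq experiment on a small genome
#'
#' Builds a random genome, embeds a protospacer + NGG PAM at each planted
#' site (with the requested number of protospacer mismatches), and emits
#' `read_count` dsODN-junction reads per site: the genomic flank 5' of the
#' blunt cut joined to the dsODN, padded to `read_length`. Background reads
#' are plain genomic fragments without the tag. Each read is reported on a
#' random sequencing orientation (the whole read may be reverse
#' complemented).
#'
#' @param genome_length Genome length in nt.
#' @param planted_sites data.frame with columns `position` (0-based
#'   protospacer start), `strand`, `mismatches` (protospacer mismatches to
#'   the guide, PAM kept NGG) and `read_count`.
#' @param protospacer 20-nt guide protospacer; `NULL` draws a random one.
#' @param dsodn Tag sequence (>= 16 nt), default [guideseq_dsodn()].
#' @param read_length Read length in nt (> tag length + 20).
#' @param n_background Number of untagged background reads.
#' @param seed Integer seed; same seed, identical reads.
#' @return List with `genome`, `protospacer`, `dsodn`, `reads` (named
#'   character vector), `sites` (truth data.frame with `position`, `cut`,
#'   `strand`, `mismatches`, `mismatch_positions`, `read_count`) and
#'   `read_truth`.
#' @export
simulate_guideseq <- function(genome_length, planted_sites,
                              protospacer = NULL,
                              dsodn = guideseq_dsodn(),
                              read_length = 100L, n_background = 500L,
                              seed = 1L) {
  genome_length <- as.integer(genome_length)
  if (nchar(dsodn) < 16L) stop("dsODN tag must be at least 16 nt")
  read_length <- as.integer(read_length)
  flank_len <- read_length - nchar(dsodn)
  if (flank_len < 20L) stop("read_length leaves less than 20 nt of genomic flank")
  sites <- planted_sites
  if (is.null(sites)) {
    sites <- data.frame(position = integer(0), strand = character(0),
                        mismatches = integer(0), read_count = integer(0))
  }
  if (nrow(sites) > 0L) {
    cuts <- ifelse(sites$strand == "+", sites$position + 17L, sites$position + 3L)
    if (any(cuts - flank_len < 0L | sites$position + 23L > genome_length |
            cuts + flank_len > genome_length | sites$position < 0L)) {
      stop("planted site too close to the genome edge")
    }
    if (nrow(sites) > 1L) {
      o <- order(sites$position)
      if (any(diff(sites$position[o]) < 23L)) stop("planted sites overlap")
    }
  }

  with_seed(seed, {
    if (is.null(protospacer)) {
      protospacer <- paste(sample(DNA_BASES, 20L, replace = TRUE), collapse = "")
    }
    genome <- random_dna(genome_length, 0.5)

    mm_positions <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
      site_seq <- protospacer
      mm <- integer(0)
      if (sites$mismatches[i] > 0L) {
        mm <- sort(sample.int(20L, sites$mismatches[i]))
        for (p in mm) {
          site_seq <- sub_base(site_seq, p - 1L, other_base(substr(site_seq, p, p)))
        }
      }
      mm_positions[[i]] <- mm
      embedded <- paste0(site_seq, paste0(sample(DNA_BASES, 1L), "GG"))
      if (sites$strand[i] == "-") embedded <- revcomp(embedded)
      substr(genome, sites$position[i] + 1L,
             sites$position[i] + 23L) <- embedded
    }

    cuts <- if (nrow(sites) > 0L) {
      ifelse(sites$strand == "+", sites$position + 17L, sites$position + 3L)
    } else integer(0)

    reads <- character(0)
    origin <- character(0)
    for (i in seq_len(nrow(sites))) {
      flank <- if (sites$strand[i] == "+") {
        substr(genome, cuts[i] - flank_len + 1L, cuts[i])
      } else {
        revcomp(substr(genome, cuts[i] + 1L, cuts[i] + flank_len))
      }
      reads <- c(reads, rep(paste0(flank, dsodn), sites$read_count[i]))
      origin <- c(origin, rep(sprintf("site_%d", i), sites$read_count[i]))
    }
    if (n_background > 0L) {
      starts <- sample.int(genome_length - read_length + 1L, n_background,
                           replace = TRUE)
      reads <- c(reads, substring(genome, starts, starts + read_length - 1L))
      origin <- c(origin, rep("background", n_background))
    }
    flip <- runif(length(reads)) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    ids <- sprintf("gsread_%06d", seq_along(reads))

    truth_sites <- if (nrow(sites) > 0L) {
      data.frame(position = sites$position, cut = cuts,
                 strand = sites$strand, mismatches = sites$mismatches,
                 mismatch_positions = vapply(mm_positions, paste,
                                             character(1), collapse = ","),
                 read_count = sites$read_count, stringsAsFactors = FALSE)
    } else {
      data.frame(position = integer(0), cut = integer(0),
                 strand = character(0), mismatches = integer(0),
                 mismatch_positions = character(0), read_count = integer(0))
    }
    list(genome = genome, protospacer = protospacer, dsodn = dsodn,
         reads = setNames(reads, ids), sites = truth_sites,
         read_truth = data.frame(read_id = ids, origin = origin,
                                 stringsAsFactors = FALSE))
  })
}
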