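# GUIDE-seq-style integration-site calling: tag detection, flank mapping,
# site clustering and protospacer mismatch scoring.

#' Find dsODN-tagged reads and extract their genomic flanks
#'
#' A read is tagged iff the dsODN occurs in either orientation with at most
#' `max_mismatches` substitutions. The genomic flank is the maximal read
#' segment adjacent to the tag junction, oriented 5' to 3' toward the
#' junction (for a reverse-orientation tag the segment after the tag is
#' reverse complemented); reads whose flank is shorter than `min_flank` are
#' dropped.
#'
#' @param reads Named character vector (or `DNAStringSet`) of reads.
#' @param dsodn Tag sequence.
#' @param max_mismatches Maximum substitutions allowed in the tag match.
#' @param min_flank Minimum flank length in nt.
#' @return data.frame with `read_id`, `orientation` (`"F"`/`"R"`) and
#'   `flank`.
#' @export
find_dsodn_reads <- function(reads, dsodn, max_mismatches = 2L,
                             min_flank = 20L) {
  if (length(reads) == 0L) stop("reads must be non-empty")
  ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
  set <- Biostrings::DNAStringSet(as.character(reads))
  fwd <- Biostrings::vmatchPattern(dsodn, set, max.mismatch = max_mismatches)
  rev <- Biostrings::vmatchPattern(revcomp(dsodn), set,
                                   max.mismatch = max_mismatches)
  n_fwd <- S4Vectors::elementNROWS(fwd)
  n_rev <- S4Vectors::elementNROWS(rev)
  hit <- which(n_fwd > 0L | n_rev > 0L)
  if (length(hit) == 0L) {
    return(data.frame(read_id = character(0), orientation = character(0),
                      flank = character(0), stringsAsFactors = FALSE))
  }
  seqs <- as.character(set)
  rows <- lapply(hit, function(i) {
    if (n_fwd[i] > 0L) {
      m <- fwd[[i]][1L]
      flank <- substr(seqs[i], 1L, BiocGenerics::start(m) - 1L)
      orient <- "F"
    } else {
      m <- rev[[i]][1L]
      flank <- revcomp(substr(seqs[i], BiocGenerics::end(m) + 1L,
                              nchar(seqs[i])))
      orient <- "R"
    }
    list(read_id = ids[i], orientation = orient, flank = flank)
  })
  out <- data.frame(
    read_id = vapply(rows, `[[`, character(1), "read_id"),
    orientation = vapply(rows, `[[`, character(1), "orientation"),
    flank = vapply(rows, `[[`, character(1), "flank"),
    stringsAsFactors = FALSE)
  out[nchar(out$flank) >= min_flank, , drop = FALSE]
}

#' Build an exact k-mer index of a genome (both strands)
#'
#' @param genome Genome sequence (string) or named length-1 character.
#' @param k Seed length.
#' @return A `genome_index` object used by [map_flank()].
#' @export
genome_index <- function(genome, k = 12L) {
  contig <- names(genome) %||% "genome"
  g <- toupper(as.character(genome)[1])
  k <- as.integer(k)
  glen <- nchar(g)
  if (glen < k) stop("genome shorter than the seed length")
  starts <- seq_len(glen - k + 1L)
  kmer_table <- function(s) {
    kmers <- substring(s, starts, starts + k - 1L)
    split(starts - 1L, kmers)
  }
  structure(list(contig = contig, k = k, genome = g, genome_rc = revcomp(g),
                 fwd = kmer_table(g), rc = kmer_table(revcomp(g)),
                 length = glen),
            class = "genome_index")
}

#' Map a genomic flank onto the genome
#'
#' Seed-and-verify mapping: `max_mismatches + 1` non-overlapping exact
#' k-mer seeds guarantee (pigeonhole) that every placement with at most
#' `max_mismatches` substitutions is recovered; candidates are verified by
#' Hamming distance on both strands. Equivalent to an exhaustive
#' both-strand scan.
#'
#' @param flank Flank sequence (5' to 3' toward the junction).
#' @param genome A `genome_index` (or a sequence, indexed on the fly).
#' @param max_mismatches Maximum substitutions for a placement.
#' @return data.frame with `contig`, `start` (0-based), `strand`,
#'   `junction` (0-based inter-base integration coordinate) and
#'   `mismatches`.
#' @export
map_flank <- function(flank, genome, max_mismatches = 1L) {
  if (!nzchar(flank %||% "")) stop("empty flank")
  idx <- if (inherits(genome, "genome_index")) genome else genome_index(genome)
  k <- idx$k
  L <- nchar(flank)
  if (L < k) stop("flank shorter than the seed length")
  n_seeds <- min(max_mismatches + 1L, L %/% k)
  offsets <- floor(seq(0L, L - k, length.out = n_seeds))

  scan_strand <- function(table, target) {
    cand <- integer(0)
    for (off in offsets) {
      kmer <- substr(flank, off + 1L, off + k)
      hits <- table[[kmer]]
      if (!is.null(hits)) cand <- c(cand, hits - off)
    }
    cand <- unique(cand[cand >= 0L & cand + L <= idx$length])
    keep <- vapply(cand, function(s) {
      hamming(substr(target, s + 1L, s + L), flank) <= max_mismatches
    }, logical(1))
    cand[keep]
  }

  fwd <- scan_strand(idx$fwd, idx$genome)
  rc <- scan_strand(idx$rc, idx$genome_rc)

  out <- data.frame(contig = character(0), start = integer(0),
                    strand = character(0), junction = integer(0),
                    mismatches = integer(0), stringsAsFactors = FALSE)
  if (length(fwd) > 0L) {
    out <- rbind(out, data.frame(
      contig = idx$contig, start = fwd, strand = "+", junction = fwd + L,
      mismatches = vapply(fwd, function(s) {
        hamming(substr(idx$genome, s + 1L, s + L), flank)
      }, numeric(1)), stringsAsFactors = FALSE))
  }
  if (length(rc) > 0L) {
    start_plus <- idx$length - rc - L
    out <- rbind(out, data.frame(
      contig = idx$contig, start = start_plus, strand = "-",
      junction = start_plus,
      mismatches = vapply(rc, function(s) {
        hamming(substr(idx$genome_rc, s + 1L, s + L), flank)
      }, numeric(1)), stringsAsFactors = FALSE))
  }
  out[order(out$start), , drop = FALSE]
}

#' Consolidate mapped junctions into integration sites
#'
#' Reads with a unique placement are grouped by contig and strand; junction
#' positions within `merge_distance` merge into one site (single linkage).
#' The site coordinate is the most frequent junction (smallest on ties);
#' sites supported by fewer than `min_reads` distinct reads are dropped, so
#' every tagged read contributes to at most one site.
#'
#' @param placements data.frame with `read_id`, `contig`, `junction`,
#'   `strand` (one row per read placement; multi-placement reads are
#'   dropped as ambiguous).
#' @param merge_distance Maximum junction gap within a site (nt).
#' @param min_reads Minimum distinct supporting reads.
#' @return data.frame with `contig`, `position`, `strand`, `read_count`.
#' @export
cluster_sites <- function(placements, merge_distance = 10L, min_reads = 2L) {
  empty <- data.frame(contig = character(0), position = integer(0),
                      strand = character(0), read_count = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(placements) == 0L) return(empty)
  multi <- names(which(table(placements$read_id) > 1L))
  placements <- placements[!placements$read_id %in% multi, , drop = FALSE]
  if (nrow(placements) == 0L) return(empty)

  out <- empty
  for (key in unique(paste(placements$contig, placements$strand))) {
    sub <- placements[paste(placements$contig, placements$strand) == key, ,
                      drop = FALSE]
    sub <- sub[order(sub$junction), , drop = FALSE]
    brk <- cumsum(c(0L, diff(sub$junction) > merge_distance))
    for (cl in split(seq_len(nrow(sub)), brk)) {
      jx <- sub$junction[cl]
      counts <- table(jx)
      pos <- as.integer(names(counts)[which.max(counts)])
      n <- length(unique(sub$read_id[cl]))
      if (n >= min_reads) {
        out <- rbind(out, data.frame(contig = sub$contig[cl[1]],
                                     position = pos,
                                     strand = sub$strand[cl[1]],
                                     read_count = n,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out[order(-out$read_count, out$position), , drop = FALSE]
}

#' Score an integration site against the guide
#'
#' Slides the 23-nt protospacer + PAM frame over both strands within
#' `span` nt of the site junction, preferring NGG-adjacent placements and
#' minimizing protospacer mismatches; ties go to the placement whose
#' predicted cut lies closest to the junction. When no NGG placement
#' exists, the best PAM-less match is reported and flagged.
#'
#' @param site A row of [cluster_sites()] output (or a list with `position`
#'   and `read_count`).
#' @param genome Genome sequence (string).
#' @param protospacer 20-nt guide protospacer.
#' @param span Search span around the junction in nt.
#' @return List of class `offtarget_record`: `position`, `strand`,
#'   `read_count`, `protospacer_match`, `pam`, `pam_ok`, `n_mismatches`,
#'   `mismatch_positions` (1-based within the protospacer), `cut_estimate`
#'   and `is_on_target` (zero mismatches with an NGG PAM).
#' @export
score_site_vs_guide <- function(site, genome, protospacer, span = 25L) {
  g <- toupper(as.character(genome)[1])
  glen <- nchar(g)
  pos <- as.integer(site$position)
  if (pos < 0L || pos > glen) stop("site position outside the genome")
  lo <- max(0L, pos - span - 23L)
  hi <- min(glen, pos + span + 23L)

  best <- NULL
  consider <- function(n_mm, mm_pos, pam, pam_ok, cut, strand, window) {
    cand <- list(n_mismatches = n_mm, mismatch_positions = mm_pos, pam = pam,
                 pam_ok = pam_ok, cut_estimate = cut, strand = strand,
                 protospacer_match = window)
    if (is.null(best)) { best <<- cand; return(invisible()) }
    better <- (cand$pam_ok && !best$pam_ok) ||
      (cand$pam_ok == best$pam_ok &&
         (cand$n_mismatches < best$n_mismatches ||
            (cand$n_mismatches == best$n_mismatches &&
               abs(cand$cut_estimate - pos) < abs(best$cut_estimate - pos))))
    if (better) best <<- cand
  }

  for (s in lo:(hi - 23L)) {
    frame <- substr(g, s + 1L, s + 23L)
    # plus strand
    proto <- substr(frame, 1L, 20L)
    pam <- substr(frame, 21L, 23L)
    mm <- which(charToRaw(proto) != charToRaw(protospacer))
    consider(length(mm), mm, pam, substr(pam, 2L, 3L) == "GG", s + 17L, "+",
             proto)
    # minus strand
    frame_rc <- revcomp(frame)
    proto_rc <- substr(frame_rc, 1L, 20L)
    pam_rc <- substr(frame_rc, 21L, 23L)
    mm_rc <- which(charToRaw(proto_rc) != charToRaw(protospacer))
    consider(length(mm_rc), mm_rc, pam_rc, substr(pam_rc, 2L, 3L) == "GG",
             s + 3L, "-", proto_rc)
  }
  structure(c(list(position = pos,
                   read_count = site$read_count %||% NA_integer_),
              best,
              list(is_on_target = best$n_mismatches == 0L && best$pam_ok)),
            class = "offtarget_record")
}

#' Off-target report
#'
#' Aggregates scored integration sites into a per-site table and the
#' off-target read fractions. Because the denominator of "fraction of total
#' reads" is ambiguous in published accounts, both are reported: off-target
#' reads over all sequenced reads and over dsODN-tagged site reads.
#'
#' @param records List of `offtarget_record`s.
#' @param total_reads Total sequenced reads in the run.
#' @return List with `table` (one row per site), `on_target_reads`,
#'   `off_target_reads`, `off_fraction_total`, `off_fraction_tagged`.
#' @export
offtarget_report <- function(records, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (length(records) == 0L) {
    return(list(table = data.frame(), on_target_reads = 0L,
                off_target_reads = 0L, off_fraction_total = 0,
                off_fraction_tagged = 0))
  }
  tab <- data.frame(
    position = vapply(records, `[[`, numeric(1), "position"),
    strand = vapply(records, `[[`, character(1), "strand"),
    read_count = vapply(records, `[[`, numeric(1), "read_count"),
    protospacer_match = vapply(records, `[[`, character(1), "protospacer_match"),
    pam = vapply(records, `[[`, character(1), "pam"),
    pam_ok = vapply(records, `[[`, logical(1), "pam_ok"),
    n_mismatches = vapply(records, `[[`, numeric(1), "n_mismatches"),
    mismatch_positions = vapply(records, function(r) {
      paste(r$mismatch_positions, collapse = ",")
    }, character(1)),
    is_on_target = vapply(records, `[[`, logical(1), "is_on_target"),
    stringsAsFactors = FALSE)
  tab$read_fraction_of_total <- tab$read_count / total_reads
  on_reads <- sum(tab$read_count[tab$is_on_target])
  off_reads <- sum(tab$read_count[!tab$is_on_target])
  tagged <- on_reads + off_reads
  list(table = tab[order(-tab$is_on_target, tab$n_mismatches), , drop = FALSE],
       on_target_reads = on_reads, off_target_reads = off_reads,
       off_fraction_total = off_reads / total_reads,
       off_fraction_tagged = if (tagged > 0) off_reads / tagged else 0)
}

#' Call and score integration sites from tagged reads
#'
#' Convenience wrapper running [find_dsodn_reads()], [map_flank()],
#' [cluster_sites()], [score_site_vs_guide()] and [offtarget_report()].
#'
#' @inheritParams find_dsodn_reads
#' @param genome Genome sequence.
#' @param protospacer 20-nt guide protospacer.
#' @param max_map_mismatches Mismatches allowed when mapping flanks.
#' @param merge_distance,min_reads See [cluster_sites()].
#' @param span See [score_site_vs_guide()].
#' @return List with `sites`, `records` and `report`.
#' @export
call_integration_sites <- function(reads, genome, protospacer,
                                   dsodn = guideseq_dsodn(),
                                   max_mismatches = 2L, min_flank = 20L,
                                   max_map_mismatches = 1L,
                                   merge_distance = 10L, min_reads = 2L,
                                   span = 25L) {
  tagged <- find_dsodn_reads(reads, dsodn, max_mismatches, min_flank)
  idx <- genome_index(genome)
  placements <- data.frame(read_id = character(0), contig = character(0),
                           junction = integer(0), strand = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(tagged) > 0L) {
    by_flank <- split(tagged$read_id, tagged$flank)
    rows <- lapply(names(by_flank), function(fl) {
      hits <- map_flank(fl, idx, max_map_mismatches)
      if (nrow(hits) == 0L) return(NULL)
      do.call(rbind, lapply(by_flank[[fl]], function(id) {
        data.frame(read_id = id, contig = hits$contig,
                   junction = hits$junction, strand = hits$strand,
                   stringsAsFactors = FALSE)
      }))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) > 0L) placements <- do.call(rbind, rows)
  }
  sites <- cluster_sites(placements, merge_distance, min_reads)
  records <- lapply(seq_len(nrow(sites)), function(i) {
    score_site_vs_guide(sites[i, ], genome, protospacer, span)
  })
  list(sites = sites, records = records,
       report = offtarget_report(records, length(reads)))
}
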