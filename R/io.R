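# Sequence and table I/O. FASTA parsing goes through Biostrings; FASTQ is
# written with a fixed 'I' quality line (the analysis is quality-agnostic)
# so identical simulations produce byte-identical files.

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs) %||% paste0("seq_", seq_along(seqs))
  set <- Biostrings::DNAStringSet(as.character(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path Input file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop(sprintf("malformed FASTA in %s: %s", path,
                                 conditionMessage(e)))
                  })
  setNames(as.character(set), sub(" .*$", "", names(set)))
}

#' Write reads to FASTQ (fixed quality)
#'
#' @param reads Named character vector of reads.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
  lines <- character(4L * length(reads))
  lines[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", ids)
  lines[seq(2L, by = 4L, length.out = length(reads))] <- as.character(reads)
  lines[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(reads))] <-
    strrep("I", nchar(reads))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Input file.
#' @return Named character vector of reads.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: %s", path))
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                  error = function(e) {
                    stop(sprintf("malformed FASTQ in %s: %s", path,
                                 conditionMessage(e)))
                  })
  setNames(as.character(set), sub(" .*$", "", names(set)))
}

#' Write a data.frame as TSV
#'
#' List columns (e.g. allele events) are flattened to compact strings.
#'
#' @param df A data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(evs) {
        paste(vapply(evs, function(ev) {
          switch(ev$kind,
                 insertion = sprintf("ins:%d:%s", ev$ref_start, ev$alt),
                 deletion = sprintf("del:%d:%d", ev$ref_start, ev$ref_length),
                 substitution = sprintf("sub:%d:%s", ev$ref_start, ev$alt))
        }, character(1)), collapse = ";")
      }, character(1))
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write integration sites as BED
#'
#' 0-based half-open single-base intervals at each junction.
#'
#' @param sites [cluster_sites()] output.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = sites$contig, start = sites$position,
                    end = sites$position + 1L,
                    name = sprintf("site_%d", seq_len(nrow(sites))),
                    score = sites$read_count, strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
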