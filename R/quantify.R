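# AEE quantification and allele tables.

# Quantify from a pre-computed alignment set (shared by quantify_edits and
# dual_window_aee so both windows see the same aligned read partition).
quantify_from_aset <- function(aset, cut, width) {
  window <- quant_window(cut, width)
  ref_len <- nchar(aset$alignments[[1L]]$ref)
  b <- window_bounds(window, ref_len)
  keep <- !aset$discarded
  n_discarded <- sum(aset$count[!keep])
  if (!any(keep)) stop("no aligned reads")
  mod <- vapply(aset$alignments[keep], function(a) {
    events_modify_window(a$events, b[["lo"]], b[["hi"]])
  }, logical(1))
  n_modified <- sum(aset$count[keep][mod])
  n_unmodified <- sum(aset$count[keep][!mod])
  structure(list(n_modified = n_modified,
                 n_unmodified = n_unmodified,
                 n_discarded = n_discarded,
                 aee = n_modified / (n_modified + n_unmodified),
                 window = window),
            class = "aee_result")
}

#' Quantify alleged editing efficiency (AEE)
#'
#' Aligns every read to the reference amplicon, classifies each as modified
#' or unmodified within a quantification window of total width `width`
#' centered on the predicted cut site, and returns the AEE: modified reads
#' out of all aligned (modified + unmodified) reads. Reads below the
#' identity floor are discarded and excluded from the denominator.
#'
#' @param reads Character vector (or `DNAStringSet`) of amplicon reads.
#' @param amplicon Reference amplicon (string or design list).
#' @param guide A [guide_spec()] matching the amplicon.
#' @param width Even window width in nt (the study uses 2 and 20).
#' @param scoring See [default_scoring()].
#' @return An `aee_result` with counts (`n_modified`, `n_unmodified`,
#'   `n_discarded`), `aee` and the `window`.
#' @export
quantify_edits <- function(reads, amplicon, guide, width = 2L,
                           scoring = default_scoring()) {
  cut <- cut_site(guide, amplicon)
  aset <- align_read_set(reads, amplicon, scoring)
  quantify_from_aset(aset, cut, width)
}

#' @export
print.aee_result <- function(x, ...) {
  cat(sprintf("AEE (window %d nt): %.4f  [modified %d / aligned %d; discarded %d]\n",
              x$window$width, x$aee, x$n_modified,
              x$n_modified + x$n_unmodified, x$n_discarded))
  invisible(x)
}

# Render the aligned read over reference span [lo, hi): one character per
# reference position ('-' for deleted), insertions anchored strictly inside
# the span appear in lowercase at their anchor.
render_span <- function(aligned_read, aligned_ref, lo, hi) {
  r <- strsplit(aligned_read, "", fixed = TRUE)[[1]]
  f <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  out <- character(0)
  refpos <- 0L
  for (i in seq_along(r)) {
    if (f[i] == "-") {
      if (refpos > lo && refpos < hi) out <- c(out, tolower(r[i]))
    } else {
      if (refpos >= lo && refpos < hi) out <- c(out, r[i])
      refpos <- refpos + 1L
    }
  }
  paste(out, collapse = "")
}

#' Allele table around the cut site
#'
#' Collapses aligned reads by their rendered sequence over a report span
#' centered on the cut site (default 40 nt, i.e. +/- 20). Deletions are
#' rendered as `-`, insertions as lowercase bases at their anchor. Each
#' allele row carries its read count, frequency among aligned reads, the
#' modification events of its most frequent member, and whether it is
#' modified within the quantification window (default width 20). Rows are
#' ordered by count descending, ties broken lexicographically.
#'
#' @inheritParams quantify_edits
#' @param report_span Even total span in nt rendered around the cut.
#' @param window_width Window used for the `modified` flag.
#' @return A `data.frame` of class `allele_table` with columns
#'   `aligned_sequence`, `count`, `frequency`, `modified`, `sub_only`,
#'   `has_indel` and a list column `events`; attributes `cut_site`,
#'   `report_span`, `n_aligned`.
#' @export
allele_table <- function(reads, amplicon, guide, report_span = 40L,
                         window_width = 20L, scoring = default_scoring()) {
  report_span <- as.integer(report_span)
  if (report_span <= 0L || report_span %% 2L != 0L) {
    stop("report_span must be a positive even integer")
  }
  cut <- cut_site(guide, amplicon)
  aset <- align_read_set(reads, amplicon, scoring)
  ref_len <- nchar(amp_seq(amplicon))
  half <- report_span %/% 2L
  lo <- max(0L, cut - half)
  hi <- min(ref_len, cut + half)
  wb <- window_bounds(quant_window(cut, window_width), ref_len)

  keep <- which(!aset$discarded)
  if (length(keep) == 0L) stop("no aligned reads")
  rendered <- vapply(aset$alignments[keep], function(a) {
    render_span(a$aligned_read, a$aligned_ref, lo, hi)
  }, character(1))
  cnt <- aset$count[keep]
  n_aligned <- sum(cnt)

  idx_by_allele <- split(seq_along(rendered), rendered)
  rows <- lapply(names(idx_by_allele), function(key) {
    ix <- idx_by_allele[[key]]
    top <- ix[which.max(cnt[ix])]
    ev <- aset$alignments[keep][[top]]$events
    kinds <- vapply(ev, `[[`, character(1), "kind")
    list(aligned_sequence = key,
         count = sum(cnt[ix]),
         modified = events_modify_window(ev, wb[["lo"]], wb[["hi"]]),
         sub_only = length(ev) > 0L && all(kinds == "substitution"),
         has_indel = any(kinds %in% c("insertion", "deletion")),
         events = list(ev))
  })
  tab <- data.frame(
    aligned_sequence = vapply(rows, `[[`, character(1), "aligned_sequence"),
    count = vapply(rows, `[[`, numeric(1), "count"),
    stringsAsFactors = FALSE)
  tab$frequency <- tab$count / n_aligned
  tab$modified <- vapply(rows, `[[`, logical(1), "modified")
  tab$sub_only <- vapply(rows, `[[`, logical(1), "sub_only")
  tab$has_indel <- vapply(rows, `[[`, logical(1), "has_indel")
  tab$events <- lapply(rows, function(r) r$events[[1L]])
  ord <- order(-tab$count, tab$aligned_sequence)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "cut_site") <- cut
  attr(tab, "report_span") <- report_span
  attr(tab, "n_aligned") <- n_aligned
  class(tab) <- c("allele_table", "data.frame")
  tab
}

#' Plain-text rendering of an allele table
#'
#' Produces a CRISPResso2-like text view: the reference span on top (marked
#' with `*`), then each allele with its count and frequency. The predicted
#' cut site falls at the middle of the span.
#'
#' @param tab An [allele_table()].
#' @param amplicon,guide The amplicon and guide the table was built from.
#' @param top_n Number of alleles to render.
#' @return Character vector of lines.
#' @export
format_allele_text <- function(tab, amplicon, guide, top_n = 10L) {
  cut <- attr(tab, "cut_site")
  half <- attr(tab, "report_span") %/% 2L
  ref <- amp_seq(amplicon)
  lo <- max(0L, cut - half)
  hi <- min(nchar(ref), cut + half)
  ref_span <- substr(ref, lo + 1L, hi)
  lines <- sprintf("%-*s  %8s  %8s  *reference", max(nchar(ref_span), 20L),
                   ref_span, "reads", "freq")
  n <- min(nrow(tab), top_n)
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%-*s  %8d  %7.2f%%%s",
                              max(nchar(ref_span), 20L),
                              tab$aligned_sequence[i],
                              as.integer(tab$count[i]),
                              100 * tab$frequency[i],
                              if (!tab$modified[i]) "  *unmodified" else ""))
  }
  lines
}
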