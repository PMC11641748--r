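# dsODN tag detection, flank mapping, site clustering and mismatch scoring.

test_that("tag detection respects the mismatch budget and extracts flanks", {
  set.seed(90)
  tag <- guideseq_dsodn()
  flank <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  read_ok <- paste0(flank, tag)
  read_plain <- paste(sample(c("A", "C", "G", "T"), 94, TRUE), collapse = "")
  # one mismatch in the tag
  tag_mm <- tag
  substr(tag_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(tag, 5, 5))[1]
  read_mm1 <- paste0(flank, tag_mm)
  reads <- setNames(c(read_ok, read_plain, read_mm1), c("a", "b", "c"))

  hits1 <- find_dsodn_reads(reads, tag, max_mismatches = 1)
  expect_setequal(hits1$read_id, c("a", "c"))
  expect_equal(hits1$flank[hits1$read_id == "a"], flank)
  hits0 <- find_dsodn_reads(reads, tag, max_mismatches = 0)
  expect_equal(hits0$read_id, "a")

  # reverse-orientation read normalizes back to the same flank
  rc_read <- dualwindow:::revcomp(read_ok)
  hits_rc <- find_dsodn_reads(setNames(rc_read, "r"), tag, max_mismatches = 0)
  expect_equal(hits_rc$orientation, "R")
  expect_equal(hits_rc$flank, flank)

  # short flanks are dropped
  short_read <- paste0(substr(flank, 1, 10), tag)
  expect_equal(nrow(find_dsodn_reads(setNames(short_read, "s"), tag)), 0)
})

test_that("map_flank equals the exhaustive both-strand scan", {
  set.seed(91)
  genome <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  idx <- genome_index(genome)
  for (i in 1:8) {
    s <- sample(0:(4000 - 40), 1)
    flank <- substr(genome, s + 1, s + 40)
    if (i %% 2 == 0) { # plant one mismatch
      p <- sample(40, 1)
      substr(flank, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(flank, p, p))[1]
    }
    mine <- map_flank(flank, idx, max_mismatches = 1)
    oracle <- brute_scan(flank, genome, 1)
    expect_equal(nrow(mine), nrow(oracle))
    expect_setequal(paste(mine$start, mine$strand),
                    paste(oracle$start, oracle$strand))
  }
  # a duplicated flank reports both placements
  dup <- substr(genome, 101, 140)
  genome2 <- paste0(genome, dup)
  m2 <- map_flank(dup, genome_index(genome2), max_mismatches = 0)
  expect_equal(nrow(m2), 2)
  expect_error(map_flank("", idx), "empty")
})

test_that("minus-strand placements carry the junction at the flank 3' end", {
  set.seed(92)
  genome <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  s <- 600L
  L <- 50L
  # flank whose revcomp sits at [s, s+L): junction must be at s
  flank <- dualwindow:::revcomp(substr(genome, s + 1, s + L))
  m <- map_flank(flank, genome_index(genome), max_mismatches = 0)
  minus <- m[m$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$start, s)
  expect_equal(minus$junction, s)
})

test_that("cluster_sites merges nearby junctions and filters low support", {
  mk <- function(ids, pos) {
    data.frame(read_id = ids, contig = "genome", junction = pos,
               strand = "+", stringsAsFactors = FALSE)
  }
  s1 <- cluster_sites(mk(c("r1", "r2", "r3"), c(1000L, 1001L, 1003L)))
  expect_equal(nrow(s1), 1)
  expect_equal(s1$read_count, 3)
  expect_true(s1$position %in% c(1000L, 1001L, 1003L))
  s2 <- cluster_sites(mk(c("r1", "r2", "r3", "r4"),
                         c(1000L, 1001L, 1100L, 1101L)))
  expect_equal(nrow(s2), 2)
  s3 <- cluster_sites(mk("r1", 1000L), min_reads = 2)
  expect_equal(nrow(s3), 0)
  # ambiguous multi-mapping reads never support a site
  amb <- mk(c("r1", "r1", "r2", "r3"), c(1000L, 2000L, 1001L, 1002L))
  s4 <- cluster_sites(amb)
  expect_equal(s4$read_count, 2)
})

test_that("site scoring recovers planted mismatch positions and the on-target flag", {
  sites <- data.frame(position = c(3000L, 9000L), strand = c("+", "+"),
                      mismatches = c(0L, 3L), read_count = c(30L, 6L))
  gs <- simulate_guideseq(12000, sites, read_length = 100,
                          n_background = 50, seed = 93)
  rec_on <- score_site_vs_guide(list(position = gs$sites$cut[1],
                                     read_count = 30L),
                                gs$genome, gs$protospacer)
  expect_true(rec_on$is_on_target)
  expect_equal(rec_on$n_mismatches, 0)
  expect_true(rec_on$pam_ok)
  rec_off <- score_site_vs_guide(list(position = gs$sites$cut[2],
                                      read_count = 6L),
                                 gs$genome, gs$protospacer)
  expect_false(rec_off$is_on_target)
  expect_equal(rec_off$n_mismatches, 3)
  expect_equal(paste(rec_off$mismatch_positions, collapse = ","),
               gs$sites$mismatch_positions[2])
})

test_that("offtarget_report computes both read fractions", {
  rec <- function(pos, n, mm, on) {
    structure(list(position = pos, read_count = n, n_mismatches = mm,
                   mismatch_positions = integer(0), pam = "TGG",
                   pam_ok = TRUE, cut_estimate = pos, strand = "+",
                   protospacer_match = strrep("A", 20), is_on_target = on),
              class = "offtarget_record")
  }
  rep1 <- offtarget_report(list(rec(100, 600, 0, TRUE), rec(900, 5, 3, FALSE)),
                           total_reads = 65517)
  expect_equal(rep1$off_target_reads, 5)
  expect_equal(rep1$off_fraction_total, 5 / 65517)
  expect_equal(rep1$off_fraction_tagged, 5 / 605)
  expect_equal(rep1$table$read_fraction_of_total[1], 600 / 65517)
  rep0 <- offtarget_report(list(rec(100, 600, 0, TRUE)), total_reads = 1000)
  expect_equal(rep0$off_fraction_total, 0)
  expect_error(offtarget_report(list(), 0), "positive")
  expect_equal(offtarget_report(list(), 10)$off_fraction_total, 0)
})

test_that("end-to-end calling recovers planted sites with exact counts", {
  sites <- data.frame(position = c(2000L, 7000L, 10000L),
                      strand = c("+", "-", "+"),
                      mismatches = c(0L, 3L, 4L),
                      read_count = c(80L, 7L, 5L))
  gs <- simulate_guideseq(14000, sites, read_length = 100,
                          n_background = 200, seed = 94)
  res <- call_integration_sites(gs$reads, gs$genome, gs$protospacer, gs$dsodn)
  expect_equal(nrow(res$sites), 3)
  expect_setequal(res$sites$position, gs$sites$cut)
  got <- res$sites[match(gs$sites$cut, res$sites$position), ]
  expect_equal(got$read_count, gs$sites$read_count)
  n_on <- sum(vapply(res$records, `[[`, logical(1), "is_on_target"))
  expect_equal(n_on, 1)
})
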