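# Amplicon/read/genome simulators: postconditions, determinism, composition.

test_that("make_amplicon plants a unique NGG guide with flanks and is deterministic", {
  d <- make_amplicon(250, 0.5, seed = 1)
  expect_equal(nchar(d$sequence), 250)
  expect_equal(nchar(d$guide$protospacer), 20)
  expect_match(d$guide$pam, "^[ACGT]GG$")
  # planted exactly once, with >= 25 nt flanks
  occ <- gregexpr(d$guide$protospacer, d$sequence, fixed = TRUE)[[1]]
  expect_length(occ, 1)
  expect_gte(d$guide$protospacer_start, 25)
  expect_lte(d$guide$protospacer_start + 23, 250 - 25)
  expect_silent(validate_guide(d$guide, d))
  # determinism
  d2 <- make_amplicon(250, 0.5, seed = 1)
  expect_identical(d, d2)
  expect_false(identical(d$sequence, make_amplicon(250, 0.5, seed = 2)$sequence))
})

test_that("make_amplicon rejects amplicons too short for the flanks", {
  expect_error(make_amplicon(79, 0.5, seed = 1), "at least 80")
})

test_that("error-free unedited simulation reproduces the reference exactly", {
  d <- fixture_design()
  sc <- scenario_spec(edit_fraction = 0, n_reads = 50, error_rate = 0, seed = 3)
  sim <- simulate_reads(d, d$guide, sc)
  expect_length(sim$reads, 50)
  expect_true(all(sim$reads == d$sequence))
  expect_true(all(!sim$truth$edited))
  expect_equal(nrow(sim$truth), 50)
})

test_that("edited-read count equals the seeded Bernoulli draw of the generator contract", {
  d <- fixture_design()
  sc <- scenario_spec(edit_fraction = 0.5, n_reads = 10, error_rate = 0, seed = 11)
  sim <- simulate_reads(d, d$guide, sc)
  # independent re-draw following the documented contract: with a single
  # template the origin draw is skipped and edited flags are runif(n) < e
  expected <- local({
    set.seed(11L)
    runif(10) < 0.5
  })
  expect_identical(sim$truth$edited, expected)
  # determinism: same seed, byte-identical reads and truth
  sim2 <- simulate_reads(d, d$guide, sc)
  expect_identical(sim, sim2)
})

test_that("every edited read carries an indel covering the cut site", {
  d <- fixture_design()
  cs <- cut_site(d$guide, d)
  sc <- scenario_spec(edit_fraction = 0.6, n_reads = 300, error_rate = 0, seed = 4)
  sim <- simulate_reads(d, d$guide, sc)
  edited <- sim$truth[sim$truth$edited, ]
  expect_gt(nrow(edited), 0)
  covers <- vapply(strsplit(edited$events, ";"), function(evs) {
    any(vapply(evs, function(e) {
      f <- strsplit(e, ":")[[1]]
      if (f[1] == "del") {
        s <- as.integer(f[2]); l <- as.integer(f[3])
        s < cs + 1 && s + l > cs - 1
      } else if (f[1] == "ins") {
        as.integer(f[2]) == cs
      } else FALSE
    }, logical(1)))
  }, logical(1))
  expect_true(all(covers))
  # unedited reads carry no indel events
  unedited <- sim$truth[!sim$truth$edited, ]
  expect_false(any(grepl("del:|ins:", unedited$events)))
})

test_that("truth origins tally to the drawn mixture and homolog fraction is recovered", {
  d <- fixture_design()
  cs <- cut_site(d$guide, d)
  offs <- c(-7L, 4L)
  alts <- vapply(offs, function(o) {
    setdiff(c("A", "C", "G", "T"), substr(d$sequence, cs + o + 1, cs + o + 1))[1]
  }, character(1))
  sc <- scenario_spec(n_reads = 2000, error_rate = 0, seed = 5,
                      homolog = list(freq = 0.216,
                                     substitutions = data.frame(offset = offs,
                                                                alt = alts)))
  sim <- simulate_reads(d, d$guide, sc)
  tally <- table(sim$truth$origin)
  expect_equal(sum(tally), 2000)
  hfrac <- tally[["homolog"]] / 2000
  expect_lt(abs(hfrac - 0.216), 4 * sqrt(0.216 * 0.784 / 2000))
  # homolog reads carry exactly the haplotype substitutions
  hom_reads <- sim$reads[sim$truth$origin == "homolog" & !sim$truth$edited]
  expect_true(all(hom_reads == hom_reads[1]))
  expect_equal(dualwindow:::hamming(hom_reads[[1]], d$sequence), 2)
})

test_that("a paralog identical to the primary template raises a warning, not an error", {
  d <- fixture_design()
  sc <- scenario_spec(n_reads = 10, error_rate = 0, seed = 1,
                      paralogs = list(list(weight = 0.3, sequence = d$sequence)))
  expect_warning(simulate_reads(d, d$guide, sc), "identical to the primary")
})

test_that("paired samples share variation structure and only the treated is edited", {
  d <- fixture_design()
  sc <- scenario_spec(n_reads = 500, error_rate = 0, seed = 6)
  pair <- simulate_paired_samples(d, d$guide, sc, 0.41)
  expect_true(all(!pair$control$truth$edited))
  efrac <- mean(pair$treated$truth$edited)
  expect_lt(abs(efrac - 0.41), 4 * sqrt(0.41 * 0.59 / 500))
  aee_c <- quantify_edits(pair$control$reads, d, d$guide, 2)$aee
  aee_t <- quantify_edits(pair$treated$reads, d, d$guide, 2)$aee
  expect_equal(aee_c, 0)
  expect_lt(abs(aee_t - mean(pair$treated$truth$edited)), 1e-9)
})

test_that("guideseq simulator plants the promised reads and is byte-deterministic", {
  sites <- data.frame(position = c(2000L, 6000L), strand = c("+", "-"),
                      mismatches = c(0L, 3L), read_count = c(40L, 5L))
  gs <- simulate_guideseq(8000, sites, read_length = 100,
                          n_background = 100, seed = 7)
  expect_equal(nrow(gs$sites), 2)
  expect_equal(gs$sites$read_count, c(40L, 5L))
  expect_equal(sum(gs$read_truth$origin == "site_1"), 40)
  # no planted sites -> no dsODN-containing reads
  gs0 <- simulate_guideseq(8000, NULL, read_length = 100,
                           n_background = 50, seed = 8)
  hits <- Biostrings::vcountPattern(gs0$dsodn,
                                    Biostrings::DNAStringSet(gs0$reads)) +
    Biostrings::vcountPattern(dualwindow:::revcomp(gs0$dsodn),
                              Biostrings::DNAStringSet(gs0$reads))
  expect_true(all(hits == 0))
  # same seed -> identical FASTQ bytes
  gs2 <- simulate_guideseq(8000, sites, read_length = 100,
                           n_background = 100, seed = 7)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(gs$reads, f1); write_fastq(gs2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # too close to the edge
  expect_error(simulate_guideseq(8000, data.frame(position = 10L, strand = "+",
                                                  mismatches = 0L,
                                                  read_count = 5L), seed = 1),
               "edge")
})

test_that("expression/editing simulator hits its rank-correlation target", {
  tab <- simulate_expression_editing_table(400, 0.25, seed = 9)
  expect_equal(dim(tab$counts), c(400L, 6L))
  et <- normalize_counts(tab$counts)
  r <- correlate_expression_editing(
    et, data.frame(gene = tab$editing$gene, aee2 = tab$editing$true_efficiency))
  expect_lt(abs(r$correlation$rho - 0.25), 0.12)
  # null case across seeds
  rhos <- vapply(1:10, function(s) {
    t0 <- simulate_expression_editing_table(100, 0, seed = s)
    spearman_cor(rowMeans(t0$counts), t0$editing$true_efficiency)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
  expect_error(simulate_expression_editing_table(3, 0.2, seed = 1), "at least 5")
  expect_error(simulate_expression_editing_table(50, 1.2, seed = 1),
               "correlation_target")
})
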