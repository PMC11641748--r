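# Artifact classification from control/treated allele tables.

# Build dual-window result + allele tables for a simulated locus.
locus_inputs <- function(loc) {
  list(dual = dual_window_aee(loc$control$reads, loc$amplicon, loc$guide),
       control = allele_table(loc$control$reads, loc$amplicon, loc$guide),
       treated = allele_table(loc$treated$reads, loc$amplicon, loc$guide))
}

test_that("the three study signatures classify as SNP, DIVERGENT_HOMOLOG and REPEAT", {
  d <- fixture_design(seed = 7)
  cs <- cut_site(d$guide, d)

  # SNP-like locus: several moderate substitution carriers flanking the cut
  offs <- c(-9L, -6L, -4L, 3L, 5L, 7L, 8L, 9L)
  alts <- vapply(offs, function(o) {
    setdiff(c("A", "C", "G", "T"), substr(d$sequence, cs + o + 1, cs + o + 1))[1]
  }, character(1))
  sc_snp <- scenario_spec(n_reads = 800, error_rate = 0.001, seed = 60,
                          snps = data.frame(offset = offs, alt = alts,
                                            freq = rep(0.25, 8)))
  pair <- simulate_paired_samples(d, d$guide, sc_snp, 0.3)
  at_c <- allele_table(pair$control$reads, d, d$guide)
  dw_c <- dual_window_aee(pair$control$reads, d, d$guide)
  call_snp <- classify_locus(dw_c, at_c,
                             allele_table(pair$treated$reads, d, d$guide))
  expect_equal(call_snp$label, "SNP")
  expect_gt(call_snp$evidence$control_delta_pp, 10)

  # divergent-homolog locus: one substitution-only haplotype at 21.6%
  hoffs <- c(-7L, 4L, 8L)
  halts <- vapply(hoffs, function(o) {
    setdiff(c("A", "C", "G", "T"), substr(d$sequence, cs + o + 1, cs + o + 1))[1]
  }, character(1))
  sc_hom <- scenario_spec(n_reads = 800, error_rate = 0.001, seed = 61,
                          homolog = list(freq = 0.216,
                                         substitutions = data.frame(
                                           offset = hoffs, alt = halts)))
  pair_h <- simulate_paired_samples(d, d$guide, sc_hom, 0.1)
  inp_h <- list(dual = dual_window_aee(pair_h$control$reads, d, d$guide),
                control = allele_table(pair_h$control$reads, d, d$guide),
                treated = allele_table(pair_h$treated$reads, d, d$guide))
  call_hom <- classify_locus(inp_h$dual, inp_h$control, inp_h$treated)
  expect_equal(call_hom$label, "DIVERGENT_HOMOLOG")
  expect_lt(abs(call_hom$evidence$control_allele_freq - 0.216), 0.06)

  # repeat locus: paralog with an indel inside the narrow window
  p1 <- delete_at(substitute_at(d$sequence, cs - 15L), cs - 1L, 2L)
  sc_rep <- scenario_spec(n_reads = 800, error_rate = 0.001, seed = 62,
                          paralogs = list(list(weight = 0.3, sequence = p1)))
  pair_r <- simulate_paired_samples(d, d$guide, sc_rep, 0.2)
  dw_r <- dual_window_aee(pair_r$control$reads, d, d$guide)
  call_rep <- classify_locus(dw_r, allele_table(pair_r$control$reads, d, d$guide),
                             allele_table(pair_r$treated$reads, d, d$guide))
  expect_equal(call_rep$label, "REPEAT")
  expect_gt(dw_r$aee2, classifier_params()$noise_floor)
})

test_that("a clean control is NO_ARTIFACT and labels ignore allele row order", {
  loc <- simulate_variation_locus("NO_ARTIFACT", seed = 70)
  inp <- locus_inputs(loc)
  call <- classify_locus(inp$dual, inp$control, inp$treated)
  expect_equal(call$label, "NO_ARTIFACT")

  loc2 <- simulate_variation_locus("SNP", seed = 71)
  inp2 <- locus_inputs(loc2)
  base_label <- classify_locus(inp2$dual, inp2$control, inp2$treated)$label
  set.seed(72)
  for (i in 1:3) {
    perm <- inp2$control[sample(nrow(inp2$control)), , drop = FALSE]
    attributes(perm)[c("cut_site", "report_span", "n_aligned")] <-
      attributes(inp2$control)[c("cut_site", "report_span", "n_aligned")]
    class(perm) <- class(inp2$control)
    expect_equal(classify_locus(inp2$dual, perm, inp2$treated)$label,
                 base_label)
  }
})

test_that("mismatched allele-table spans are rejected", {
  loc <- simulate_variation_locus("NO_ARTIFACT", seed = 73)
  at_c <- allele_table(loc$control$reads, loc$amplicon, loc$guide,
                       report_span = 40)
  at_t <- allele_table(loc$treated$reads, loc$amplicon, loc$guide,
                       report_span = 30)
  dw <- dual_window_aee(loc$control$reads, loc$amplicon, loc$guide)
  expect_error(classify_locus(dw, at_c, at_t), "span")
  expect_error(corrected_efficiency(at_t, at_c), "span")
})

test_that("corrected efficiency removes control-shared alleles only", {
  d <- fixture_design(seed = 8)
  cs <- cut_site(d$guide, d)
  # planted: e = 0.10 true edits on top of a 0.49 SNP carrier at -8
  alt <- setdiff(c("A", "C", "G", "T"), substr(d$sequence, cs - 7L, cs - 7L))[1]
  sc <- scenario_spec(n_reads = 2000, error_rate = 0, seed = 80,
                      snps = data.frame(offset = -8L, alt = alt, freq = 0.49))
  pair <- simulate_paired_samples(d, d$guide, sc, 0.10)
  at_c <- allele_table(pair$control$reads, d, d$guide)
  at_t <- allele_table(pair$treated$reads, d, d$guide)
  uncorrected <- dual_window_aee(pair$treated$reads, d, d$guide)$aee20
  corrected <- corrected_efficiency(at_t, at_c)
  true_e <- mean(pair$treated$truth$edited)
  expect_gt(uncorrected, 0.45) # SNP inflates the wide window
  expect_lt(abs(corrected - true_e), 0.02)
  expect_lte(corrected, uncorrected)

  # no shared alleles -> corrected equals uncorrected
  sc2 <- scenario_spec(edit_fraction = 0, n_reads = 300, error_rate = 0,
                       seed = 81)
  pair2 <- simulate_paired_samples(d, d$guide, sc2, 0.35)
  at_c2 <- allele_table(pair2$control$reads, d, d$guide)
  at_t2 <- allele_table(pair2$treated$reads, d, d$guide)
  expect_equal(corrected_efficiency(at_t2, at_c2),
               dual_window_aee(pair2$treated$reads, d, d$guide)$aee20)

  # all treated modified alleles present in the control -> corrected 0
  expect_equal(corrected_efficiency(at_c, at_c), 0)
})

test_that("classification_report builds a 5x5 confusion matrix and accuracy", {
  labels <- c("SNP", "REPEAT", "NO_ARTIFACT")
  rep1 <- classification_report(labels, labels)
  expect_equal(rep1$accuracy, 1)
  expect_equal(dim(rep1$confusion), c(5L, 5L))
  expect_equal(sum(rep1$confusion), 3)
  rep2 <- classification_report(c("SNP", "SNP"), c("SNP", "REPEAT"))
  expect_equal(rep2$accuracy, 0.5)
  expect_error(classification_report(character(0), character(0)), "no calls")
  expect_error(classification_report(c("SNP"), c("SNP", "REPEAT")), "length")
})
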