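# Seeded amplicon read simulator with per-read ground truth.

#' Simulate amplicon reads under a scenario
#'
#' Emits `n_reads` full-length amplicon reads (single merged-read model) and
#' one truth record per read. Read origin (primary template, divergent
#' homolog, paralog) is drawn from the scenario mixture; edited flags are
#' drawn as independent Bernoulli(`edit_fraction`) draws immediately after
#' the origin draw, so the number of edited truths is the seeded binomial
#' draw. Edited reads receive one NHEJ indel whose reference interval (or
#' insertion anchor) covers the cut site; SNP carriers (primary-template
#' reads only) receive their substitutions; every read is then subjected to
#' uniform substitution sequencing error.
#'
#' @param amplicon Amplicon design (from [make_amplicon()]) or sequence.
#' @param guide A [guide_spec()] matching the amplicon.
#' @param scenario A [scenario_spec()].
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `origin`, `edited`, `events`).
#' @export
simulate_reads <- function(amplicon, guide, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  ref <- amp_seq(amplicon)
  cut <- cut_site(guide, amplicon)
  n <- scenario$n_reads

  # resolve templates
  templates <- list(primary = ref)
  weights <- c(primary = 1)
  if (!is.null(scenario$homolog)) {
    h <- scenario$homolog
    hseq <- h$sequence
    if (is.null(hseq)) {
      hsub <- data.frame(pos = cut + h$substitutions$offset,
                         alt = h$substitutions$alt)
      hseq <- apply_variants(ref, subs = hsub)
    }
    templates$homolog <- toupper(hseq)
    weights <- c(weights, homolog = h$freq)
    weights["primary"] <- weights["primary"] - h$freq
  }
  if (!is.null(scenario$paralogs)) {
    for (i in seq_along(scenario$paralogs)) {
      p <- scenario$paralogs[[i]]
      nm <- paste0("paralog_", i)
      if (toupper(p$sequence) == ref) {
        warning(sprintf("%s is identical to the primary template", nm))
      }
      templates[[nm]] <- toupper(p$sequence)
      weights <- c(weights, setNames(p$weight, nm))
      weights["primary"] <- weights["primary"] - p$weight
    }
  }

  snps <- scenario$snps
  spectrum <- scenario$indel_spectrum
  err <- scenario$error_rate

  with_seed(scenario$seed, {
    origins <- if (length(templates) > 1L) {
      sample(names(templates), n, replace = TRUE, prob = weights)
    } else {
      rep("primary", n)
    }
    edited <- runif(n) < scenario$edit_fraction

    reads <- character(n)
    events <- character(n)
    for (i in seq_len(n)) {
      seqi <- templates[[origins[i]]]
      ev <- character(0)
      if (origins[i] == "primary" && !is.null(snps) && nrow(snps) > 0L) {
        carry <- runif(nrow(snps)) < snps$freq
        for (j in which(carry)) {
          pos <- cut + snps$offset[j]
          seqi <- sub_base(seqi, pos, snps$alt[j])
          ev <- c(ev, sprintf("sub:%d:%s", pos, snps$alt[j]))
        }
      }
      if (edited[i]) {
        ind <- sample_indel(spectrum, cut, seqi)
        if (ind$kind == "deletion") {
          seqi <- apply_variants(seqi, deletion = c(ind$start, ind$length))
          ev <- c(ev, sprintf("del:%d:%d", ind$start, ind$length))
        } else {
          seqi <- apply_variants(seqi,
                                 insertion = list(pos = ind$start, alt = ind$alt))
          ev <- c(ev, sprintf("ins:%d:%s", ind$start, ind$alt))
        }
      }
      if (err > 0) {
        nerr <- rbinom(1L, nchar(seqi), err)
        if (nerr > 0L) {
          pos <- sample.int(nchar(seqi), nerr)
          for (p in pos) {
            base <- substr(seqi, p, p)
            seqi <- sub_base(seqi, p - 1L, other_base(base))
            ev <- c(ev, sprintf("err:%d", p - 1L))
          }
        }
      }
      reads[i] <- seqi
      events[i] <- paste(ev, collapse = ";")
    }
    ids <- sprintf("read_%06d", seq_len(n))
    list(reads = setNames(reads, ids),
         truth = data.frame(read_id = ids, origin = origins,
                            edited = edited, events = events,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a paired sgRNA-free control and treated sample
#'
#' Both samples share the identical variation structure (SNPs, homolog,
#' paralogs, error rate, read depth); only the treated sample contains
#' edited reads. The control is the base scenario with `edit_fraction = 0`;
#' the treated sample uses a seed derived from the base seed.
#'
#' @inheritParams simulate_reads
#' @param base_scenario A [scenario_spec()]; its `edit_fraction` is ignored.
#' @param treated_edit_fraction True edited fraction of the treated sample.
#' @return List with `control` and `treated`, each as from
#'   [simulate_reads()].
#' @export
simulate_paired_samples <- function(amplicon, guide, base_scenario,
                                    treated_edit_fraction) {
  stopifnot(inherits(base_scenario, "scenario_spec"))
  control_sc <- base_scenario
  control_sc$edit_fraction <- 0
  treated_sc <- base_scenario
  treated_sc$edit_fraction <- treated_edit_fraction
  treated_sc$seed <- derive_seed(base_scenario$seed, 777L)
  list(control = simulate_reads(amplicon, guide, control_sc),
       treated = simulate_reads(amplicon, guide, treated_sc))
}

#' Simulate a locus with a planted genetic-variation class
#'
#' Generates an amplicon plus paired control/treated samples whose control
#' allele structure carries one of the four planted classes used to
#' validate the artifact classifier: `NO_ARTIFACT` (clean editing), `SNP`
#' (several moderate-frequency substitution carriers flanking the cut),
#' `DIVERGENT_HOMOLOG` (one substitution-only haplotype at 20-35%) or
#' `REPEAT` (co-amplified paralogs with indel-like divergence, half the
#' time overlapping the narrow window).
#'
#' @param class One of `"NO_ARTIFACT"`, `"SNP"`, `"DIVERGENT_HOMOLOG"`,
#'   `"REPEAT"`.
#' @param seed Integer seed.
#' @param n_reads Reads per sample.
#' @param amplicon_length Amplicon length in nt.
#' @param error_rate Sequencing error rate.
#' @return List with `amplicon`, `guide`, `control`, `treated`,
#'   `truth_class` and the sampled `params`.
#' @export
simulate_variation_locus <- function(class = c("NO_ARTIFACT", "SNP",
                                               "DIVERGENT_HOMOLOG", "REPEAT"),
                                     seed = 1L, n_reads = 400L,
                                     amplicon_length = 160L,
                                     error_rate = 0.001) {
  class <- match.arg(class)
  design <- make_amplicon(amplicon_length, 0.5, seed = derive_seed(seed, 11L))
  guide <- design$guide
  ref <- design$sequence
  cut <- cut_site(guide, design)

  # offsets inside the wide window but outside the narrow one
  wide_offsets <- setdiff(-10:9, c(-1L, 0L))

  params <- with_seed(derive_seed(seed, 23L), {
    switch(class,
      NO_ARTIFACT = list(treated_e = runif(1, 0.2, 0.6)),
      SNP = list(
        offsets = sort(sample(wide_offsets, 8L)),
        freqs = runif(8L, 0.2, 0.3),
        treated_e = runif(1, 0.2, 0.5)),
      DIVERGENT_HOMOLOG = list(
        offsets = sort(sample(wide_offsets, 3L)),
        freq = runif(1, 0.2, 0.35),
        treated_e = runif(1, 0.05, 0.15)),
      REPEAT = {
        flavor <- if (runif(1) < 0.6) "narrow" else "wide_only"
        if (flavor == "narrow") {
          list(flavor = flavor,
               weight = runif(1, 0.15, 0.5),
               treated_e = runif(1, 0.1, 0.3))
        } else {
          list(flavor = flavor,
               weights = runif(2, 0.12, 0.3),
               treated_e = runif(1, 0.1, 0.3))
        }
      })
  })

  base <- switch(class,
    NO_ARTIFACT = scenario_spec(n_reads = n_reads, error_rate = error_rate,
                                seed = derive_seed(seed, 31L)),
    SNP = {
      alts <- with_seed(derive_seed(seed, 37L), {
        vapply(params$offsets, function(o) {
          other_base(substr(ref, cut + o + 1L, cut + o + 1L))
        }, character(1))
      })
      scenario_spec(n_reads = n_reads, error_rate = error_rate,
                    seed = derive_seed(seed, 31L),
                    snps = data.frame(offset = params$offsets, alt = alts,
                                      freq = params$freqs))
    },
    DIVERGENT_HOMOLOG = {
      alts <- with_seed(derive_seed(seed, 37L), {
        vapply(params$offsets, function(o) {
          other_base(substr(ref, cut + o + 1L, cut + o + 1L))
        }, character(1))
      })
      scenario_spec(n_reads = n_reads, error_rate = error_rate,
                    seed = derive_seed(seed, 31L),
                    homolog = list(freq = params$freq,
                                   substitutions = data.frame(
                                     offset = params$offsets, alt = alts)))
    },
    REPEAT = {
      paralogs <- with_seed(derive_seed(seed, 37L), {
        if (params$flavor == "narrow") {
          sub_pos <- cut + sample(c(-20:-12, 12:20), 2L)
          p1 <- apply_variants(ref,
                               subs = data.frame(pos = sub_pos,
                                                 alt = vapply(sub_pos, function(p) {
                                                   other_base(substr(ref, p + 1L, p + 1L))
                                                 }, character(1))),
                               deletion = c(cut - 1L, 2L))
          list(list(weight = params$weight, sequence = p1))
        } else {
          p1 <- apply_variants(ref, deletion = c(cut + 3L, 2L))
          p2 <- apply_variants(ref, deletion = c(cut - 7L, 3L))
          list(list(weight = params$weights[1], sequence = p1),
               list(weight = params$weights[2], sequence = p2))
        }
      })
      scenario_spec(n_reads = n_reads, error_rate = error_rate,
                    seed = derive_seed(seed, 31L), paralogs = paralogs)
    })

  pair <- simulate_paired_samples(design, guide, base, params$treated_e)
  list(amplicon = design, guide = guide, control = pair$control,
       treated = pair$treated, truth_class = class, params = params)
}
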