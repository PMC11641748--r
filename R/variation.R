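# Rule-based classification of false-editing artifacts from control and
# treated allele tables.

#' Classifier parameters
#'
#' @param noise_floor Allele/AEE frequency separating sequencing error from
#'   genetic variation (fraction of aligned reads).
#' @param major_floor Frequency above which a single substitution-only
#'   control allele is treated as a major divergent haplotype.
#' @param freq_tol Control/treated allele frequency match tolerance
#'   (fraction, i.e. 0.10 = 10 percentage points).
#' @param min_allele_freq Alleles below this frequency are ignored when
#'   judging allele families (single-read error alleles).
#' @return A parameter list.
#' @export
classifier_params <- function(noise_floor = 0.02, major_floor = 0.10,
                              freq_tol = 0.10, min_allele_freq = 0.005) {
  list(noise_floor = noise_floor, major_floor = major_floor,
       freq_tol = freq_tol, min_allele_freq = min_allele_freq)
}

VARIATION_LABELS <- c("NO_ARTIFACT", "SNP", "DIVERGENT_HOMOLOG", "REPEAT",
                      "UNCLASSIFIED")

#' Classify a locus into a genetic-variation artifact type
#'
#' Applies ordered decision rules to the sgRNA-free control dual-window
#' result and the control/treated allele tables:
#' 1. `NO_ARTIFACT` if the control discrepancy is within the threshold and
#'    the control narrow-window AEE is at the noise floor;
#' 2. `REPEAT` if the control shows narrow-window "editing" without any
#'    sgRNA (AEE2 above the noise floor) or at least two distinct modified
#'    control allele families with indel-like differences;
#' 3. `DIVERGENT_HOMOLOG` if exactly one substitution-only control allele
#'    exceeds the major-allele floor and a treated allele with the same
#'    spanning sequence matches its frequency within tolerance;
#' 4. `SNP` if the control's modified alleles are substitution-only, each
#'    below the major-allele floor, collectively above the noise floor;
#' 5. otherwise `UNCLASSIFIED`.
#'
#' The label depends only on allele content, never on table row order.
#' Whether a divergent haplotype sits on a sex chromosome cannot be decided
#' from amplicon data; the label reports the allele pattern only.
#'
#' @param control_dual `dual_window_result` of the sgRNA-free control.
#' @param control_alleles,treated_alleles [allele_table()]s built with the
#'   same guide and report span (`treated_alleles` may be `NULL` for a
#'   control-only run; rule 3 then cannot fire).
#' @param threshold `threshold_spec` or percentage points (default 10).
#' @param params See [classifier_params()].
#' @return List of class `variation_call` with `label` and `evidence`.
#' @export
classify_locus <- function(control_dual, control_alleles,
                           treated_alleles = NULL,
                           threshold = fixed_threshold(10),
                           params = classifier_params()) {
  stopifnot(inherits(control_dual, "dual_window_result"))
  thr <- threshold_value(threshold)
  if (!is.null(treated_alleles)) {
    if (!identical(attr(control_alleles, "report_span"),
                   attr(treated_alleles, "report_span")) ||
        !identical(attr(control_alleles, "cut_site"),
                   attr(treated_alleles, "cut_site"))) {
      stop("control and treated allele tables were built with different spans")
    }
  }

  ca <- as.data.frame(control_alleles)
  ca <- ca[ca$modified & ca$frequency >= params$min_allele_freq, , drop = FALSE]

  evidence <- list(control_aee2 = control_dual$aee2,
                   control_aee20 = control_dual$aee20,
                   control_delta_pp = control_dual$delta_pp,
                   n_modified_control_alleles = nrow(ca))

  call <- function(label, ...) {
    structure(list(label = label,
                   evidence = c(evidence, list(...))), class = "variation_call")
  }

  # 1. concordant control with clean narrow window
  if (control_dual$delta_pp <= thr && control_dual$aee2 <= params$noise_floor) {
    return(call("NO_ARTIFACT"))
  }

  # 2. repeats: narrow-window false editing, or >= 2 indel allele families
  indel_families <- ca[ca$has_indel & ca$frequency >= params$noise_floor, ,
                       drop = FALSE]
  if (control_dual$aee2 > params$noise_floor || nrow(indel_families) >= 2L) {
    return(call("REPEAT",
                narrow_window_false_editing = control_dual$aee2 > params$noise_floor,
                indel_allele_freqs = indel_families$frequency))
  }

  # 3. single major substitution-only haplotype mirrored in the treated sample
  majors <- ca[ca$sub_only & ca$frequency > params$major_floor, , drop = FALSE]
  if (nrow(majors) == 1L && !is.null(treated_alleles)) {
    ta <- as.data.frame(treated_alleles)
    match_row <- ta[ta$aligned_sequence == majors$aligned_sequence, ,
                    drop = FALSE]
    if (nrow(match_row) == 1L &&
        abs(match_row$frequency - majors$frequency) <= params$freq_tol) {
      return(call("DIVERGENT_HOMOLOG",
                  control_allele_freq = majors$frequency,
                  treated_allele_freq = match_row$frequency,
                  note = "substitution-only haplotype; chromosomal origin not determinable from amplicon data"))
    }
  }

  # 4. many minor substitution-only alleles
  if (nrow(ca) > 0L && all(ca$sub_only) &&
      all(ca$frequency < params$major_floor) &&
      sum(ca$frequency) > params$noise_floor) {
    return(call("SNP",
                n_substitution_alleles = nrow(ca),
                total_substitution_freq = sum(ca$frequency)))
  }

  call("UNCLASSIFIED")
}

#' Control-corrected editing efficiency
#'
#' Treated modified-read fraction after excluding alleles whose spanning
#' sequence also occurs in the sgRNA-free control above the noise floor
#' (pre-existing variation, not editing). Never exceeds the uncorrected
#' AEE of the same window.
#'
#' @param treated_alleles,control_alleles [allele_table()]s built with the
#'   same guide and span.
#' @param params See [classifier_params()].
#' @return Corrected modified-read fraction in `[0, 1]`.
#' @export
corrected_efficiency <- function(treated_alleles, control_alleles,
                                 params = classifier_params()) {
  if (!identical(attr(control_alleles, "report_span"),
                 attr(treated_alleles, "report_span")) ||
      !identical(attr(control_alleles, "cut_site"),
                 attr(treated_alleles, "cut_site"))) {
    stop("allele tables were built with different spans")
  }
  ca <- as.data.frame(control_alleles)
  shared <- ca$aligned_sequence[ca$frequency > params$noise_floor]
  ta <- as.data.frame(treated_alleles)
  sum(ta$frequency[ta$modified & !(ta$aligned_sequence %in% shared)])
}

#' Confusion matrix and accuracy of classifier calls
#'
#' @param calls List of `variation_call`s (or character labels).
#' @param truth Character vector of planted classes, same length.
#' @return List with `confusion` (5x5 matrix, truth in rows) and
#'   `accuracy`.
#' @export
classification_report <- function(calls, truth) {
  if (length(calls) == 0L) stop("no calls to score")
  labels <- if (is.character(calls)) calls else
    vapply(calls, function(x) x$label, character(1))
  if (length(labels) != length(truth)) stop("calls and truth differ in length")
  confusion <- table(factor(truth, levels = VARIATION_LABELS),
                     factor(labels, levels = VARIATION_LABELS))
  list(confusion = unclass(confusion),
       accuracy = sum(diag(confusion)) / length(labels))
}
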