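# Dual-window AEE contrast, threshold derivation and grouping.

#' Construct a dual-window result from known AEE values
#'
#' Used when the two AEEs are already known (e.g. from a published report or
#' an external quantification) rather than recomputed from reads.
#'
#' @param aee2,aee20 AEE in the narrow and wide windows, in `[0, 1]`.
#' @return An object of class `dual_window_result` with `aee2`, `aee20` and
#'   `delta_pp` (percentage points, `100 * (aee20 - aee2)`).
#' @export
dual_window_result <- function(aee2, aee20) {
  stopifnot(aee2 >= 0, aee2 <= 1, aee20 >= 0, aee20 <= 1)
  structure(list(aee2 = aee2, aee20 = aee20,
                 delta_pp = 100 * (aee20 - aee2)),
            class = "dual_window_result")
}

#' Dual-window AEE of a read set
#'
#' Computes the AEE in the narrow and wide quantification windows on the
#' same aligned read partition (one alignment pass) and the discrepancy in
#' percentage points. By window nesting the wide-window AEE can never fall
#' below the narrow one, so `delta_pp >= 0` always holds; this is asserted.
#'
#' @inheritParams quantify_edits
#' @param widths Two even window widths, ascending (default `c(2, 20)`).
#' @return A `dual_window_result`; the per-window `aee_result`s are attached
#'   as `results`.
#' @export
dual_window_aee <- function(reads, amplicon, guide, widths = c(2L, 20L),
                            scoring = default_scoring()) {
  widths <- as.integer(widths)
  if (length(widths) != 2L || widths[1] >= widths[2]) {
    stop("widths must be two ascending window widths")
  }
  cut <- cut_site(guide, amplicon)
  aset <- align_read_set(reads, amplicon, scoring)
  r_narrow <- quantify_from_aset(aset, cut, widths[1])
  r_wide <- quantify_from_aset(aset, cut, widths[2])
  stopifnot(r_wide$aee >= r_narrow$aee)
  out <- dual_window_result(r_narrow$aee, r_wide$aee)
  out$results <- list(narrow = r_narrow, wide = r_wide)
  out
}

#' @export
print.dual_window_result <- function(x, ...) {
  cat(sprintf("AEE narrow %.4f | wide %.4f | discrepancy %.2f pp\n",
              x$aee2, x$aee20, x$delta_pp))
  invisible(x)
}

# Accept a threshold as a number or threshold_spec.
threshold_value <- function(threshold) {
  v <- if (inherits(threshold, "threshold_spec")) threshold$value_pp else threshold
  if (!is.numeric(v) || length(v) != 1L || v <= 0) {
    stop("threshold must be a positive number of percentage points")
  }
  v
}

#' Derive the discrepancy threshold from positive controls
#'
#' The threshold is the largest narrow-vs-wide discrepancy (in percentage
#' points) observed across the positive-control results, rounded to the
#' nearest integer percentage point. Applied to the positive control of the
#' study this rule yields 10 pp (40.97% vs 51.09%).
#'
#' @param controls A list of `dual_window_result`s (or a data.frame with
#'   columns `aee2` and `aee20`).
#' @param digits Rounding digits for the derived value (default 0).
#' @return An object of class `threshold_spec` with `value_pp` and
#'   `provenance = "derived"`.
#' @export
derive_threshold <- function(controls, digits = 0L) {
  if (is.data.frame(controls)) {
    deltas <- 100 * (controls$aee20 - controls$aee2)
  } else {
    if (inherits(controls, "dual_window_result")) controls <- list(controls)
    if (length(controls) == 0L) stop("at least one control result is required")
    deltas <- vapply(controls, function(x) x$delta_pp, numeric(1))
  }
  if (length(deltas) == 0L) stop("at least one control result is required")
  value <- round(max(deltas), digits)
  if (value <= 0) stop("degenerate threshold: control discrepancies round to 0 pp")
  structure(list(value_pp = value, provenance = "derived"),
            class = "threshold_spec")
}

#' Fixed threshold specification
#'
#' @param value_pp Positive threshold in percentage points (study value: 10).
#' @return A `threshold_spec` with `provenance = "fixed"`.
#' @export
fixed_threshold <- function(value_pp = 10) {
  if (value_pp <= 0) stop("threshold must be > 0 pp")
  structure(list(value_pp = value_pp, provenance = "fixed"),
            class = "threshold_spec")
}

#' Group sgRNAs by dual-window discrepancy
#'
#' Splits sgRNAs into a concordant group (`delta_pp <= threshold`, boundary
#' inclusive) and a discordant group (`delta_pp > threshold`).
#'
#' @param results List of `dual_window_result`s or a data.frame with
#'   `aee2`/`aee20` (an optional `sgrna_id` column labels the output).
#' @param threshold A `threshold_spec` or a number in percentage points.
#' @return A list with `labels` (per-sgRNA data.frame), `n_below`,
#'   `n_above` and `fraction_below` (`NA` when empty).
#' @export
group_sgrnas <- function(results, threshold) {
  thr <- threshold_value(threshold)
  if (is.data.frame(results)) {
    ids <- results$sgrna_id %||% sprintf("sgRNA_%d", seq_len(nrow(results)))
    deltas <- 100 * (results$aee20 - results$aee2)
  } else {
    ids <- names(results) %||% sprintf("sgRNA_%d", seq_along(results))
    deltas <- vapply(results, function(x) x$delta_pp, numeric(1))
  }
  below <- deltas <= thr
  list(labels = data.frame(sgrna_id = ids, delta_pp = deltas,
                           group = ifelse(below, "below", "above"),
                           stringsAsFactors = FALSE),
       n_below = sum(below),
       n_above = sum(!below),
       fraction_below = if (length(deltas) == 0L) NA_real_ else mean(below))
}
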