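# Proportion statistics used by the dual-window analysis.

#' Arcsine square-root transform of proportions
#'
#' Variance-stabilizing transform `asin(sqrt(p))` applied to AEE proportions
#' before parametric tests.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @export
arcsine_transform <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  asin(sqrt(p))
}

#' Levene's test for homogeneity of variance (mean-centered)
#'
#' Computes the Levene W statistic as the one-way ANOVA F of the absolute
#' deviations from each group mean, with a p-value from the
#' F(k - 1, N - k) distribution.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `W`, `p_value`, `df1`, `df2`.
#' @export
levene_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("at least two groups are required")
  }
  n_i <- vapply(groups, length, integer(1))
  if (any(n_i < 2L)) stop("each group needs at least two observations")
  z <- lapply(groups, function(x) abs(x - mean(x)))
  zbar_i <- vapply(z, mean, numeric(1))
  N <- sum(n_i)
  k <- length(groups)
  zbar <- sum(unlist(z)) / N
  ss_between <- sum(n_i * (zbar_i - zbar)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2),
                          numeric(1)))
  if (ss_within == 0) {
    stop("Levene W undefined: zero within-group deviation of absolute residuals")
  }
  W <- ((N - k) / (k - 1)) * ss_between / ss_within
  list(W = W, p_value = pf(W, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1L, df2 = N - k)
}

#' Repeated-measures comparison of the two window AEE distributions
#'
#' Each sgRNA contributes one AEE per window, so the within-subject one-way
#' RM-ANOVA reduces to its two-level special case: F equals the square of
#' the paired t statistic on the (optionally arcsine-transformed) pairs,
#' with p from F(1, n - 1).
#'
#' @param aee2,aee20 Paired AEE vectors (same sgRNAs, both windows).
#' @param transform Apply [arcsine_transform()] first (default `TRUE`).
#' @return List with `F`, `p_value`, `df1`, `df2`, `n`.
#' @export
compare_window_distributions <- function(aee2, aee20, transform = TRUE) {
  if (length(aee2) != length(aee20)) stop("paired vectors must have equal length")
  n <- length(aee2)
  if (n < 3L) stop("at least three paired observations are required")
  x <- if (transform) arcsine_transform(aee2) else aee2
  y <- if (transform) arcsine_transform(aee20) else aee20
  d <- y - x
  if (all(d == 0)) {
    return(list(F = 0, p_value = 1, df1 = 1L, df2 = n - 1L, n = n))
  }
  sdd <- sd(d)
  if (sdd == 0) stop("degenerate pairs: constant non-zero differences")
  t_stat <- mean(d) / (sdd / sqrt(n))
  Fval <- t_stat^2
  list(F = Fval, p_value = pf(Fval, 1, n - 1, lower.tail = FALSE),
       df1 = 1L, df2 = n - 1L, n = n)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; rho is the Pearson correlation of the ranks and
#' the p-value comes from the t approximation with n - 2 degrees of freedom
#' (`stats::cor.test(method = "spearman", exact = FALSE)`).
#'
#' @param x,y Numeric vectors of equal length, n >= 5.
#' @return List with `rho`, `p_value`, `n` (class `correlation_result`).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 5L) stop("at least five observations are required")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    stop("zero variance in ranks")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (p = %.4g, n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}
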