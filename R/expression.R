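# Expression normalization and the editing-efficiency rank correlation.

#' Median-of-ratios normalization with log2 transform
#'
#' Size factors are computed as the median, per replicate, of the ratios of
#' counts to the per-gene geometric mean over replicates (computed on genes
#' with all-positive counts). The normalized expression value per gene is
#' the mean over replicates of `log2(count / size_factor + 1)`. This is a
#' declared stand-in for a regularized log transform: rank-based statistics
#' downstream are insensitive to the monotone difference.
#'
#' @param counts Integer matrix or data.frame, genes x replicates, with
#'   gene ids as rownames.
#' @return List of class `expression_table` with `size_factors` and
#'   `values` (data.frame `gene`, `normalized`).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("at least two replicates are required")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  positive <- rowSums(counts > 0) == ncol(counts)
  if (!any(positive)) stop("no gene with all-positive counts")
  log_geo <- rowMeans(log(counts[positive, , drop = FALSE]))
  size_factors <- apply(counts[positive, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo))
  })
  norm <- sweep(counts, 2, size_factors, "/")
  values <- rowMeans(log2(norm + 1))
  genes <- rownames(counts) %||% paste0("gene_", seq_len(nrow(counts)))
  structure(list(size_factors = size_factors,
                 values = data.frame(gene = genes, normalized = unname(values),
                                     stringsAsFactors = FALSE)),
            class = "expression_table")
}

#' Correlate gene expression with editing efficiency
#'
#' Matches genes by identifier between a normalized expression table and a
#' per-gene narrow-window AEE table and computes the Spearman rank
#' correlation on the matched pairs.
#'
#' @param expression An `expression_table` (from [normalize_counts()]) or a
#'   data.frame with `gene` and `normalized`.
#' @param editing data.frame with columns `gene` and `aee2`.
#' @return List with the `correlation_result`, `pairs` (matched
#'   data.frame) and `unmatched` gene ids.
#' @export
correlate_expression_editing <- function(expression, editing) {
  ex <- if (inherits(expression, "expression_table")) expression$values else expression
  stopifnot(all(c("gene", "normalized") %in% names(ex)),
            all(c("gene", "aee2") %in% names(editing)))
  pairs <- merge(ex, editing, by = "gene")
  if (nrow(pairs) < 5L) {
    stop(sprintf("only %d genes matched; at least 5 are required", nrow(pairs)))
  }
  unmatched <- c(setdiff(ex$gene, pairs$gene), setdiff(editing$gene, pairs$gene))
  res <- spearman_cor(pairs$normalized, pairs$aee2)
  list(correlation = res, pairs = pairs, unmatched = unmatched)
}

#' Simulate a paired expression / editing-efficiency table
#'
#' Draws per-gene expression means on a log-normal scale and
#' negative-binomial counts across replicates (default six, mirroring a
#' three-male/three-female embryo pool), together with per-gene editing
#' efficiencies whose population Spearman correlation with the expression
#' means equals `correlation_target` (Gaussian copula; the Pearson
#' parameter is `2 * sin(pi * rho_s / 6)`).
#'
#' @param n_genes Number of genes (>= 5).
#' @param correlation_target Spearman correlation in `[-1, 1]`.
#' @param n_replicates Replicates per gene.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return List with `counts` (genes x replicates matrix) and `editing`
#'   (data.frame `gene`, `true_efficiency`).
#' @export
simulate_expression_editing_table <- function(n_genes, correlation_target,
                                              n_replicates = 6L,
                                              dispersion = 20,
                                              seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 5L) stop("n_genes must be at least 5")
  if (abs(correlation_target) > 1) stop("correlation_target must be in [-1, 1]")
  rho_p <- 2 * sin(pi * correlation_target / 6)
  with_seed(seed, {
    z1 <- rnorm(n_genes)
    z2 <- rho_p * z1 + sqrt(1 - rho_p^2) * rnorm(n_genes)
    mu <- 2^(6 + 2 * z1)
    counts <- t(vapply(mu, function(m) {
      rnbinom(n_replicates, mu = m, size = dispersion)
    }, numeric(n_replicates)))
    rownames(counts) <- sprintf("gene_%03d", seq_len(n_genes))
    colnames(counts) <- sprintf("rep_%d", seq_len(n_replicates))
    editing <- data.frame(gene = rownames(counts),
                          true_efficiency = pnorm(z2),
                          stringsAsFactors = FALSE)
    list(counts = counts, editing = editing)
  })
}
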