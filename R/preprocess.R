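#' Median-of-ratios size factors
#'
#' The standard RNA-seq normalization: per sample, the median over reference
#' genes of `count / geometric mean across samples`, computed on genes with
#' strictly positive counts in every sample. Identical samples get factors
#' of 1; scaling a sample's counts by `c` scales its factor by `c`.
#'
#' @param counts an [expression_matrix()] with unit counts.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (expression_unit(counts) != "counts")
    stopf("size factors are defined for raw counts")
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable))
    stopf(paste("no gene has positive counts in every sample;",
                "filter samples or use a pseudo-reference workflow"))
  logs <- log(unclass(counts)[usable, , drop = FALSE])
  log_geo <- rowMeans(logs)
  factors <- apply(logs, 2, function(col) exp(stats::median(col - log_geo)))
  names(factors) <- colnames(counts)
  factors
}

#' Normalize counts to a log scale
#'
#' Divides counts by their size factors and applies `log2(x + 1)` — a
#' monotone variance-dampening transform. Because the downstream enrichment
#' scoring is rank-based within each sample, any per-gene-comparable
#' monotone transform yields identical expHRD scores; users with a
#' variance-stabilizing transform from another tool can read its output
#' with `unit = "normalized"` and skip this step. Genes with zero total
#' count are removed.
#'
#' @param counts an [expression_matrix()] with unit counts.
#' @param factors size factors from [size_factors()]; computed when missing.
#' @return an [expression_matrix()] with unit `"normalized"`.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (expression_unit(counts) != "counts")
    stopf("normalize_counts expects raw counts")
  if (is.null(factors)) factors <- size_factors(counts)
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  keep <- rowSums(unclass(counts)) > 0
  values <- log2(sweep(unclass(counts)[keep, , drop = FALSE], 2, factors, `/`) + 1)
  expression_matrix(values, "normalized")
}

#' Differential-expression pre-filter against scar status
#'
#' Splits samples into scar-high (`scar >= threshold`, the conventional
#' positivity cutoff 42 by default) and scar-low groups and runs a per-gene
#' Welch two-sample t-test on normalized values, with Benjamini-Hochberg
#' adjustment. A gene is selected when `adjusted_p <= alpha` and
#' `|effect| >= min_abs_effect`, where effect is the mean difference
#' (high - low) on the log2 scale. This is a pre-filter: the elastic net
#' re-selects features downstream, so the test only needs to rank genes
#' sensibly, not be the final arbiter.
#'
#' @param normalized an [expression_matrix()] with unit `"normalized"`.
#' @param scar named per-sample numeric scar scores.
#' @param threshold scar-high cutoff (inclusive), default 42.
#' @param alpha BH-adjusted significance cutoff, default 0.05.
#' @param min_abs_effect minimal |log2 mean difference|, default 0.
#' @return a `DEGTable` data.frame: `gene`, `effect`, `statistic`,
#'   `p_value`, `adjusted_p`, `selected`.
#' @export
deg_filter <- function(normalized, scar, threshold = 42, alpha = 0.05,
                       min_abs_effect = 0) {
  stopifnot(inherits(normalized, "ExpressionMatrix"))
  if (is.null(names(scar))) stopf("scar scores must be named by sample")
  shared <- intersect(colnames(normalized), names(scar))
  if (length(shared) < 4L) stopf("need at least 4 shared samples")
  x <- unclass(normalized)[, shared, drop = FALSE]
  hi <- scar[shared] >= threshold
  n1 <- sum(hi)
  n0 <- sum(!hi)
  if (n1 < 2L || n0 < 2L)
    stopf("each scar group needs >= 2 samples (high: %d, low: %d)", n1, n0)
  m1 <- rowMeans(x[, hi, drop = FALSE])
  m0 <- rowMeans(x[, !hi, drop = FALSE])
  v1 <- apply(x[, hi, drop = FALSE], 1, stats::var)
  v0 <- apply(x[, !hi, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v0 / n0
  stat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  # constant genes in both groups: no evidence either way
  p[!is.finite(stat)] <- 1
  stat[!is.finite(stat)] <- 0
  adj <- stats::p.adjust(p, method = "BH")
  effect <- m1 - m0
  data.frame(gene = rownames(x), effect = effect, statistic = stat,
             p_value = p, adjusted_p = adj,
             selected = adj <= alpha & abs(effect) >= min_abs_effect,
             row.names = NULL)
}
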