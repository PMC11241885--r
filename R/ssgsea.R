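#' ssGSEA scoring parameters
#'
#' @param tau non-negative rank-weight exponent (default 0.25). `tau = 0`
#'   weights all positions equally.
#' @param weight `"rank"` (default) weights in-set genes by their rank
#'   position raised to `tau`, which makes the score invariant to any
#'   strictly increasing transform of one sample's values and hence exactly
#'   reproducible n-of-1; `"value"` weights by `|expression|^tau` for
#'   experiments mirroring value-weighted implementations.
#' @param normalize_across_samples when `TRUE`, [ssgsea_matrix()] rescales
#'   all scores by the cohort-wide score range. Off by default: cross-sample
#'   rescaling breaks single-sample (n-of-1) scoring.
#' @return an `SSGSEAParams` list.
#' @export
ssgsea_params <- function(tau = 0.25, weight = c("rank", "value"),
                          normalize_across_samples = FALSE) {
  weight <- match.arg(weight)
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0)
  structure(list(tau = tau, weight = weight,
                 normalize_across_samples = isTRUE(normalize_across_samples)),
            class = "SSGSEAParams")
}

#' Single-sample gene set enrichment score
#'
#' Computes the integrated running-sum enrichment statistic for one sample:
#' genes are ranked by decreasing expression (ties broken deterministically
#' by gene label, so scoring is bit-reproducible); at every rank position
#' the difference between the tau-weighted empirical distribution of in-set
#' genes and the unweighted empirical distribution of out-of-set genes is
#' accumulated, and the score is the sum of those differences over all
#' positions (the integrated ssGSEA form, not the max-deviation GSEA form).
#' In the default rank mode the weight of the gene at position `p` of `N`
#' is `(N - p + 1)^tau`.
#'
#' @param values named numeric vector: one sample's expression across genes.
#' @param set a [gene_set()].
#' @param params an [ssgsea_params()].
#' @return a single numeric score.
#' @export
ssgsea_score <- function(values, set, params = ssgsea_params()) {
  stopifnot(inherits(set, "GeneSet"))
  genes <- names(values)
  if (is.null(genes)) stopf("expression values must be named by gene")
  n <- length(values)
  in_set <- genes %in% set$genes
  m <- sum(in_set)
  if (m == 0L) stopf("gene set '%s' shares no genes with the expression data",
                     set$name)
  if (m == n) stopf("gene set '%s' covers the whole gene universe", set$name)
  ord <- order(-values, genes, method = "radix")
  in_ord <- in_set[ord]
  w <- if (params$weight == "rank") {
    (n - seq_len(n) + 1)^params$tau
  } else {
    abs(values[ord])^params$tau
  }
  win <- w * in_ord
  p_in <- cumsum(win) / sum(win)
  p_out <- cumsum(!in_ord) / (n - m)
  sum(p_in - p_out)
}

#' ssGSEA scores for every sample and set
#'
#' Column `j` of the result equals [ssgsea_score()] applied to sample `j`
#' alone whenever `normalize_across_samples` is off — the n-of-1 guarantee:
#' adding or removing other samples cannot change a sample's score. With
#' normalization on, every score is divided by the cohort-wide range
#' (max - min over all sets and samples); the constant is returned as the
#' `"normalization_constant"` attribute so deployments can reuse it.
#'
#' @param x an `ExpressionMatrix` (or plain gene-by-sample matrix).
#' @param sets list of [gene_set()]s (or one set).
#' @param params an [ssgsea_params()].
#' @return numeric matrix, sets in rows, samples in columns.
#' @export
ssgsea_matrix <- function(x, sets, params = ssgsea_params()) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    names(col) <- rownames(x)
    vapply(sets, function(s) ssgsea_score(col, s, params), numeric(1))
  }, numeric(length(sets)))
  scores <- matrix(scores, nrow = length(sets),
                   dimnames = list(vapply(sets, `[[`, character(1), "name"),
                                   colnames(x)))
  if (params$normalize_across_samples) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
    attr(scores, "normalization_constant") <- rng
  }
  scores
}
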