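#' Default pipeline configuration
#'
#' One nested list holding every tunable of the training and scoring
#' pipeline, one section per stage. The fixed conventions of the method —
#' the scar positivity cutoff 42, the expHRD high cutoff 1000, five-fold
#' grid search, B = 100 bootstrap refits with 98/100 retention — are the
#' defaults here and flow to every stage from this single place.
#'
#' @param seed global seed; per-stage seeds are derived from it with
#'   [derive_seed()].
#' @return a `PipelineConfig` nested list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scars = list(
      loh_min_length = 15e6, lst_min_segment = 10e6, lst_max_gap = 3e6,
      lst_smooth_below = 3e6, telomere_tolerance = 0,
      count_whole_chrom_loh = FALSE, include_sex = FALSE),
    preprocess = list(
      scar_positive = 42, deg_alpha = 0.05, deg_min_abs_effect = 0),
    train = list(
      cv_alphas = c(0.01, 0.03, 0.1, 0.3, 1, 3, 10),
      cv_rhos = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
      cv_k = 5L, B = 100L, f_min = 0.98, subsample_fraction = 0.8,
      replace = FALSE),
    ssgsea = list(tau = 0.25, weight = "rank",
                  normalize_across_samples = FALSE),
    thresholds = list(scar_positive = 42, exphrd_high = 1000)),
    class = "PipelineConfig")
}

#' Load and validate a pipeline configuration file
#'
#' YAML with the same section/key layout as [default_config()]. Values
#' present in the file override the defaults; unknown sections or keys are
#' rejected by name.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param seed global seed applied when the file sets none.
#' @return a validated `PipelineConfig`.
#' @export
load_config <- function(path = NULL, seed = 1L) {
  cfg <- default_config(seed)
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_section <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stopf("unknown config key '%s' in section '%s'", unknown[1L], where)
    for (k in names(upd)) {
      if (is.list(base[[k]])) base[[k]] <- merge_section(base[[k]], upd[[k]], k)
      else base[[k]] <- upd[[k]]
    }
    base
  }
  out <- merge_section(unclass(cfg), user, "<top>")
  out$seed <- as.integer(out$seed)
  structure(out, class = "PipelineConfig")
}

#' Train a calibrated expHRD model end to end
#'
#' The full serial recipe: median-of-ratios normalization; differential
#' expression pre-filter against scar status; elastic-net fit with k-fold
#' grid search, keeping nonzero genes; a second-round elastic-net refit on
#' the survivors at the same hyperparameters, again keeping nonzero genes;
#' bootstrap stability selection; signed gene-set derivation; expHRD
#' computation on the training cohort and linear calibration to the scar
#' scale. Fully reproducible from the config seed.
#'
#' @param counts an [expression_matrix()] with unit counts.
#' @param scar named per-sample scar scores (e.g. `scar_total` from
#'   [scar_scores()], or any scar-scale value).
#' @param config a [default_config()]-shaped `PipelineConfig`.
#' @param verbose print stage progress?
#' @return a `CalibratedModel`; the per-stage intermediates are attached as
#'   attribute `"stages"` (DEG table, CV report, fits, stability result).
#' @export
train_pipeline <- function(counts, scar, config = default_config(),
                           verbose = FALSE) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (is.null(names(scar))) stopf("scar scores must be named by sample")
  shared <- intersect(colnames(counts), names(scar))
  if (length(shared) < 10L) stopf("need >= 10 shared samples to train")
  counts <- expression_matrix(unclass(counts)[, shared, drop = FALSE],
                              "counts")
  y <- as.numeric(scar[shared])
  say <- function(...) if (verbose) message(sprintf(...))

  say("normalizing %d samples", ncol(counts))
  norm <- normalize_counts(counts)

  say("DEG pre-filter")
  deg <- deg_filter(norm, scar[shared],
                    threshold = config$preprocess$scar_positive,
                    alpha = config$preprocess$deg_alpha,
                    min_abs_effect = config$preprocess$deg_min_abs_effect)
  genes1 <- deg$gene[deg$selected]
  if (length(genes1) < 2L) stopf("stage DEG filter: fewer than 2 genes pass")
  say("  %d genes pass", length(genes1))

  X <- t(unclass(norm)[genes1, , drop = FALSE])
  grid <- expand.grid(alpha = config$train$cv_alphas,
                      rho = config$train$cv_rhos)
  say("grid search (%d cells, %d-fold)", nrow(grid), config$train$cv_k)
  cv <- grid_search_cv(X, y, grid, k = config$train$cv_k,
                       seed = derive_seed(config$seed, "cv"))
  say("  best alpha = %g, rho = %g", cv$best$alpha, cv$best$rho)

  fit1 <- fit_elastic_net(X, y, cv$best$alpha, cv$best$rho)
  genes2 <- names(fit1$weights)[fit1$weights != 0]
  if (length(genes2) < 2L) stopf("stage elastic net: fewer than 2 nonzero genes")
  say("elastic net keeps %d genes", length(genes2))

  fit2 <- fit_elastic_net(X[, genes2, drop = FALSE], y,
                          cv$best$alpha, cv$best$rho)
  genes3 <- names(fit2$weights)[fit2$weights != 0]
  if (length(genes3) < 2L)
    stopf("stage second-round elastic net: fewer than 2 nonzero genes")
  say("second-round elastic net keeps %d genes", length(genes3))

  say("stability selection (B = %d)", config$train$B)
  stab <- stability_select(X[, genes3, drop = FALSE], y,
                           cv$best$alpha, cv$best$rho,
                           B = config$train$B, f_min = config$train$f_min,
                           subsample_fraction = config$train$subsample_fraction,
                           replace = config$train$replace,
                           seed = derive_seed(config$seed, "stability"))
  sets <- derive_gene_sets(stab)
  say("  %d positive / %d negative genes",
      length(sets$positive$genes), length(sets$negative$genes))

  params <- ssgsea_params(tau = config$ssgsea$tau,
                          weight = config$ssgsea$weight,
                          normalize_across_samples =
                            config$ssgsea$normalize_across_samples)
  ex <- compute_exphrd(norm, sets, params)
  cal <- calibrate_exphrd(ex, scar[shared])
  model <- calibrated_model(sets, cal, params,
                            thresholds = config$thresholds,
                            provenance = list(seed = config$seed))
  attr(model, "stages") <- list(deg = deg, cv = cv, fit1 = fit1, fit2 = fit2,
                                stability = stab, exphrd_train = ex)
  model
}
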