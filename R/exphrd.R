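#' Compute the expHRD statistic
#'
#' Per sample, the single-sample enrichment score of the positively
#' associated HRD signature minus that of the negatively associated one:
#' `expHRD = ssGSEA(positive) - ssGSEA(negative)`. With the default
#' rank-mode parameters the value for a sample depends on that sample
#' alone (n-of-1 scoring).
#'
#' @param x an `ExpressionMatrix` (or gene-by-sample matrix).
#' @param sets an `HRDGeneSets` pair from [derive_gene_sets()].
#' @param params an [ssgsea_params()].
#' @return named numeric vector, one expHRD value per sample.
#' @export
compute_exphrd <- function(x, sets, params = ssgsea_params()) {
  stopifnot(inherits(sets, "HRDGeneSets"))
  sc <- ssgsea_matrix(x, list(sets$positive, sets$negative), params)
  stats::setNames(sc[1L, ] - sc[2L, ], colnames(sc))
}

#' Calibrate expHRD against the scar scale
#'
#' Ordinary least-squares regression of the scar score on expHRD over a
#' paired cohort, keeping the sufficient statistics needed for 95%
#' prediction intervals of a new sample: residual SD, n, mean of x and
#' centered sum of squares.
#'
#' @param exphrd per-sample expHRD values.
#' @param scar per-sample scar scores (same order, or matched by names when
#'   both are named).
#' @return a `Calibration` list: `slope`, `intercept`, `residual_sd`,
#'   `n_cal`, `mean_x`, `sxx`, `df`.
#' @export
calibrate_exphrd <- function(exphrd, scar) {
  if (!is.null(names(exphrd)) && !is.null(names(scar))) {
    shared <- intersect(names(exphrd), names(scar))
    exphrd <- exphrd[shared]
    scar <- scar[shared]
  }
  n <- length(exphrd)
  if (n < 3L || n != length(scar)) stopf("need >= 3 paired observations")
  if (stats::sd(exphrd) == 0) stopf("constant expHRD cannot be calibrated")
  fit <- stats::lm(scar ~ exphrd)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 residual_sd = summary(fit)$sigma, n_cal = n,
                 mean_x = mean(exphrd),
                 sxx = sum((exphrd - mean(exphrd))^2), df = n - 2L),
            class = "Calibration")
}

#' Predict a scar-scale HRD score from an expHRD value
#'
#' Point prediction `slope * x + intercept` with a 95% interval from the
#' stored calibration statistics. The default is the new-observation
#' prediction interval (the quantity that brackets an individual sample);
#' `interval = "mean"` gives the narrower mean-response confidence
#' interval.
#'
#' @param exphrd numeric expHRD value(s).
#' @param model a `CalibratedModel` (or bare `Calibration`).
#' @param interval `"prediction"` (default) or `"mean"`.
#' @param level coverage level, default 0.95.
#' @return data.frame with columns `predicted`, `lower`, `upper`.
#' @export
predict_hrd <- function(exphrd, model, interval = c("prediction", "mean"),
                        level = 0.95) {
  interval <- match.arg(interval)
  cal <- if (inherits(model, "CalibratedModel")) model$calibration else model
  if (!inherits(cal, "Calibration")) stopf("model is not calibrated")
  pred <- cal$slope * exphrd + cal$intercept
  extra <- if (interval == "prediction") 1 else 0
  se <- cal$residual_sd *
    sqrt(extra + 1 / cal$n_cal + (exphrd - cal$mean_x)^2 / cal$sxx)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = cal$df)
  data.frame(predicted = pred, lower = pred - tcrit * se,
             upper = pred + tcrit * se)
}

#' Assemble a calibrated expHRD model
#'
#' @param gene_sets an `HRDGeneSets` pair.
#' @param calibration a [calibrate_exphrd()] result.
#' @param ssgsea an [ssgsea_params()].
#' @param thresholds list with `scar_positive` (default 42, the scar-scale
#'   positivity cutoff) and `exphrd_high` (default 1000; meaningful only
#'   under the enrichment parameterization stored in the same archive).
#' @param provenance list with at least `seed`.
#' @return a `CalibratedModel`.
#' @export
calibrated_model <- function(gene_sets, calibration,
                             ssgsea = ssgsea_params(),
                             thresholds = list(scar_positive = 42,
                                               exphrd_high = 1000),
                             provenance = list(seed = NA_integer_)) {
  stopifnot(inherits(gene_sets, "HRDGeneSets"),
            inherits(calibration, "Calibration"),
            calibration$n_cal >= 3, calibration$residual_sd >= 0,
            thresholds$scar_positive > 0, thresholds$exphrd_high > 0)
  provenance$package_version <-
    as.character(utils::packageVersion("hrdex"))
  structure(list(gene_sets = gene_sets, calibration = calibration,
                 ssgsea = ssgsea, thresholds = thresholds,
                 provenance = provenance),
            class = "CalibratedModel")
}

#' @export
print.CalibratedModel <- function(x, ...) {
  cat(sprintf(paste0(
    "CalibratedModel: %d+/%d- genes; scar = %.4g * expHRD + %.4g ",
    "(n = %d, residual SD %.3g)\n"),
    length(x$gene_sets$positive$genes), length(x$gene_sets$negative$genes),
    x$calibration$slope, x$calibration$intercept, x$calibration$n_cal,
    x$calibration$residual_sd))
  invisible(x)
}

#' Classify samples from expHRD and predicted HRD
#'
#' Both comparisons are inclusive: `class_exphrd` is `"high"` iff
#' `exphrd >= exphrd_high` and `class_predicted` is `"positive"` iff
#' `predicted >= scar_positive`, with the thresholds taken from the model
#' archive.
#'
#' @param exphrd numeric expHRD values.
#' @param predicted numeric predicted scar-scale values.
#' @param thresholds list with `exphrd_high`, `scar_positive`.
#' @return data.frame with `class_exphrd` and `class_predicted`.
#' @export
classify_hrd <- function(exphrd, predicted,
                         thresholds = list(scar_positive = 42,
                                           exphrd_high = 1000)) {
  data.frame(
    class_exphrd = ifelse(exphrd >= thresholds$exphrd_high, "high", "low"),
    class_predicted = ifelse(predicted >= thresholds$scar_positive,
                             "positive", "negative"))
}

#' Score samples with a calibrated model
#'
#' The deployment entry point: computes expHRD, maps it to the scar scale
#' with the stored calibration, attaches 95% interval bounds and both class
#' labels. Scoring is per-sample, so a sample's row is identical whether it
#' is scored alone or inside any cohort.
#'
#' @param x an `ExpressionMatrix`.
#' @param model a `CalibratedModel`.
#' @param interval passed to [predict_hrd()].
#' @return an `ExpHRDReport` data.frame: `sample`, `exphrd`, `p_hrd`,
#'   `lower_hrd`, `higher_hrd`, `class_exphrd`, `class_predicted`.
#' @export
score_samples <- function(x, model, interval = "prediction") {
  stopifnot(inherits(model, "CalibratedModel"))
  e <- compute_exphrd(x, model$gene_sets, model$ssgsea)
  pr <- predict_hrd(e, model, interval = interval)
  cl <- classify_hrd(e, pr$predicted, model$thresholds)
  data.frame(sample = names(e), exphrd = unname(e), p_hrd = pr$predicted,
             lower_hrd = pr$lower, higher_hrd = pr$upper,
             class_exphrd = cl$class_exphrd,
             class_predicted = cl$class_predicted, row.names = NULL)
}

#' Write a calibrated model archive
#'
#' One JSON text file holding the gene sets, enrichment parameters,
#' calibration statistics, thresholds and provenance — everything needed to
#' score a single new sample. Rewriting the same model is byte-identical.
#'
#' @param model a `CalibratedModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hrd_model <- function(model, path) {
  stopifnot(inherits(model, "CalibratedModel"))
  obj <- list(
    format = "hrdex-model", format_version = 1L,
    gene_sets = list(
      positive = list(name = model$gene_sets$positive$name,
                      description = model$gene_sets$positive$description,
                      genes = model$gene_sets$positive$genes),
      negative = list(name = model$gene_sets$negative$name,
                      description = model$gene_sets$negative$description,
                      genes = model$gene_sets$negative$genes)),
    ssgsea = unclass(model$ssgsea),
    calibration = unclass(model$calibration),
    thresholds = model$thresholds,
    provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibrated model archive
#'
#' @param path path to a file written by [write_hrd_model()].
#' @return a `CalibratedModel`.
#' @export
read_hrd_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hrdex-model"))
    stopf("%s: not an hrdex model archive", path)
  sets <- structure(list(
    positive = gene_set(obj$gene_sets$positive$name,
                        obj$gene_sets$positive$genes,
                        obj$gene_sets$positive$description %||% ""),
    negative = gene_set(obj$gene_sets$negative$name,
                        obj$gene_sets$negative$genes,
                        obj$gene_sets$negative$description %||% "")),
    class = "HRDGeneSets")
  params <- ssgsea_params(tau = obj$ssgsea$tau, weight = obj$ssgsea$weight,
                          normalize_across_samples =
                            obj$ssgsea$normalize_across_samples)
  cal <- structure(obj$calibration, class = "Calibration")
  cal$df <- as.integer(cal$df)
  cal$n_cal <- as.integer(cal$n_cal)
  calibrated_model(sets, cal, params, obj$thresholds,
                   obj$provenance[setdiff(names(obj$provenance),
                                          "package_version")])
}
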