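# Elastic-net training of scar score on expression, with k-fold grid
# search, bootstrap stability selection and signed gene-set derivation.
#
# The fitted objective is
#   min_w (1/2n) ||Xs w + b - y||^2 + alpha * rho * ||w||_1
#                                   + alpha * (1 - rho) / 2 * ||w||^2
# where Xs is the internally standardized design (mean 0, variance 1 with
# the 1/n convention). Weights are reported back on the original scale.
# glmnet provides the coordinate-descent solver; it is driven down a
# warm-start path ending exactly at the requested penalty with a tight
# convergence threshold (1e-14 on the weighted objective change).

standardize_design <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(X^2) - mu^2)
  list(mu = mu, sd = sd, ok = sd > 0)
}

#' Fit one elastic-net regression
#'
#' Columns are standardized internally; the penalty applies on the
#' standardized scale and reported weights are back-transformed to the
#' original scale. Zero-variance columns are excluded from the fit with a
#' warning and receive weight 0. `alpha = 0` is the unpenalized
#' (least-squares) limit; `rho = 1` is the lasso, `rho = 0` the ridge.
#'
#' @param X numeric matrix, samples in rows, genes in columns.
#' @param y numeric response (scar scores), length `nrow(X)`.
#' @param alpha overall penalty strength (non-negative).
#' @param rho L1 mixing fraction in `[0, 1]`.
#' @return an `ElasticNetModel` list: `weights` (original scale, named),
#'   `intercept`, `weights_std`, `center`, `scale`, `alpha`, `rho`,
#'   `n_samples`, `genes`.
#' @export
fit_elastic_net <- function(X, y, alpha, rho) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2,
            alpha >= 0, rho >= 0, rho <= 1)
  genes <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  std <- standardize_design(X)
  if (!all(std$ok))
    warnf("excluding %d zero-variance gene(s) from the fit",
          sum(!std$ok))
  if (!any(std$ok)) stopf("no gene with positive variance")
  Xs <- sweep(sweep(X[, std$ok, drop = FALSE], 2, std$mu[std$ok]), 2,
              std$sd[std$ok], `/`)
  n <- nrow(X)
  yc <- y - mean(y)
  s_y <- sqrt(mean(yc^2))
  lmax_l1 <- max(abs(crossprod(Xs, yc))) / n
  w_std <- numeric(sum(std$ok))
  b0 <- mean(y)
  if (s_y == 0) {
    # constant response: null model
  } else if (rho > 0 && alpha * rho >= lmax_l1) {
    # L1 part alone shrinks every weight to zero (KKT bound): exact null fit
  } else {
    # glmnet internally rescales a gaussian response to unit variance, which
    # would skew the L1/L2 mix of the stated objective; feed it unit-variance
    # y and remap (lambda, alpha) so the minimized objective is exactly ours,
    # then map coefficients back.
    ys <- y / s_y
    lam <- alpha * rho / s_y + alpha * (1 - rho)
    mix <- if (lam > 0) (alpha * rho / s_y) / lam else 1
    hi <- if (mix > 0) max(lmax_l1 / s_y / mix * 1.05, lam * 1.01, 1e-8)
          else max(lam * 100, 1e-3)
    lo <- max(lam, hi * 1e-6)
    path <- exp(seq(log(hi), log(lo), length.out = 40L))
    if (lam < lo) path <- c(path, lam)
    fit <- glmnet::glmnet(Xs, ys, family = "gaussian", alpha = mix,
                          lambda = path, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-16, maxit = 1e7)
    co <- stats::coef(fit) # last path point is exactly `lam`
    w_std <- as.numeric(co[-1L, ncol(co)]) * s_y
    b0 <- as.numeric(co[1L, ncol(co)]) * s_y
  }
  weights <- numeric(length(genes))
  names(weights) <- genes
  weights[std$ok] <- w_std / std$sd[std$ok]
  intercept <- b0 - sum(std$mu[std$ok] * w_std / std$sd[std$ok])
  structure(list(weights = weights, intercept = intercept,
                 weights_std = w_std, center = std$mu, scale = std$sd,
                 included = std$ok, alpha = alpha, rho = rho,
                 n_samples = n, genes = genes),
            class = "ElasticNetModel")
}

#' @export
print.ElasticNetModel <- function(x, ...) {
  cat(sprintf(
    "ElasticNetModel: %d genes (%d nonzero), alpha = %g, rho = %g, n = %d\n",
    length(x$weights), sum(x$weights != 0), x$alpha, x$rho, x$n_samples))
  invisible(x)
}

#' @export
predict.ElasticNetModel <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  drop(newdata[, object$genes, drop = FALSE] %*% object$weights) +
    object$intercept
}

#' Elastic-net objective value of a fitted model
#'
#' Evaluates the penalized objective on the standardized design — the
#' quantity the solver minimizes — for the model's own training data or any
#' compatible `(X, y)`.
#'
#' @param model an `ElasticNetModel`.
#' @param X,y data on the original scale.
#' @return the objective value.
#' @export
elastic_net_objective <- function(model, X, y) {
  Xs <- sweep(sweep(X[, model$included, drop = FALSE], 2,
                    model$center[model$included]), 2,
              model$scale[model$included], `/`)
  w <- model$weights_std
  b0_std <- model$intercept + sum(model$center[model$included] * w /
                                    model$scale[model$included])
  r <- y - (Xs %*% w + b0_std)
  sum(r^2) / (2 * length(y)) + model$alpha * model$rho * sum(abs(w)) +
    model$alpha * (1 - model$rho) / 2 * sum(w^2)
}

#' Hyperparameter grid search with k-fold cross-validation
#'
#' Deterministic fold assignment from `seed`; for each `(alpha, rho)` cell
#' the mean validation mean-squared error across folds is recorded and the
#' best cell is the argmin, with ties broken toward smaller `alpha` (less
#' shrinkage) then larger `rho` (sparser).
#'
#' @param X samples-by-genes matrix.
#' @param y response.
#' @param grid data.frame with columns `alpha`, `rho`.
#' @param k fold count, default 5.
#' @param seed integer seed for fold assignment.
#' @return a `CVReport` list: `grid` (with `mean_mse`), `fold_mse`
#'   (cells x folds), `k`, `best` (list with `alpha`, `rho`), `seed`.
#' @export
grid_search_cv <- function(X, y, grid, k = 5L, seed = 1L) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0L) stopf("empty hyperparameter grid")
  stopifnot(all(c("alpha", "rho") %in% names(grid)), k >= 2,
            nrow(X) >= k)
  n <- nrow(X)
  folds <- with_seed(derive_seed(seed, "cv-folds"),
                     sample(rep(seq_len(k), length.out = n)))
  fold_mse <- matrix(NA_real_, nrow(grid), k)
  for (f in seq_len(k)) {
    tr <- folds != f
    for (g in seq_len(nrow(grid))) {
      m <- fit_elastic_net(X[tr, , drop = FALSE], y[tr],
                           grid$alpha[g], grid$rho[g])
      pred <- predict(m, X[!tr, , drop = FALSE])
      fold_mse[g, f] <- mean((y[!tr] - pred)^2)
    }
  }
  grid$mean_mse <- rowMeans(fold_mse)
  best <- order(grid$mean_mse, grid$alpha, -grid$rho)[1L]
  structure(list(grid = grid, fold_mse = fold_mse, k = as.integer(k),
                 best = list(alpha = grid$alpha[best], rho = grid$rho[best]),
                 seed = seed),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport: %d-fold over %d cells; best alpha = %g, rho = %g\n",
              x$k, nrow(x$grid), x$best$alpha, x$best$rho))
  invisible(x)
}

#' Bootstrap stability selection
#'
#' Refits the elastic net `B` times on random sample subsets at fixed
#' hyperparameters and counts, per gene, the refits with a nonzero weight.
#' A gene is retained when its count reaches `ceiling(f_min * B)` — with
#' the defaults, nonzero in at least 98 of 100 refits. Subsets are drawn
#' without replacement by default (`replace = TRUE` gives the classical
#' bootstrap reading).
#'
#' @param X samples-by-genes matrix.
#' @param y response.
#' @param alpha,rho fixed hyperparameters (from [grid_search_cv()]).
#' @param B refit count, default 100.
#' @param f_min retention fraction, default 0.98.
#' @param subsample_fraction fraction of samples per refit, default 0.8.
#' @param replace draw with replacement?
#' @param seed integer seed.
#' @return a `StabilityResult` list: `B`, `selection_count`,
#'   `mean_coefficient` (mean over refits where nonzero; 0 if never),
#'   `sign_consistent`, `retained`, `f_min`, `subsample_size`, `seed`.
#' @export
stability_select <- function(X, y, alpha, rho, B = 100L, f_min = 0.98,
                             subsample_fraction = 0.8, replace = FALSE,
                             seed = 1L) {
  stopifnot(f_min >= 0, f_min <= 1, B >= 1)
  n <- nrow(X)
  m <- floor(subsample_fraction * n)
  if (m < 3L)
    stopf("subsample of %d samples is too small to fit", m)
  genes <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  count <- integer(ncol(X))
  coef_sum <- numeric(ncol(X))
  pos_seen <- logical(ncol(X))
  neg_seen <- logical(ncol(X))
  with_seed(derive_seed(seed, "stability"), {
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = replace)
      fit <- suppressWarnings(
        fit_elastic_net(X[idx, , drop = FALSE], y[idx], alpha, rho))
      w <- fit$weights
      nz <- w != 0
      count <- count + nz
      coef_sum <- coef_sum + w
      pos_seen <- pos_seen | w > 0
      neg_seen <- neg_seen | w < 0
    }
  })
  mean_coef <- ifelse(count > 0, coef_sum / pmax(count, 1L), 0)
  structure(list(B = as.integer(B),
                 selection_count = stats::setNames(count, genes),
                 mean_coefficient = stats::setNames(mean_coef, genes),
                 sign_consistent = stats::setNames(!(pos_seen & neg_seen), genes),
                 retained = stats::setNames(count >= ceiling(f_min * B), genes),
                 f_min = f_min, subsample_size = m, seed = seed),
            class = "StabilityResult")
}

#' @export
print.StabilityResult <- function(x, ...) {
  cat(sprintf(
    "StabilityResult: B = %d, retained %d / %d genes (f_min = %.2f)\n",
    x$B, sum(x$retained), length(x$retained), x$f_min))
  invisible(x)
}

#' Derive signed HRD gene sets from a stability result
#'
#' Retained genes with sign-consistent nonzero coefficients across refits
#' are partitioned by the sign of their mean coefficient into the
#' positively and negatively associated signature. Sign-inconsistent
#' retained genes are dropped with a warning naming them. An empty positive
#' or negative set is an error, since the expHRD difference statistic is
#' then undefined.
#'
#' @param stability a [stability_select()] result.
#' @return an `HRDGeneSets` list with [gene_set()]s `positive`, `negative`.
#' @export
derive_gene_sets <- function(stability) {
  stopifnot(inherits(stability, "StabilityResult"))
  kept <- names(stability$retained)[stability$retained]
  bad <- kept[!stability$sign_consistent[kept]]
  if (length(bad)) {
    warnf("dropping sign-inconsistent retained gene(s): %s",
          paste(bad, collapse = ", "))
    kept <- setdiff(kept, bad)
  }
  mc <- stability$mean_coefficient[kept]
  pos <- kept[mc > 0]
  neg <- kept[mc < 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stopf("need both positive and negative retained genes (got %d / %d)",
          length(pos), length(neg))
  structure(list(
    positive = gene_set("HRD_POS", pos,
                        "genes positively associated with the scar score"),
    negative = gene_set("HRD_NEG", neg,
                        "genes negatively associated with the scar score")),
    class = "HRDGeneSets")
}

#' @export
print.HRDGeneSets <- function(x, ...) {
  cat(sprintf("HRDGeneSets: %d positive / %d negative genes\n",
              length(x$positive$genes), length(x$negative$genes)))
  invisible(x)
}
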