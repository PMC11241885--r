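test_that("unpenalized fit matches the least-squares closed form", {
  set.seed(2)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(5)
  fit <- fit_elastic_net(X, y, alpha = 0, rho = 0.5)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(c(fit$intercept, fit$weights) - ols)), 1e-6)
  expect_equal(unname(predict(fit, X)), unname(fitted(lm(y ~ X))),
               tolerance = 1e-6)
})

test_that("lasso with penalty above the null bound gives the null model", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20)
  lmax <- max(abs(crossprod(scale(X) * sqrt(20 / 19), y - mean(y)))) / 20
  fit <- fit_elastic_net(X, y, alpha = lmax * 1.5, rho = 1)
  expect_identical(unname(fit$weights), c(0, 0, 0))
  expect_equal(fit$intercept, mean(y))
})

test_that("zero-variance genes are excluded with weight zero", {
  set.seed(4)
  X <- cbind(a = rnorm(15), flat = rep(2, 15), b = rnorm(15))
  y <- rnorm(15)
  expect_warning(fit <- fit_elastic_net(X, y, 0.1, 0.5), "zero-variance")
  expect_equal(unname(fit$weights["flat"]), 0)
})

test_that("solution objective matches an independent coordinate-descent oracle", {
  set.seed(5)
  for (i in 1:10) {
    n <- 50L; p <- 20L
    X <- matrix(rnorm(n * p), n, p)
    w_true <- c(rnorm(4), rep(0, p - 4))
    y <- drop(X %*% w_true) + rnorm(n)
    a <- 10^runif(1, -2, 0.3)
    rho <- runif(1)
    fit <- fit_elastic_net(X, y, a, rho)
    Xs <- sweep(sweep(X, 2, colMeans(X)), 2,
                sqrt(colMeans(X^2) - colMeans(X)^2), `/`)
    orc <- cd_oracle(Xs, y, a, rho)
    obj_fit <- elastic_net_objective(fit, X, y)
    obj_orc <- cd_objective(Xs, y, orc$w, orc$b0, a, rho)
    expect_lt(abs(obj_fit - obj_orc), 1e-8)
    # objective never exceeds the zero-vector objective
    expect_lte(obj_fit, cd_objective(Xs, y, rep(0, p), mean(y), a, rho))
  }
})

test_that("grid search is a deterministic argmin with stated tie-breaks", {
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- drop(X[, 1] * 2 - X[, 2]) + rnorm(40, sd = 0.3)
  one <- grid_search_cv(X, y, data.frame(alpha = 0.3, rho = 0.5), seed = 1)
  expect_equal(one$best, list(alpha = 0.3, rho = 0.5))
  grid <- expand.grid(alpha = c(0.05, 0.5, 5), rho = c(0.2, 1))
  cv <- grid_search_cv(X, y, grid, k = 5, seed = 1)
  best_mse <- cv$grid$mean_mse[cv$grid$alpha == cv$best$alpha &
                                cv$grid$rho == cv$best$rho]
  expect_true(all(best_mse <= cv$grid$mean_mse))
  cv2 <- grid_search_cv(X, y, grid, k = 5, seed = 1)
  expect_identical(cv$grid, cv2$grid) # same seed, same folds, same result
  expect_error(grid_search_cv(X, y, data.frame(alpha = numeric(),
                                               rho = numeric())), "empty")
})

test_that("stability selection counts, thresholds and flags behave", {
  set.seed(7)
  n <- 60L
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("g", 1:8)))
  y <- drop(X[, 1:2] %*% c(3, -3)) + rnorm(n, sd = 0.5)
  st <- stability_select(X, y, alpha = 0.5, rho = 1, B = 25, f_min = 0.96,
                         seed = 9)
  # retention threshold: ceil(0.96 * 25) = 24
  expect_identical(unname(st$retained), unname(st$selection_count >= 24L))
  # the strong causal pair is always selected, with consistent signs
  expect_equal(unname(st$selection_count[c("g1", "g2")]), c(25L, 25L))
  expect_true(all(st$sign_consistent[c("g1", "g2")]))
  expect_gt(st$mean_coefficient["g1"], 0)
  expect_lt(st$mean_coefficient["g2"], 0)
  # lowering f_min never removes genes
  st0 <- stability_select(X, y, alpha = 0.5, rho = 1, B = 25, f_min = 0,
                          seed = 9)
  expect_true(all(names(which(st$retained)) %in% names(which(st0$retained))))
  # determinism
  st2 <- stability_select(X, y, alpha = 0.5, rho = 1, B = 25, f_min = 0.96,
                          seed = 9)
  expect_identical(st$selection_count, st2$selection_count)
  expect_error(stability_select(X[1:3, ], y[1:3], 0.5, 1,
                                subsample_fraction = 0.5), "too small")
})

test_that("retention arithmetic at B = 100, f_min = 0.98 keeps counts 98-100", {
  counts <- c(g1 = 97L, g2 = 98L, g3 = 99L, g4 = 100L)
  st <- structure(list(B = 100L, selection_count = counts,
                       mean_coefficient = c(g1 = 1, g2 = 1, g3 = -1, g4 = 1),
                       sign_consistent = c(g1 = TRUE, g2 = TRUE, g3 = TRUE,
                                           g4 = TRUE),
                       retained = counts >= ceiling(0.98 * 100),
                       f_min = 0.98, subsample_size = 80L, seed = 1L),
                  class = "StabilityResult")
  expect_identical(unname(st$retained), c(FALSE, TRUE, TRUE, TRUE))
  sets <- derive_gene_sets(st)
  expect_setequal(sets$positive$genes, c("g2", "g4"))
  expect_equal(sets$negative$genes, "g3")
})

test_that("gene-set derivation drops sign-inconsistent genes and needs both signs", {
  st <- structure(list(B = 10L,
                       selection_count = c(p = 10L, n = 10L, flip = 10L),
                       mean_coefficient = c(p = 0.5, n = -0.3, flip = 0.1),
                       sign_consistent = c(p = TRUE, n = TRUE, flip = FALSE),
                       retained = c(p = TRUE, n = TRUE, flip = TRUE),
                       f_min = 1, subsample_size = 8L, seed = 1L),
                  class = "StabilityResult")
  expect_warning(sets <- derive_gene_sets(st), "flip")
  expect_equal(sets$positive$genes, "p")
  expect_equal(sets$negative$genes, "n")
  st$mean_coefficient["n"] <- 0.3
  st$sign_consistent["n"] <- TRUE
  st$retained["flip"] <- FALSE
  expect_error(derive_gene_sets(st), "positive and negative")
})

test_that("training pipeline is deterministic and recovers planted structure", {
  co <- reference_cohort()
  tr <- training_samples()
  counts <- expression_matrix(unclass(co$expression)[, tr], "counts")
  model <- reference_model()
  pos <- model$gene_sets$positive$genes
  neg <- model$gene_sets$negative$genes
  # positive set enriched for planted positive-causal genes
  universe <- rownames(co$expression)
  expect_lt(fisher.test(matrix(c(
    sum(pos %in% co$causal_pos), sum(!(pos %in% co$causal_pos)),
    sum(setdiff(universe, pos) %in% co$causal_pos),
    sum(!(setdiff(universe, pos) %in% co$causal_pos))), 2, 2,
    byrow = TRUE), alternative = "greater")$p.value, 1e-6)
  # rerun with the same seed: byte-identical model archive
  m2 <- suppressWarnings(
    train_pipeline(counts, co$latent_score[tr], default_config(seed = 101L)))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hrd_model(model, f1)
  write_hrd_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
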