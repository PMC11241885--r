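# Independent oracle implementations used to cross-check the package.
# These deliberately take a different code path from the implementation.

# Coordinate descent for the penalized least-squares objective
#   (1/2n)||y - b0 - Xs w||^2 + a*rho*||w||_1 + a(1-rho)/2*||w||^2
# on a column-centered design Xs (intercept = mean(y) exactly), iterated to
# a tight tolerance.
cd_oracle <- function(Xs, y, a, rho, tol = 1e-13, max_sweeps = 50000L) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  b0 <- mean(y)
  w <- numeric(p)
  r <- y - b0
  xss <- colSums(Xs^2) / n
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      zj <- sum(Xs[, j] * r) / n + xss[j] * w[j]
      wj <- soft(zj, a * rho) / (xss[j] + a * (1 - rho))
      d <- wj - w[j]
      if (d != 0) {
        r <- r - Xs[, j] * d
        w[j] <- wj
        delta <- max(delta, abs(d))
      }
    }
    if (delta < tol) break
  }
  list(w = w, b0 = b0)
}

cd_objective <- function(Xs, y, w, b0, a, rho) {
  r <- y - b0 - Xs %*% w
  sum(r^2) / (2 * length(y)) + a * rho * sum(abs(w)) +
    a * (1 - rho) / 2 * sum(w^2)
}

# Brute-force running-sum enrichment: recompute both empirical
# distributions from scratch at every rank position.
ssgsea_brute <- function(values, set_genes, tau = 0.25) {
  gn <- names(values)
  ord <- order(-values, gn, method = "radix")
  g <- gn[ord]
  n <- length(g)
  inset <- g %in% set_genes
  w <- (n - seq_len(n) + 1)^tau
  total_in <- sum(w[inset])
  nout <- n - sum(inset)
  es <- 0
  for (i in seq_len(n)) {
    p_in <- sum(w[seq_len(i)][inset[seq_len(i)]]) / total_in
    p_out <- sum(!inset[seq_len(i)]) / nout
    es <- es + (p_in - p_out)
  }
  es
}

# Benjamini-Hochberg by the literal step-up procedure.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# Classification metrics transcribed over expanded 0/1 vectors rather than
# closed-form count arithmetic.
metrics_expanded <- function(TP, FP, TN, FN) {
  truth <- c(rep(1, TP), rep(0, FP), rep(0, TN), rep(1, FN))
  pred <- c(rep(1, TP), rep(1, FP), rep(0, TN), rep(0, FN))
  res <- c(accuracy = mean(pred == truth),
           sensitivity = if (sum(truth) == 0) NA_real_
                         else mean(pred[truth == 1] == 1),
           specificity = if (sum(!truth) == 0) NA_real_
                         else mean(pred[truth == 0] == 0),
           precision = if (sum(pred) == 0) NA_real_
                       else mean(truth[pred == 1] == 1))
  f1 <- if (2 * TP + FP + FN == 0) NA_real_ else 2 * TP / (2 * TP + FP + FN)
  sd0 <- function(v) length(v) < 2 || stats::sd(v) == 0
  mcc <- if (sd0(pred) || sd0(truth)) NA_real_ else stats::cor(pred, truth)
  c(res, f1 = f1, mcc = mcc)
}

# AUC as the normalized Mann-Whitney U with midranks (grouped ties).
auc_mannwhitney <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Textbook prediction-interval recomputation from raw paired data.
pred_interval_textbook <- function(x, y, x0, level = 0.95) {
  fit <- stats::lm(y ~ x)
  as.data.frame(stats::predict(fit, newdata = data.frame(x = x0),
                               interval = "prediction", level = level))
}
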