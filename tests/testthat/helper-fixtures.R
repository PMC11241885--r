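# Fixtures built in code; the heavyweight trained model is computed once
# per test run and cached.

# A small two-chromosome build for hand-derived scar fixtures:
# chr1 100 Mb with a centromere at 45-50 Mb, chr2 80 Mb without one.
toy_build <- function(with_centromere = TRUE) {
  cen <- if (with_centromere)
    data.frame(chrom = "chr1", start = 45e6, end = 50e6) else NULL
  genome_build(c(chr1 = 100e6, chr2 = 80e6), cen)
}

# Profile on toy_build from (chrom, start, end, total, minor) rows in Mb.
toy_profile <- function(rows, sample_id = "T1", build = toy_build()) {
  seg <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]) * 1e6,
               end = as.numeric(r[[3]]) * 1e6,
               total_cn = as.numeric(r[[4]]), minor_cn = as.numeric(r[[5]]))
  }))
  segment_profile(sample_id, seg, build = build)
}

toy_counts <- function() {
  m <- matrix(c(2, 4, 8,
                1, 1, 1,
                3, 6, 12), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  expression_matrix(m, "counts")
}

# Reference study design shared by the planted-signal checks: 500 samples
# from one generative process, the first 400 for training and the last 100
# held out. One training run is cached for the whole suite.
reference_design <- function(seed = 101L) {
  simulation_design(n_samples = 500L, n_genes = 1000L, n_pos_causal = 50L,
                    n_neg_causal = 50L, effect_size = 0.8, seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

reference_cohort <- function() {
  cached("cohort", simulate_expression(reference_design()))
}

training_samples <- function() colnames(reference_cohort()$expression)[1:400]
heldout_samples <- function() colnames(reference_cohort()$expression)[401:500]

reference_model <- function() {
  cached("model", {
    co <- reference_cohort()
    tr <- training_samples()
    counts <- expression_matrix(unclass(co$expression)[, tr], "counts")
    suppressWarnings(
      train_pipeline(counts, co$latent_score[tr],
                     default_config(seed = 101L)))
  })
}
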