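#' Simulation design for a planted-signal expression cohort
#'
#' Describes a cohort with a latent per-sample HRD score on the scar scale
#' and a set of causal genes whose expression tracks it. Defaults are the
#' package's reference study conditions: 400 samples, 1000 genes, 50
#' positively and 50 negatively associated causal genes, effect size 0.8,
#' a latent score uniform on the scar scale (0, 100) so the conventional
#' positivity cutoff of 42 is exercised, and RNA-seq-like overdispersed
#' counts (gamma-Poisson, dispersion 0.2) with library-size variation.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_pos_causal,n_neg_causal causal gene counts (disjoint sets);
#'   their sum must not exceed `n_genes`.
#' @param effect_size slope magnitude (per SD of the latent score) of the
#'   causal genes' log-mean; sets the expected |correlation| scale.
#' @param noise_sd extra log-scale observation noise SD.
#' @param latent_range `(lo, hi)` of the uniform latent scar-scale score.
#' @param library_size_range `(lo, hi)` of per-sample relative library-size
#'   factors.
#' @param dispersion gamma-Poisson overdispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return a `SimulationDesign` list.
#' @export
simulation_design <- function(n_samples = 400L, n_genes = 1000L,
                              n_pos_causal = 50L, n_neg_causal = 50L,
                              effect_size = 0.8, noise_sd = 0.3,
                              latent_range = c(0, 100),
                              library_size_range = c(0.7, 1.4),
                              dispersion = 0.2, seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 1, n_pos_causal >= 0, n_neg_causal >= 0,
            effect_size >= 0, noise_sd >= 0, dispersion > 0,
            length(latent_range) == 2L, length(library_size_range) == 2L,
            all(library_size_range > 0))
  if (n_pos_causal + n_neg_causal > n_genes)
    stopf("causal gene count exceeds n_genes")
  if (latent_range[1L] >= latent_range[2L])
    stopf("latent_range must satisfy lo < hi")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_pos_causal = as.integer(n_pos_causal),
                 n_neg_causal = as.integer(n_neg_causal),
                 effect_size = effect_size, noise_sd = noise_sd,
                 latent_range = latent_range,
                 library_size_range = library_size_range,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "SimulationDesign")
}

#' Simulate an expression cohort with a planted latent HRD score
#'
#' Per-sample latent scores are uniform on `latent_range`. Counts follow a
#' gamma-Poisson (negative-binomial-like) model: each gene's log-mean is a
#' baseline (log-normal across genes) plus, for causal genes, a linear term
#' in the standardized latent score (positive slope for `causal_pos`,
#' negative for `causal_neg`, magnitude `effect_size`), plus a per-sample
#' log library-size offset and `noise_sd` log-normal observation noise.
#' Non-causal genes are independent of the latent score.
#'
#' @param design a [simulation_design()].
#' @return a `SimulatedCohort` list: `expression` (an
#'   [expression_matrix()], unit counts), `latent_score` (named per-sample),
#'   `causal_pos`, `causal_neg` (gene labels), `design`.
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  d <- design
  with_seed(d$seed, {
    genes <- sprintf("G%04d", seq_len(d$n_genes))
    samples <- sprintf("S%04d", seq_len(d$n_samples))
    causal <- sample(genes, d$n_pos_causal + d$n_neg_causal)
    causal_pos <- sort(causal[seq_len(d$n_pos_causal)])
    causal_neg <- sort(causal[d$n_pos_causal + seq_len(d$n_neg_causal)])
    latent <- stats::runif(d$n_samples, d$latent_range[1L], d$latent_range[2L])
    names(latent) <- samples
    z <- as.numeric(scale(latent))
    beta <- numeric(d$n_genes)
    names(beta) <- genes
    beta[causal_pos] <- d$effect_size
    beta[causal_neg] <- -d$effect_size
    base_log <- stats::rnorm(d$n_genes, mean = log(60), sd = 1)
    lib <- stats::runif(d$n_samples, d$library_size_range[1L],
                        d$library_size_range[2L])
    log_mu <- outer(base_log, log(lib), `+`) + outer(beta, z) +
      matrix(stats::rnorm(d$n_genes * d$n_samples, sd = d$noise_sd),
             d$n_genes, d$n_samples)
    counts <- matrix(stats::rnbinom(d$n_genes * d$n_samples,
                                    mu = exp(log_mu), size = 1 / d$dispersion),
                     d$n_genes, d$n_samples,
                     dimnames = list(genes, samples))
    structure(list(expression = expression_matrix(counts * 1.0, "counts"),
                   latent_score = latent, causal_pos = causal_pos,
                   causal_neg = causal_neg, design = d),
              class = "SimulatedCohort")
  })
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat(sprintf(
    "SimulatedCohort: %d genes x %d samples, %d+%d causal, effect %.2f\n",
    nrow(x$expression), ncol(x$expression), length(x$causal_pos),
    length(x$causal_neg), x$design$effect_size))
  invisible(x)
}

# Placement geometry (all in bp). Events are planted on disjoint
# chromosomes, each separated from its balanced (2,1) flanks by >= 3 Mb
# assembly gaps so no incidental LST arises, with imbalanced material kept
# off the telomeres (LOH/LST) or anchored on the q-telomere without crossing
# the centromere (TAI) so no incidental TAI/LOH arises.
plant_loh <- function(L, cen) {
  len <- 16e6 + stats::runif(1, 0, min(20e6, L - 32e6))
  a <- 8e6
  gap <- 4e6
  data.frame(start = c(0, a + gap, a + gap + len + gap),
             end = c(a, a + gap + len, L),
             total_cn = c(2, 2, 2), minor_cn = c(1, 0, 1))
}

plant_lst <- function(L, cen) {
  a <- 6e6
  gap <- 4e6
  len1 <- 10e6 + stats::runif(1, 0, 4e6)
  len2 <- 10e6 + stats::runif(1, 0, 4e6)
  b <- a + gap
  data.frame(start = c(0, b, b + len1, b + len1 + len2 + gap),
             end = c(a, b + len1, b + len1 + len2, L),
             total_cn = c(2, 2, 4, 2), minor_cn = c(1, 1, 2, 1))
}

plant_tai <- function(L, cen) {
  lo <- if (is.null(cen)) L / 2 else cen$end + 2e6
  len <- min(25e6, (L - lo) * 0.8) * stats::runif(1, 0.5, 1)
  x <- L - len
  data.frame(start = c(0, x), end = c(x - 4e6, L),
             total_cn = c(2, 3), minor_cn = c(1, 1))
}

#' Simulate a segment profile with planted scar events
#'
#' Builds an allele-specific profile whose scar counts are exactly
#' `(n_loh, n_lst, n_tai)`: LOH as an interstitial `minor_cn = 0` run longer
#' than 15 Mb; LST as two abutting >= 10 Mb segments with a copy-state
#' change; TAI as an allele-imbalanced segment anchored at the q-telomere
#' that does not cross the centromere. Each event occupies its own
#' chromosome and placements are isolated by >= 3 Mb gaps so no incidental
#' extra event can arise; the function re-counts the finished profile with
#' [scar_score()] and fails if the planted and counted triples disagree.
#' Chromosomes without an event carry one balanced diploid (2,1) segment.
#'
#' @param sample_id sample identifier.
#' @param build a [genome_build()]; defaults to [grch38_autosomes()].
#' @param n_loh,n_lst,n_tai requested event counts; their sum must not
#'   exceed the number of usable autosomes.
#' @param seed integer seed.
#' @return a [segment_profile()].
#' @export
simulate_segments <- function(sample_id, build = grch38_autosomes(),
                              n_loh = 0L, n_lst = 0L, n_tai = 0L, seed = 1L) {
  stopifnot(inherits(build, "GenomeBuild"),
            n_loh >= 0, n_lst >= 0, n_tai >= 0)
  chroms <- names(build$chrom_lengths)[is_autosome(names(build$chrom_lengths))]
  chroms <- chroms[order(-build$chrom_lengths[chroms])]
  usable <- chroms[build$chrom_lengths[chroms] >= 50e6]
  kinds <- c(rep("lst", n_lst), rep("loh", n_loh), rep("tai", n_tai))
  if (length(kinds) > length(usable))
    stopf("cannot place %s event: only %d usable chromosomes for %d events",
          kinds[length(usable) + 1L], length(usable), length(kinds))
  with_seed(seed, {
    seg <- NULL
    for (i in seq_along(chroms)) {
      chr <- chroms[i]
      L <- build$chrom_lengths[[chr]]
      cen <- if (!is.null(build$centromeres) &&
                 chr %in% rownames(build$centromeres))
        build$centromeres[chr, ] else NULL
      rows <- if (i <= length(kinds)) {
        switch(kinds[i],
               loh = plant_loh(L, cen),
               lst = plant_lst(L, cen),
               tai = plant_tai(L, cen))
      } else {
        data.frame(start = 0, end = L, total_cn = 2, minor_cn = 1)
      }
      rows$chrom <- chr
      seg <- rbind(seg, rows)
    }
    profile <- segment_profile(sample_id, seg, build = build)
    got <- scar_score(profile, build)
    if (got$loh != n_loh || got$lst != n_lst || got$tai != n_tai)
      stopf("internal placement error: requested (%d,%d,%d), counted (%d,%d,%d)",
            n_loh, n_lst, n_tai, got$loh, got$lst, got$tai)
    profile
  })
}
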