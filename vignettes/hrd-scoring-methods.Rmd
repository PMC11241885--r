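---
title: "Methods: genomic scars, signature training, and n-of-1 expHRD scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic scars, signature training, and n-of-1 expHRD scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdex)
```

hrdex predicts a tumour's homologous-recombination-deficiency (HRD)
status from its transcriptome alone. This vignette is the package's own
account of the method: the model at each stage, its assumptions, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices that make results bit-reproducible.

## 1. The genomic scar score

The DNA-level ground truth is a genomic instability score computed from
allele-specific copy-number segments — per segment a total copy number
and a minor-allele copy number, with the minor allele canonicalized to
the lesser of the two. Internally all coordinates are 0-based half-open;
SEG-style files (1-based inclusive) are converted on read. Three event
types are counted per sample and summed:

* **LOH**: a maximal run of abutting segments with `minor_cn = 0` whose
  merged length *exceeds* 15 Mb. The threshold is strict: a run of
  exactly 15 Mb does not count, 15 Mb + 1 bp does. Runs covering an
  entire chromosome are excluded by default — the convention of the
  copy-number scar literature, where whole-chromosome loss is treated as
  a different phenomenon — but `count_whole_chrom = TRUE` restores the
  literal "or entire chromosome" reading.
* **LST**: a breakpoint at which the copy state `(total_cn, minor_cn)`
  changes, both flanking segments are at least 10 Mb (inclusive), and
  the gap between them is strictly below 3 Mb. Before counting,
  segments shorter than `smooth_below` (default 3 Mb) that sit between
  two abutting segments in the same state are merged away, so small
  segmentation artifacts do not mask a transition.
* **TAI**: a maximal run of abutting allele-imbalanced segments
  (`total_cn − minor_cn ≠ minor_cn`) that touches a chromosome end,
  does not span the whole chromosome, and — when the genome build
  carries centromeres — does not cross the centromere into the other
  arm. "Touches" means within `telomere_tolerance` of the recorded end;
  the default is 0 bp because synthetic fixtures are exact, and users of
  real segmentations (which rarely reach the assembly ends) should relax
  it to their platform's resolution. "Crossing" the centromere means
  spanning the entire centromere interval; a run ending inside it still
  counts.

Counts are per-chromosome sums, so chromosome order is irrelevant and
profiles restricted to disjoint chromosomes are additive. Sex
chromosomes are excluded by default because allele-specific calls on
X/Y depend on sex and platform conventions. Ploidy correction is out of
scope: the counters take the segmentation at face value.

## 2. From counts to a trained signature

### Normalization

Counts are normalized by median-of-ratios size factors (the standard
RNA-seq estimator: per sample, the median over all-positive genes of the
count over its across-sample geometric mean) and transformed as
`log2(count / factor + 1)`. This is a deliberately simple monotone
transform rather than a full variance-stabilizing transform: the
downstream enrichment statistic is rank-based *within* each sample, so
any per-gene-comparable monotone transform produces identical expHRD
scores. Users who prefer another tool's variance-stabilized output can
read it with `unit = "normalized"` and skip this stage. Batch
correction is intentionally not provided.

### Differential-expression pre-filter

Genes are screened by a per-gene Welch two-sample t-test between
scar-high (`scar ≥ 42`) and scar-low samples on the normalized scale,
with Benjamini–Hochberg adjustment; a gene passes at
`adjusted_p ≤ alpha` (default 0.05) and `|log2 mean difference| ≥
min_abs_effect` (default 0). A moderated or count-based test would be
defensible here; the Welch test was chosen because this stage is only a
pre-filter — the elastic net re-selects features — so what matters is a
sensible ranking, not exact error control. Both knobs are exposed
because the appropriate stringency depends on cohort size.

### Elastic net and hyperparameters

The regression of scar score $y$ on the filtered expression matrix $X$
minimizes

$$\min_w \frac{1}{2n}\lVert Xw - y\rVert_2^2
  + \alpha\rho\lVert w\rVert_1
  + \frac{\alpha(1-\rho)}{2}\lVert w\rVert_2^2,$$

with columns standardized internally (mean 0, variance 1 with the $1/n$
convention) and weights reported back on the original scale. The solver
is glmnet's coordinate descent, driven down a warm-start path that ends
exactly at the requested penalty with a $10^{-16}$ convergence
threshold; because glmnet internally rescales a gaussian response to
unit variance — which would silently change the L1/L2 mix of the
objective above — the wrapper feeds it a unit-variance response and
remaps $(\alpha, \rho)$ so that the minimized objective is exactly the
stated one. The test suite holds the solution to within $10^{-8}$ in
objective value of an independent coordinate-descent implementation, to
the least-squares closed form at $\alpha = 0$, and to the exact null
model above the lasso bound.

$(\alpha, \rho)$ come from a five-fold grid search (default grid
$\alpha \in \{0.01, 0.03, 0.1, 0.3, 1, 3, 10\}$,
$\rho \in \{0.1, 0.3, 0.5, 0.7, 0.9, 1\}$) minimizing mean validation
MSE, with deterministic fold assignment from the seed and ties broken
toward smaller $\alpha$, then larger $\rho$ — preferring less shrinkage
and sparser mixes, in that order, so the argmin is unique and
reproducible.

### Stability selection and signed gene sets

With hyperparameters fixed, the model is refit $B = 100$ times on
random subsets of 80% of the samples, drawn **without** replacement:
the selection should reflect sampling variability, not duplicated
observations, though `replace = TRUE` provides the classical bootstrap
reading. A first elastic-net fit prunes the DEG-filtered genes to the
nonzero set, a second-round refit on the survivors prunes again, and
stability selection runs on that reduced set. Genes nonzero in at least
`ceiling(f_min * B)` refits — 98 of 100 at the defaults — are retained.
Retained genes are split by the sign of their *mean coefficient across
refits* into the positive and negative HRD gene set; the bootstrap, not
the single initial fit, is the authority on both retention and sign,
and a retained gene whose refit coefficients disagree in sign is
dropped with a warning. An empty positive or negative set aborts
training, since the difference statistic below would be undefined.

## 3. n-of-1 scoring: ssGSEA and expHRD

The enrichment kernel is implemented from scratch. For one sample,
genes are ranked by decreasing expression; at each rank position the
running difference between the weighted in-set empirical distribution
and the unweighted out-of-set distribution is accumulated, and the
score is the *sum* over all positions (the integrated single-sample
form, not max-deviation GSEA). In the default **rank mode** the gene at
position $p$ of $N$ carries weight $(N - p + 1)^\tau$ with
$\tau = 0.25$. Weighting by rank rather than by raw expression
magnitude is a deliberate choice: it makes the score invariant under
any strictly increasing transform of one sample's values, which in turn
makes single-sample scoring exactly reproducible regardless of units or
normalization — the property the n-of-1 deployment depends on. A
value-weighted mode is available behind a flag for compatibility
experiments with value-weighted implementations; exact numerical
agreement with any external ssGSEA implementation is not claimed.

Ties are broken by gene label after a canonical radix sort, so scores
are bit-reproducible. Cross-sample normalization (rescaling by the
cohort score range) is off by default because it re-introduces cohort
dependence; when enabled, the constant is stored in the model archive
so deployment stays cohort-independent.

The statistic is

$$\mathrm{expHRD} = \mathrm{ssGSEA}(\text{positive set})
                  - \mathrm{ssGSEA}(\text{negative set}),$$

computed per sample. Swapping the two sets negates it exactly; scoring
a sample alone or inside any cohort gives bit-identical values.

## 4. Calibration, intervals, thresholds

expHRD is mapped to the scar scale by ordinary least squares of scar on
expHRD over a paired cohort. The model archive stores the sufficient
statistics (residual SD, $n$, $\bar{x}$, $S_{xx}$) so that a new
sample's predicted scar score carries the textbook **new-observation
prediction interval**

$$\hat{y}_0 \pm t_{0.975,\,n-2}\, s
  \sqrt{1 + \tfrac{1}{n} + \tfrac{(x_0-\bar{x})^2}{S_{xx}}}.$$

The prediction interval — not the narrower mean-response confidence
interval — is the default because the reported bracket is for an
individual sample's score; `interval = "mean"` gives the alternative.
Classification uses two inclusive thresholds stored in the archive:
`expHRD ≥ 1000` labels a sample HRD-high on the enrichment scale, and
predicted scar `≥ 42` labels it HRD-positive on the scar scale. The
1000 cutoff is stored rather than hard-coded because expHRD's numeric
range depends on the gene-universe size and $\tau$; it is meaningful
for genome-wide signatures and must be re-derived if the
parameterization changes. A degenerate calibration (constant expHRD) is
an error, and `residual_sd = 0` collapses the interval to the point
prediction.

## 5. What the synthetic-data generator does and does not emulate

`simulate_expression()` draws a latent per-sample score uniform on
(0, 100) — the scar scale, so the 42 cutoff is exercised — and
gamma-Poisson counts (dispersion 0.2, the typical RNA-seq
overdispersion magnitude) whose log-mean for causal genes is linear in
the standardized latent score with slope ±`effect_size`, plus
log-normal baselines (log-mean log 60, SD 1), per-sample library-size
factors uniform on (0.7, 1.4), and 0.3 SD log-scale observation noise.
The reference design used throughout the tests and the acceptance
script is 500 samples (400 train / 100 held-out), 1000 genes, 50
positive + 50 negative causal genes at effect size 0.8 — small enough
to run in about two minutes yet large enough that signature recovery
and held-out correlation are stable properties, not luck.

`simulate_segments()` plants exact event counts on a GRCh38 autosome
build: each event on its own chromosome, isolated by ≥ 3 Mb gaps from
balanced diploid flanks so no incidental LST can form, with imbalanced
material kept off the telomeres (LOH, LST) or anchored on the
q-telomere short of the centromere (TAI). The generator re-counts its
own output and refuses to return a profile whose counts differ from the
request, which is what makes the generator/counter closure test a real
two-sided check.

What passing these tests shows is that the pipeline recovers a planted
monotone expression–scar relationship and counts planted scar events
exactly. What they cannot show: performance under real gene–gene
correlation structure, batch effects, cancer-type composition, or
segmentation noise — none of which the generator attempts to mimic.
Published headline performance numbers on consortium cohorts are
likewise not reproducible from synthetic data, and the package makes no
claim to reproduce them.

## 6. Degenerate inputs and error policy

Readers reject rather than repair: duplicate gene identifiers, ragged
rows, non-numeric cells, overlapping or out-of-bounds segments and
unknown chromosomes are hard errors naming the offending location.
Zero-variance genes are excluded from elastic-net fits with weight 0
and a warning. Evaluation metrics with zero denominators are reported
as explicitly undefined (`NA` plus an `"undefined"` flag), never
silently 0, because silent zeros corrupt small-cohort comparisons. All
randomness flows from one global seed through a documented per-stage
hash (`derive_seed`), so every stage — and the whole pipeline — is
byte-reproducible; rerunning training with the same config writes an
identical model archive.

## 7. Known limitations

* The DEG pre-filter's test and cutoffs, and the per-iteration
  subsample size, are parameterized conventions, not canonical values;
  defaults are documented above and exposed in the config.
* The scar counters interpret one common convention set
  (whole-chromosome LOH excluded, strict 15 Mb / 3 Mb rules, inclusive
  10 Mb); other tools' parameter sets can differ, which is why each
  rule is a flag rather than a constant.
* expHRD inherits the scar score's blind spots: it predicts the scar
  phenotype, not current functional HR status, so reversion events that
  restore repair without erasing scars will not lower the score.
* Gene identifiers are opaque labels; mapping between annotation
  systems is the user's responsibility.
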