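# Genomic scar counting: LOH, LST, TAI from allele-specific segments.
# All three counters work chromosome by chromosome, so counts are additive
# over chromosomes and independent of chromosome order. Sex chromosomes are
# excluded by default (allele-specific calls on X/Y are convention-bound).

scar_chroms <- function(profile, include_sex) {
  chroms <- unique(profile$segments$chrom)
  if (!include_sex) chroms <- chroms[is_autosome(chroms)]
  chroms
}

check_profile_build <- function(profile, build) {
  stopifnot(inherits(profile, "SegmentProfile"), inherits(build, "GenomeBuild"))
  unknown <- setdiff(unique(profile$segments$chrom), names(build$chrom_lengths))
  if (length(unknown))
    stopf("sample %s: chromosome '%s' absent from build",
          profile$sample_id, unknown[1L])
}

# Merge abutting runs (gap == 0) of rows flagged TRUE into (start, end) spans.
merge_runs <- function(seg, flag) {
  spans <- NULL
  i <- 1L
  n <- nrow(seg)
  while (i <= n) {
    if (!flag[i]) { i <- i + 1L; next }
    s <- seg$start[i]
    e <- seg$end[i]
    j <- i + 1L
    while (j <= n && flag[j] && seg$start[j] == e) {
      e <- seg$end[j]
      j <- j + 1L
    }
    spans <- rbind(spans, c(s, e))
    i <- j
  }
  spans
}

#' Count LOH events
#'
#' Loss of heterozygosity: a maximal run of abutting segments with
#' `minor_cn == 0` whose merged length exceeds `min_length` (default 15 Mb,
#' strict: exactly 15 Mb does not count). Runs spanning an entire chromosome
#' are excluded by default, following the genomic-scar literature's
#' convention for whole-chromosome loss; set `count_whole_chrom = TRUE` for
#' the literal reading that counts them.
#'
#' @param profile a [segment_profile()].
#' @param build a [genome_build()].
#' @param min_length minimal (exclusive) run length in bp; default 15 Mb.
#' @param count_whole_chrom count runs covering the whole chromosome?
#' @param include_sex include sex chromosomes?
#' @return integer event count.
#' @export
count_loh <- function(profile, build, min_length = 15e6,
                      count_whole_chrom = FALSE, include_sex = FALSE) {
  check_profile_build(profile, build)
  total <- 0L
  for (chr in scar_chroms(profile, include_sex)) {
    seg <- profile$segments[profile$segments$chrom == chr, ]
    spans <- merge_runs(seg, seg$minor_cn == 0 & seg$total_cn > 0)
    if (is.null(spans)) next
    len <- spans[, 2] - spans[, 1]
    whole <- spans[, 1] == 0 & spans[, 2] == build$chrom_lengths[chr]
    keep <- len > min_length & (count_whole_chrom | !whole)
    total <- total + sum(keep)
  }
  as.integer(total)
}

# Smoothing for LST: drop segments shorter than `smooth_below` that sit
# between two abutting segments in the same copy state, merging the three
# into one. Repeated until stable.
smooth_segments <- function(seg, smooth_below) {
  repeat {
    n <- nrow(seg)
    if (n < 3L) return(seg)
    hit <- NA_integer_
    for (i in 2:(n - 1L)) {
      short <- (seg$end[i] - seg$start[i]) < smooth_below
      same_state <- seg$total_cn[i - 1L] == seg$total_cn[i + 1L] &&
        seg$minor_cn[i - 1L] == seg$minor_cn[i + 1L]
      abut <- seg$start[i] == seg$end[i - 1L] && seg$end[i] == seg$start[i + 1L]
      if (short && same_state && abut) { hit <- i; break }
    }
    if (is.na(hit)) return(seg)
    seg$end[hit - 1L] <- seg$end[hit + 1L]
    seg <- seg[-c(hit, hit + 1L), , drop = FALSE]
  }
}

#' Count LST events
#'
#' Large-scale state transitions: after smoothing away sub-`smooth_below`
#' segments flanked by equal copy states, a breakpoint counts when the two
#' flanking segments are each at least `min_segment` long, the copy state
#' `(total_cn, minor_cn)` changes across it, and the gap between the
#' segments is strictly below `max_gap`.
#'
#' @param profile a [segment_profile()].
#' @param build a [genome_build()].
#' @param min_segment minimal flanking segment length in bp (default 10 Mb,
#'   inclusive).
#' @param max_gap maximal inter-segment gap in bp (default 3 Mb, strict).
#' @param smooth_below segments shorter than this flanked by equal states
#'   are merged away first (default 3 Mb).
#' @param include_sex include sex chromosomes?
#' @return integer event count.
#' @export
count_lst <- function(profile, build, min_segment = 10e6, max_gap = 3e6,
                      smooth_below = 3e6, include_sex = FALSE) {
  check_profile_build(profile, build)
  total <- 0L
  for (chr in scar_chroms(profile, include_sex)) {
    seg <- profile$segments[profile$segments$chrom == chr, ]
    seg <- smooth_segments(seg, smooth_below)
    n <- nrow(seg)
    if (n < 2L) next
    len <- seg$end - seg$start
    for (i in seq_len(n - 1L)) {
      changed <- seg$total_cn[i] != seg$total_cn[i + 1L] ||
        seg$minor_cn[i] != seg$minor_cn[i + 1L]
      gap <- seg$start[i + 1L] - seg$end[i]
      if (changed && gap < max_gap &&
          len[i] >= min_segment && len[i + 1L] >= min_segment)
        total <- total + 1L
    }
  }
  as.integer(total)
}

#' Count TAI events
#'
#' Telomeric allelic imbalance: a maximal run of abutting allele-imbalanced
#' segments (`total_cn - minor_cn != minor_cn`) that touches a chromosome
#' end (within `telomere_tolerance` bp of position 0 or of the chromosome
#' length), does not span the entire chromosome, and — when the build
#' carries centromeres — does not cross the centromere (i.e. does not span
#' the whole centromere interval into the other arm).
#'
#' @param profile a [segment_profile()].
#' @param build a [genome_build()]; centromeres recommended.
#' @param telomere_tolerance bp tolerance for "touches the chromosome end"
#'   (default 0: the run must abut the recorded end).
#' @param include_sex include sex chromosomes?
#' @return integer event count.
#' @export
count_tai <- function(profile, build, telomere_tolerance = 0,
                      include_sex = FALSE) {
  check_profile_build(profile, build)
  total <- 0L
  for (chr in scar_chroms(profile, include_sex)) {
    seg <- profile$segments[profile$segments$chrom == chr, ]
    spans <- merge_runs(seg, seg$total_cn - seg$minor_cn != seg$minor_cn)
    if (is.null(spans)) next
    L <- build$chrom_lengths[[chr]]
    at_start <- spans[, 1] <= telomere_tolerance
    at_end <- spans[, 2] >= L - telomere_tolerance
    whole <- at_start & at_end
    keep <- (at_start | at_end) & !whole
    if (!is.null(build$centromeres) && chr %in% rownames(build$centromeres)) {
      cen <- build$centromeres[chr, ]
      crosses <- spans[, 1] < cen$start & spans[, 2] > cen$end
      keep <- keep & !crosses
    }
    total <- total + sum(keep)
  }
  as.integer(total)
}

#' Genomic scar score for one sample
#'
#' The aggregate genomic instability score: the sum of LOH, LST and TAI
#' event counts. Additional arguments are passed through to the three
#' counters.
#'
#' @param profile a [segment_profile()].
#' @param build a [genome_build()].
#' @param ... passed to [count_loh()], [count_lst()], [count_tai()]
#'   (matching arguments only).
#' @return a `ScarResult` list: `sample_id`, `loh`, `lst`, `tai`,
#'   `scar_total` (= loh + lst + tai).
#' @export
scar_score <- function(profile, build, ...) {
  dots <- list(...)
  pick <- function(fn) dots[intersect(names(dots), names(formals(fn)))]
  loh <- do.call(count_loh, c(list(profile, build), pick(count_loh)))
  lst <- do.call(count_lst, c(list(profile, build), pick(count_lst)))
  tai <- do.call(count_tai, c(list(profile, build), pick(count_tai)))
  structure(list(sample_id = profile$sample_id, loh = loh, lst = lst,
                 tai = tai, scar_total = loh + lst + tai),
            class = "ScarResult")
}

#' @export
print.ScarResult <- function(x, ...) {
  cat(sprintf("ScarResult '%s': LOH %d + LST %d + TAI %d = %d\n",
              x$sample_id, x$loh, x$lst, x$tai, x$scar_total))
  invisible(x)
}

#' Scar scores for several samples
#'
#' @param profiles list of [segment_profile()]s.
#' @param build a [genome_build()].
#' @param ... passed to [scar_score()].
#' @return data.frame with columns `sample`, `loh`, `lst`, `tai`,
#'   `scar_total`.
#' @export
scar_scores <- function(profiles, build, ...) {
  rows <- lapply(profiles, function(p) {
    r <- scar_score(p, build, ...)
    data.frame(sample = r$sample_id, loh = r$loh, lst = r$lst, tai = r$tai,
               scar_total = r$scar_total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
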