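#' Construct an allele-specific segment profile
#'
#' One sample's allele-specific copy-number segments. Internally the package
#' uses 0-based half-open coordinates (file I/O converts from the SEG
#' convention of 1-based inclusive). Canonicalization enforces: the minor
#' allele is the lesser of the two allele copy numbers
#' (`minor_cn <- min(minor_cn, total_cn - minor_cn)`); segments are sorted
#' by chromosome and start; within a chromosome segments must not overlap.
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `total_cn`, `minor_cn`.
#' @param build optional [genome_build()]; when given, segments must lie
#'   within their chromosome and reference only known chromosomes.
#' @return a `SegmentProfile`.
#' @export
segment_profile <- function(sample_id, segments, build = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(segments)))
    stopf("segments need columns: %s", paste(need, collapse = ", "))
  seg <- segments[, need]
  seg$chrom <- normalize_chrom(seg$chrom)
  for (col in c("start", "end", "total_cn", "minor_cn")) {
    seg[[col]] <- as.numeric(seg[[col]])
    if (anyNA(seg[[col]])) stopf("sample %s: non-numeric %s", sample_id, col)
  }
  if (any(seg$total_cn < 0) || any(seg$minor_cn < 0) ||
      any(seg$total_cn != floor(seg$total_cn)) ||
      any(seg$minor_cn != floor(seg$minor_cn)))
    stopf("sample %s: copy numbers must be non-negative integers", sample_id)
  if (any(seg$minor_cn > seg$total_cn))
    stopf("sample %s: minor_cn exceeds total_cn", sample_id)
  if (any(seg$start >= seg$end))
    stopf("sample %s: segment with start >= end", sample_id)
  # canonical minor allele = lesser allele
  seg$minor_cn <- pmin(seg$minor_cn, seg$total_cn - seg$minor_cn)
  if (!is.null(build)) {
    unknown <- setdiff(seg$chrom, names(build$chrom_lengths))
    if (length(unknown))
      stopf("sample %s: unknown chromosome '%s'", sample_id, unknown[1L])
    over <- seg$end > build$chrom_lengths[seg$chrom] | seg$start < 0
    if (any(over))
      stopf("sample %s: segment %s:%d-%d extends past chromosome bounds",
            sample_id, seg$chrom[over][1L],
            seg$start[over][1L], seg$end[over][1L])
  }
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, ]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stopf("sample %s: overlapping segments on %s", sample_id, chr)
  }
  structure(list(sample_id = sample_id, segments = seg),
            class = "SegmentProfile")
}

#' @export
print.SegmentProfile <- function(x, ...) {
  cat(sprintf("SegmentProfile '%s': %d segments on %d chromosomes\n",
              x$sample_id, nrow(x$segments), length(unique(x$segments$chrom))))
  invisible(x)
}

#' Read allele-specific copy-number segments (SEG-like TSV)
#'
#' Expected header columns: `sample`, `chrom`, `start`, `end`, `total_cn`,
#' `minor_cn`, with 1-based inclusive coordinates as in SEG files.
#' Coordinates are converted to the package-internal 0-based half-open
#' convention; the minor allele is canonicalized to the lesser allele.
#' Out-of-bounds segments, overlapping segments within a sample/chromosome
#' and unknown chromosomes are hard errors.
#'
#' @param path file path.
#' @param build a [genome_build()] used for bounds checking.
#' @return named list of [segment_profile()], one per sample.
#' @export
read_segments <- function(path, build) {
  stopifnot(inherits(build, "GenomeBuild"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(tab)))
    stopf("%s: missing column(s): %s", path,
          paste(setdiff(need, names(tab)), collapse = ", "))
  if (any(tab$start < 1)) stopf("%s: 1-based start below 1", path)
  # 1-based inclusive -> 0-based half-open
  tab$start <- tab$start - 1
  profiles <- lapply(split(tab, tab$sample), function(s) {
    segment_profile(s$sample[1L], s[, need[-1L]], build = build)
  })
  profiles[unique(tab$sample)]
}

#' Write segment profiles as SEG-like TSV (1-based inclusive)
#'
#' @param profiles list of `SegmentProfile`s (or one profile).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "SegmentProfile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    s <- p$segments
    data.frame(sample = p$sample_id, chrom = s$chrom,
               start = s$start + 1, end = s$end,
               total_cn = s$total_cn, minor_cn = s$minor_cn)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
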