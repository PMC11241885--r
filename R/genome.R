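#' Construct a genome build
#'
#' Chromosome lengths plus optional centromere intervals. Chromosome names
#' are normalized to the "chr"-prefixed dialect ("1" and "chr1" both become
#' "chr1"). Centromere intervals use 0-based half-open coordinates and must
#' lie within their chromosome.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param centromeres optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return a `GenomeBuild` list with elements `chrom_lengths`, `centromeres`.
#' @export
genome_build <- function(chrom_lengths, centromeres = NULL) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stopf("chrom_lengths must be a named vector")
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  if (anyDuplicated(names(chrom_lengths)))
    stopf("duplicate chromosome name after normalization")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stopf("chromosome lengths must be positive and finite")
  if (!is.null(centromeres)) {
    stopifnot(is.data.frame(centromeres),
              all(c("chrom", "start", "end") %in% names(centromeres)))
    centromeres$chrom <- normalize_chrom(centromeres$chrom)
    unknown <- setdiff(centromeres$chrom, names(chrom_lengths))
    if (length(unknown))
      stopf("centromere for unknown chromosome: %s", unknown[1L])
    len <- chrom_lengths[centromeres$chrom]
    if (any(centromeres$start < 0) || any(centromeres$end > len) ||
        any(centromeres$start >= centromeres$end))
      stopf("centromere interval outside [0, chrom_length)")
    rownames(centromeres) <- centromeres$chrom
  }
  structure(list(chrom_lengths = chrom_lengths, centromeres = centromeres),
            class = "GenomeBuild")
}

#' @export
print.GenomeBuild <- function(x, ...) {
  cat(sprintf("GenomeBuild: %d chromosomes, %.1f Mb total%s\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              if (is.null(x$centromeres)) "" else ", with centromeres"))
  invisible(x)
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @param centromere_path optional BED3 file (0-based half-open) of
#'   centromere intervals.
#' @return a [genome_build()].
#' @export
read_chrom_sizes <- function(path, centromere_path = NULL) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stopf("%s: expected two tab-separated columns", path)
  lens <- as.numeric(tab[[2L]])
  if (anyNA(lens)) stopf("%s: non-numeric chromosome length", path)
  names(lens) <- tab[[1L]]
  cen <- NULL
  if (!is.null(centromere_path)) {
    bed <- utils::read.delim(centromere_path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 3L) stopf("%s: expected BED3", centromere_path)
    cen <- data.frame(chrom = bed[[1L]], start = as.numeric(bed[[2L]]),
                      end = as.numeric(bed[[3L]]))
  }
  genome_build(lens, cen)
}

#' GRCh38 autosome reference build
#'
#' The 22 human autosomes with GRCh38 sequence lengths and approximate
#' centromere intervals (rounded to 0.1 Mb; adequate for arm-level event
#' placement and telomeric/centromeric tests, not for base-precise work).
#'
#' @return a [genome_build()] with centromeres.
#' @export
grch38_autosomes <- function() {
  lens <- c(
    chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
    chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468)
  cen_mb <- rbind(
    chr1 = c(121.7, 125.1), chr2 = c(91.8, 96.0), chr3 = c(87.8, 94.0),
    chr4 = c(48.2, 51.8), chr5 = c(46.1, 50.1), chr6 = c(58.5, 62.6),
    chr7 = c(58.1, 62.4), chr8 = c(43.2, 47.2), chr9 = c(42.2, 45.5),
    chr10 = c(38.0, 41.6), chr11 = c(51.0, 55.8), chr12 = c(34.7, 37.2),
    chr13 = c(16.0, 18.1), chr14 = c(16.0, 18.2), chr15 = c(17.0, 19.7),
    chr16 = c(36.3, 38.3), chr17 = c(22.7, 27.4), chr18 = c(15.4, 20.9),
    chr19 = c(24.4, 28.1), chr20 = c(25.7, 30.4), chr21 = c(10.9, 13.0),
    chr22 = c(13.7, 17.4))
  cen <- data.frame(chrom = rownames(cen_mb),
                    start = cen_mb[, 1] * 1e6, end = cen_mb[, 2] * 1e6)
  genome_build(lens, cen)
}
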