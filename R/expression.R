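#' Construct an expression matrix
#'
#' A light container for a gene-by-sample numeric matrix tagged with its
#' unit. `unit = "counts"` asserts non-negative, finite values (raw counts);
#' `unit = "normalized"` places no sign constraint (e.g. log-scale values).
#' Gene and sample identifiers must be unique and non-empty; duplicates are
#' an error, never silently collapsed.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames.
#' @param unit `"counts"` or `"normalized"`.
#' @return an `ExpressionMatrix`: the matrix with a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("counts", "normalized")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("expression values must be a numeric matrix")
  gn <- rownames(values)
  sn <- colnames(values)
  if (is.null(gn) || is.null(sn))
    stopf("expression matrix needs gene rownames and sample colnames")
  if (any(gn == "") || any(is.na(gn)))
    stopf("every gene needs a non-empty identifier")
  if (anyDuplicated(gn))
    stopf("duplicate gene identifier(s): %s",
          paste(unique(gn[duplicated(gn)]), collapse = ", "))
  if (anyDuplicated(sn))
    stopf("duplicate sample identifier(s): %s",
          paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (unit == "counts") {
    if (any(!is.finite(values)))
      stopf("count matrix contains non-finite values")
    if (any(values < 0))
      stopf("count matrix contains negative values")
  }
  structure(values, unit = unit, class = c("ExpressionMatrix", class(values)))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (unit = %s)\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return `"counts"` or `"normalized"`.
#' @export
expression_unit <- function(x) attr(x, "unit") %||% "normalized"

#' Read a gene-by-sample expression table
#'
#' Tab-separated text; first column holds gene identifiers, the header row
#' holds sample identifiers. The reader validates rather than repairs:
#' duplicate gene identifiers, ragged rows and non-numeric cells are hard
#' errors naming the offending location. All-zero rows are retained —
#' filtering is the preprocessing stage's job.
#'
#' @param path file path.
#' @param unit_hint `"counts"` or `"normalized"`; recorded as the unit tag.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, unit_hint = c("counts", "normalized")) {
  unit_hint <- match.arg(unit_hint)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("%s: need a header plus at least one gene row", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expect <- length(header)
  samples <- header[-1L]
  if (length(samples) == 0L) stopf("%s: no sample columns", path)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != ncol_expect)) {
    bad <- which(widths != ncol_expect)[1L]
    stopf("%s: ragged row at line %d (%d fields, expected %d)",
          path, bad + 1L, widths[bad], ncol_expect)
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  if (any(genes == ""))
    stopf("%s: gene identifier missing at line %d", path,
          which(genes == "")[1L] + 1L)
  if (anyDuplicated(genes))
    stopf("%s: duplicate gene identifier '%s'", path,
          genes[duplicated(genes)][1L])
  raw <- vapply(body, function(f) f[-1L], character(ncol_expect - 1L))
  raw <- matrix(raw, nrow = ncol_expect - 1L) # columns = genes here
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num) && !all(raw[is.na(num)] == "NA")) {
    bad <- which(is.na(num) & raw != "NA")[1L]
    gi <- (bad - 1L) %/% (ncol_expect - 1L) + 1L
    ci <- (bad - 1L) %% (ncol_expect - 1L) + 1L
    stopf("%s: non-numeric value '%s' for gene '%s', sample '%s'",
          path, raw[bad], genes[gi], samples[ci])
  }
  values <- matrix(num, nrow = ncol_expect - 1L)
  values <- t(values)
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, unit_hint)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written at full double precision so `read_expression()`
#' round-trips exactly.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format_full(x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
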