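#' Construct a gene set
#'
#' @param name set name.
#' @param description free-text description.
#' @param genes character vector of unique gene labels; gene identifiers are
#'   treated as opaque labels (no symbol mapping is performed).
#' @return a `GeneSet`.
#' @export
gene_set <- function(name, genes, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0L) stopf("gene set '%s' is empty", name)
  if (anyDuplicated(genes))
    stopf("gene set '%s' has duplicate gene(s): %s", name,
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(list(name = name, description = description, genes = genes),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name TAB description TAB gene TAB gene ...`. Lines with fewer than three
#' fields and duplicate genes within a line are hard errors.
#'
#' @param path file path.
#' @return named list of [gene_set()]s in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopf("%s: line %d has %d field(s), need at least 3", path, i, length(f))
    gene_set(f[1L], f[-(1:2)], f[2L])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of `GeneSet`s (or one set).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
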