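# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a per-stage random seed from one global seed
#'
#' One global seed fans out to independent per-stage seeds so that every
#' pipeline stage is reproducible on its own without seed collisions between
#' stages. The derivation is a polynomial rolling hash of the stage label
#' (base 31, modulo 2^31 - 1) folded into the global seed; the result is a
#' positive integer below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"cv"` or `"stability"`.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  s <- (abs(as.numeric(seed)) %% m + h * 2654435.0) %% m
  as.integer(s %% (m - 1)) + 1L
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Chromosome names are normalized to the "chr"-prefixed dialect.
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

is_autosome <- function(chrom) grepl("^chr[0-9]+$", chrom)

# Format numbers for TSV output so that read -> write -> read is lossless.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.17g", v)
  }, character(1))
  out
}
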