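test_that("expression reader validates and round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2",
               "TP53\t1.5\t2",
               "BRCA1\t0\t7.25",
               "ZERO\t0\t0"), path)
  em <- read_expression(path, "counts")
  expect_s3_class(em, "ExpressionMatrix")
  expect_equal(dim(em), c(3L, 2L))
  expect_equal(em["TP53", "s2"], 2)
  expect_equal(em["ZERO", ], c(s1 = 0, s2 = 0)) # all-zero rows retained

  out <- withr::local_tempfile(fileext = ".tsv")
  set.seed(4)
  vals <- matrix(rexp(12) * pi, 4, 3,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  write_expression(expression_matrix(vals, "normalized"), out)
  back <- read_expression(out, "normalized")
  expect_identical(unclass(back)[, ], vals) # full precision
  # byte-stable rewrite of a canonical file
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(back, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("malformed expression input fails with located errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "TP53\t1", "TP53\t2"), dup)
  expect_error(read_expression(dup), "TP53")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\t1"), ragged)
  expect_error(read_expression(ragged), "ragged row at line 3")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\ttwo"), bad)
  expect_error(read_expression(bad), "non-numeric value 'two'.*sample 's2'")

  expect_error(expression_matrix(
    matrix(-1, 1, 1, dimnames = list("g", "s")), "counts"), "negative")
})

test_that("segment reader converts coordinates and canonicalizes alleles", {
  build <- genome_build(c(chr1 = 248956422, chr2 = 100e6))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
               "S1\tchr1\t1\t1000\t2\t1",
               "S1\t2\t501\t2000\t4\t3"), path)
  prof <- read_segments(path, build)
  expect_named(prof, "S1")
  seg <- prof$S1$segments
  # 1-based inclusive -> 0-based half-open
  expect_equal(seg$start[seg$chrom == "chr1"], 0)
  expect_equal(seg$end[seg$chrom == "chr1"], 1000)
  # "2" normalized to "chr2"; minor 3 of total 4 canonicalized to lesser 1
  expect_equal(seg$minor_cn[seg$chrom == "chr2"], 1)

  # round trip preserves the profile
  out <- withr::local_tempfile(fileext = ".tsv")
  write_segments(prof, out)
  expect_equal(read_segments(out, build)$S1$segments, prof$S1$segments)
})

test_that("segment reader rejects out-of-bounds, overlap, unknown chrom", {
  build <- genome_build(c(chr1 = 248956422))
  header <- "sample\tchrom\tstart\tend\ttotal_cn\tminor_cn"
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, "S1\tchr1\t1\t300000000\t2\t1"), p)
  expect_error(read_segments(p, build), "past chromosome")
  writeLines(c(header, "S1\tchr1\t1\t5000\t2\t1",
               "S1\tchr1\t4000\t9000\t2\t1"), p)
  expect_error(read_segments(p, build), "overlap")
  writeLines(c(header, "S1\tchr9\t1\t100\t2\t1"), p)
  expect_error(read_segments(p, build), "unknown chromosome")
})

test_that("GMT files parse, validate and round-trip in order", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("HRD_POS\tdesc\tA\tB", "HRD_NEG\t\tC\tD\tE"), path)
  sets <- read_gmt(path)
  expect_equal(sets$HRD_POS$genes, c("A", "B"))
  expect_equal(length(sets$HRD_NEG$genes), 3L)

  short <- withr::local_tempfile(fileext = ".gmt")
  writeLines("ONLY_NAME\tdesc", short)
  expect_error(read_gmt(short), "line 1")

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S\td\tA\tA", dup)
  expect_error(read_gmt(dup), "duplicate")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(read_gmt(out), sets)
})

test_that("chrom.sizes and centromere BED load into a validated build", {
  cs <- withr::local_tempfile()
  writeLines(c("chr1\t100000000", "chr2\t80000000"), cs)
  bed <- withr::local_tempfile()
  writeLines("chr1\t45000000\t50000000", bed)
  b <- read_chrom_sizes(cs, bed)
  expect_equal(unname(b$chrom_lengths["chr1"]), 1e8)
  expect_equal(b$centromeres$start, 45e6)
  bad <- withr::local_tempfile()
  writeLines("chr1\t90000000\t110000000", bad)
  expect_error(read_chrom_sizes(cs, bad), "centromere")
})

test_that("model archive round-trips through JSON", {
  sets <- structure(list(positive = gene_set("HRD_POS", c("A", "B")),
                         negative = gene_set("HRD_NEG", c("C"))),
                    class = "HRDGeneSets")
  cal <- calibrate_exphrd(c(1, 2, 3, 4, 5.5), c(10, 21, 29, 44, 50))
  model <- calibrated_model(sets, cal, ssgsea_params(tau = 0.5),
                            provenance = list(seed = 7L))
  path <- withr::local_tempfile(fileext = ".json")
  write_hrd_model(model, path)
  back <- read_hrd_model(path)
  expect_equal(back$gene_sets$positive$genes, c("A", "B"))
  expect_equal(back$calibration$slope, model$calibration$slope)
  expect_equal(back$ssgsea$tau, 0.5)
  expect_equal(back$thresholds$exphrd_high, 1000)
  # rewriting the loaded model is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_hrd_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
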