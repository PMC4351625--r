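test_that("cytosine report lines map to records field by field", {
  f <- withr::local_tempfile()
  writeLines(c("Chr1\t104\t+\t7\t3\tCG\tCGA",
               "Chr1\t105\t-\t0\t12\tCHH\tCAT"), f)
  tab <- readCytosineReport(f, "plantA")
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "sample"), "plantA")
  expect_equal(tab$chrom[1], "Chr1")
  expect_equal(tab$pos[1], 104L)
  expect_equal(tab$strand[1], "+")
  expect_equal(tab$meth[1], 7L)
  expect_equal(tab$unmeth[1], 3L)
  expect_equal(tab$context[1], "CG")
  expect_equal(tab$trinucleotide[2], "CAT")
})

test_that("empty report gives empty table; bad lines are rejected by line", {
  f <- withr::local_tempfile()
  writeLines(character(), f)
  tab <- readCytosineReport(f, "empty")
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "sample"), "empty")

  writeLines(c("Chr1\t104\t+\t7\t3\tCG\tCGA",
               "Chr1\t104\t+\t1\t1\tCG\tCGA"), f)
  expect_error(readCytosineReport(f, "x"), "duplicate")
  writeLines(c("Chr1\t104\t+\t7\t3\tCG\tCGA",
               "Chr1\tnotanumber\t+\t7\t3\tCG\tCGA"), f)
  expect_error(readCytosineReport(f, "x"), "line 2")
  writeLines("Chr1\t104\t+\t7\t3\tCpG\tCGA", f)
  expect_error(readCytosineReport(f, "x"), "context")
  writeLines("Chr1\t104\t+", f)
  expect_error(readCytosineReport(f, "x"), "line 1")
})

test_that("per-sample reports assemble into a zero-filled count matrix", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.cx"); f2 <- file.path(d, "b.cx")
  writeLines(c("Chr1\t10\t+\t3\t1\tCG\tCGT",
               "Chr1\t50\t-\t0\t5\tCHH\tCAT"), f1)
  writeLines("Chr1\t10\t+\t1\t7\tCG\tCGT", f2)
  me <- readCytosineReports(c(a = f1, b = f2))
  expect_s4_class(me, "MethylomeExperiment")
  expect_equal(dim(me), c(2L, 2L))
  expect_equal(totalReads(me)["Chr1 10 +", "b"], 8L)
  # site absent from sample b gets zero coverage
  expect_equal(totalReads(me)["Chr1 50 -", "b"], 0L)
  expect_equal(methCounts(me)["Chr1 10 +", "a"], 3L)
})

test_that("cytosine report write/read round-trips a sample", {
  me <- makeME(pos = c(10, 25, 40), context = c("CG", "CHG", "CHH"),
               meth = cbind(a = c(3L, 0L, 5L)),
               cov = cbind(a = c(10L, 4L, 5L)))
  f <- withr::local_tempfile()
  writeCytosineReport(me, "a", f)
  tab <- readCytosineReport(f, "a")
  expect_equal(tab$meth, c(3L, 0L, 5L))
  expect_equal(tab$meth + tab$unmeth, c(10L, 4L, 5L))
  expect_equal(tab$context, c("CG", "CHG", "CHH"))
})

test_that("BED6+2 and GFF3 convert to 1-based inclusive intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr1\t999\t2000\tgeneA\t0\t+\tgene\t0",
               "Chr1\t4999\t6000\tte1\t0\t-\ttransposon\t1"), f)
  gr <- readAnnotationFeatures(f, "BED")
  expect_equal(GenomicRanges::start(gr), c(1000L, 5000L))
  expect_equal(GenomicRanges::end(gr), c(2000L, 6000L))
  expect_equal(S4Vectors::mcols(gr)$kind, c("gene", "transposon"))
  expect_equal(S4Vectors::mcols(gr)$has_te_gene, c(FALSE, TRUE))

  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\ttoy\tgene\t1000\t2000\t.\t+\t.\tID=geneA",
               paste0("Chr1\ttoy\ttransposable_element\t5000\t6000\t.\t-",
                      "\t.\tID=te1;te_gene=1")), g)
  gg <- readAnnotationFeatures(g, "GFF3")
  expect_equal(GenomicRanges::start(gg), c(1000L, 5000L))
  expect_equal(GenomicRanges::end(gg), c(2000L, 6000L))
  expect_equal(S4Vectors::mcols(gg)$kind, c("gene", "transposon"))
  expect_equal(S4Vectors::mcols(gg)$has_te_gene, c(FALSE, TRUE))
  # the BED and GFF3 readings describe the same internal intervals
  expect_equal(GenomicRanges::start(gr), GenomicRanges::start(gg))
  expect_equal(GenomicRanges::end(gr), GenomicRanges::end(gg))
})

test_that("BED -> internal -> BED is the identity on coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr1\t999\t2000\tgeneA\t0\t+\tgene\t0",
               "Chr2\t0\t150\tte9\t0\t-\ttransposon\t1"), f)
  gr <- readAnnotationFeatures(f, "BED")
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeAnnotationBed(gr, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("unknown kinds and inverted intervals are rejected", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("Chr1\t10\t20\tx\t0\t+\tenhancer\t0", f)
  expect_error(readAnnotationFeatures(f, "BED"), "kind")
})

test_that("result tables round-trip through TSV unchanged", {
  tabs <- list(
    dmp = data.frame(chrom = c("Chr1", "Chr1", "Chr2"),
                     pos = c(10L, 99L, 5L),
                     p = c(1.234567891e-7, 0.4857142857142857, 1),
                     status = c("DMP", "NDMP", "untested"),
                     stringsAsFactors = FALSE),
    empty = data.frame(chrom = character(), q = numeric(),
                       stringsAsFactors = FALSE))
  d <- withr::local_tempdir()
  paths <- writeResultTables(tabs, d)
  back <- readResultTable(paths[["dmp"]])
  expect_equal(back$p, tabs$dmp$p, tolerance = 0)
  expect_equal(back$chrom, tabs$dmp$chrom)
  expect_equal(length(readLines(paths[["dmp"]])), 4L)
  # empty table writes a header-only file
  expect_equal(length(readLines(paths[["empty"]])), 1L)
})

test_that("overlap fallback flags transposons containing TE genes", {
  feats <- GenomicRanges::GRanges(
    "Chr1", IRanges::IRanges(c(100, 1000, 5000), c(900, 1900, 5400)),
    id = c("te1", "te2", "gene1"),
    kind = c("transposon", "transposon", "gene"),
    has_te_gene = FALSE)
  teg <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(1200, 1500))
  out <- flagTEGenesByOverlap(feats, teg)
  expect_equal(S4Vectors::mcols(out)$has_te_gene, c(FALSE, TRUE, FALSE))
})

test_that("chromosome size and centromere TSVs read as named vectors", {
  f <- withr::local_tempfile()
  writeLines(c("Chr1\t1000000", "Chr2\t900000"), f)
  cs <- readChromSizes(f)
  expect_identical(cs, c(Chr1 = 1000000L, Chr2 = 900000L))
  writeLines(c("Chr1\t500000", "Chr2\t450000"), f)
  expect_identical(readCentromeres(f), c(Chr1 = 5e5, Chr2 = 4.5e5))
})
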