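mkAnn <- function(starts, ends, kinds, strands = "+", teg = FALSE,
                  chrom = "Chr1", size = 1e6) {
  n <- length(starts)
  feats <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, ends),
    strand = rep_len(strands, n),
    id = paste0("f", seq_len(n)), kind = rep_len(kinds, n),
    has_te_gene = rep_len(teg, n) & rep_len(kinds, n) == "transposon")
  GenomeAnnotation(stats::setNames(size, chrom), features = feats)
}

dmpRow <- function(pos, context = "CG", status = "DMP", chrom = "Chr1") {
  data.frame(chrom = chrom, pos = pos, context = context, status = status,
             stringsAsFactors = FALSE)
}

test_that("containment and sign conventions for feature offsets", {
  ann <- mkAnn(1000, 2000, "gene")
  inGene <- assignFeatures(dmpRow(1500), ann)
  expect_equal(inGene$feature_kind, "gene")
  expect_true(inGene$contained)
  expect_equal(inGene$offset_start, 500)
  expect_equal(inGene$offset_end, -500)

  up <- assignFeatures(dmpRow(900), ann)
  expect_equal(up$offset_start, -100)  # upstream is negative
  expect_equal(up$feature_kind, "other")

  # minus-strand gene: upstream lies at higher coordinates
  annM <- mkAnn(1000, 2000, "gene", strands = "-")
  upM <- assignFeatures(dmpRow(2100), annM)
  expect_equal(upM$offset_start, -100)
})

test_that("a transposon with a TE gene labels its DMPs te_gene and wins
           containment ties", {
  ann <- mkAnn(starts = c(1000, 1200), ends = c(3000, 2000),
               kinds = c("gene", "transposon"), teg = c(FALSE, TRUE))
  hit <- assignFeatures(dmpRow(1500), ann)
  expect_equal(hit$feature_kind, "te_gene")
  expect_equal(hit$feature_id, "f2")
})

test_that("positions on unannotated chromosomes warn and stay unassigned", {
  ann <- mkAnn(1000, 2000, "gene")
  expect_warning(out <- assignFeatures(dmpRow(500, chrom = "ChrX"), ann),
                 "unassigned")
  expect_true(is.na(out$feature_id))
})

test_that("feature assignment agrees with a brute-force nearest scan", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    starts <- sort(sample(seq(1, 90000, by = 7), n))
    ends <- starts + sample(100:900, n, TRUE)
    kinds <- sample(c("gene", "transposon"), n, TRUE)
    ann <- mkAnn(starts, ends, kinds, size = 1e5)
    pos <- sample(seq(1, 1e5, by = 3), 30)
    out <- assignFeatures(dmpRow(pos), ann)
    for (i in seq_along(pos)) {
      contains <- which(starts <= pos[i] & ends >= pos[i])
      if (length(contains)) {
        prio <- c(transposon = 1L, gene = 2L)[kinds[contains]]
        w <- (ends - starts + 1)[contains]
        best <- contains[order(prio, w)][1]
        expect_equal(out$feature_id[i], paste0("f", best))
        expect_true(out$contained[i])
      } else {
        d <- pmax(starts - pos[i], pos[i] - ends)
        if (sum(d == min(d)) == 1)
          expect_equal(out$feature_id[i], paste0("f", which.min(d)))
        expect_equal(out$feature_kind[i], "other")
      }
    }
  }
})

test_that("boundary bins are length-adjusted by the hostable-feature
           proportion", {
  # 10 genes: 4 long enough (>= 1600 bp) to host the [1500,1600) bin
  starts <- seq(1000, by = 10000, length.out = 10)
  lens <- c(rep(2000, 4), rep(1200, 6))
  ann <- mkAnn(starts, starts + lens - 1, "gene")
  # 6 DMPs at offset 1550 inside the long genes
  dmps <- dmpRow(c(starts[1] + 1550, starts[2] + 1550, starts[3] + 1550,
                   starts[4] + 1550, starts[1] + 1555, starts[2] + 1555))
  prof <- boundaryProfiles(list(s1 = dmps), ann, kinds = "gene")
  b <- prof[prof$anchor == "start" & prof$context == "CG" &
            prof$offset_lo == 1500, ]
  expect_equal(b$raw, 6)
  expect_equal(b$adjusted, 6 / 0.4)  # 4 of 10 features can host the bin

  # a bin fully hostable by every feature keeps its raw count
  dmps2 <- dmpRow(starts[1:5] + 150)
  prof2 <- boundaryProfiles(list(s1 = dmps2), ann, kinds = "gene")
  b2 <- prof2[prof2$anchor == "start" & prof2$context == "CG" &
              prof2$offset_lo == 100, ]
  expect_equal(b2$adjusted, b2$raw)

  # upstream (external) bins are never length-adjusted
  b3 <- prof2[prof2$anchor == "start" & prof2$offset_lo < 0, ]
  expect_true(all(b3$adjusted == b3$raw))
})

test_that("max scaling puts the profile maximum at exactly 1 and is
           invariant to count rescaling", {
  starts <- seq(1000, by = 10000, length.out = 6)
  ann <- mkAnn(starts, starts + 2999, "gene")
  dmps <- dmpRow(c(starts[1] + 250, starts[2] + 250, starts[3] + 850))
  prof <- boundaryProfiles(list(s1 = dmps), ann, kinds = "gene")
  expect_equal(max(prof$scaled, na.rm = TRUE), 1)
  expect_true(all(prof$scaled >= 0 & prof$scaled <= 1, na.rm = TRUE))

  # tripling every DMP leaves the scaled profile unchanged
  dmps3 <- dmps[rep(seq_len(nrow(dmps)), 3), ]
  prof3 <- boundaryProfiles(list(s1 = dmps3), ann, kinds = "gene")
  expect_equal(prof3$scaled, prof$scaled, tolerance = 1e-12)

  # a single nonzero bin scales to exactly 1
  one <- boundaryProfiles(list(s1 = dmpRow(starts[1] + 50)), ann,
                          kinds = "gene")
  expect_equal(sum(one$scaled == 1, na.rm = TRUE) >= 1, TRUE)
})

test_that("bin counts plus out-of-span positions account for every DMP", {
  set.seed(5)
  starts <- seq(5000, by = 12000, length.out = 8)
  ann <- mkAnn(starts, starts + 1999, "gene")
  pos <- sample(seq(1, 1e5), 200)
  dmps <- dmpRow(pos)
  prof <- boundaryProfiles(list(s1 = dmps), ann, kinds = "gene")
  forAnchor <- prof[prof$anchor == "start" & prof$context == "CG", ]
  offs <- methylDMA:::.nearestKindOffsets(
    dmps, annotationFeatures(ann))$offset_start
  inSpan <- sum(offs >= -2000 & offs < 2000)
  expect_equal(sum(forAnchor$raw), inSpan)
})

test_that("chromosome density tracks share one genome-wide scale", {
  cs <- c(Chr1 = 1e6, Chr2 = 1e6)
  # Chr1 max window holds 40 DMPs, Chr2 max holds 10
  dmps <- rbind(dmpRow(rep(50000, 40)),
                dmpRow(rep(250000, 10), chrom = "Chr2"),
                dmpRow(rep(70000, 25), status = "NDMP"))
  dens <- chromosomeDensity(dmps, cs, window = 1e5)
  expect_equal(max(dens$dmp_scaled), 1)
  expect_equal(dens$dmp_scaled[dens$chrom == "Chr2" &
                               dens$start == 200001], 0.25)
  expect_true(all(dens$dmp_scaled[dens$n_dmp == 0] == 0))
  expect_equal(nrow(dens), 20)  # 10 windows per chromosome
})

test_that("TE-gene enrichment reproduces the cross-product odds ratio and
           exact p", {
  res <- teGeneEnrichment(rbind(c(33, 7), c(167, 293)))
  expect_equal(res$oddsRatio, (33 * 293) / (7 * 167), tolerance = 1e-12)
  expect_equal(res$p, fisherOracle(33, 7, 167, 293), tolerance = 1e-10)

  even <- teGeneEnrichment(rbind(c(10, 10), c(30, 30)))
  expect_equal(even$oddsRatio, 1)
  expect_equal(even$p, 1)

  degenerate <- teGeneEnrichment(rbind(c(5, 0), c(0, 5)))
  expect_equal(degenerate$oddsRatio, Inf)
  expect_equal(degenerate$p, fisherOracle(5, 0, 0, 5), tolerance = 1e-10)

  # GRanges interface: flagged transposons enriched among the associated
  tes <- GenomicRanges::GRanges("Chr1",
                                IRanges::IRanges(1:40 * 100, width = 50),
                                id = paste0("te", 1:40),
                                kind = "transposon",
                                has_te_gene = rep(c(TRUE, FALSE), c(10, 30)))
  assoc <- tes[c(1:8, 11)]
  res2 <- teGeneEnrichment(assoc, tes)
  expect_equal(res2$table, rbind(c(8, 1), c(2, 29)))
  expect_equal(res2$p, fisherOracle(8, 1, 2, 29), tolerance = 1e-10)
  expect_error(teGeneEnrichment(tes[0], tes), "empty")
})
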