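#' Read a Bismark-style cytosine report
#'
#' Parses a 7-column tab-separated per-cytosine table: chromosome, 1-based
#' position, strand, methylated read count, unmethylated read count, context
#' (CG/CHG/CHH) and trinucleotide. Strands are kept separate: the two
#' cytosines of a CG dyad are two independent records.
#'
#' @param path file path.
#' @param sampleName sample label attached to the returned table.
#' @return data.frame with columns chrom, pos, strand, meth, unmeth, context,
#'   trinucleotide and attribute \code{sample}; one row per input line.
#' @export
readCytosineReport <- function(path, sampleName) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- data.frame(chrom = character(), pos = integer(),
                    strand = character(), meth = integer(),
                    unmeth = integer(), context = character(),
                    trinucleotide = character(),
                    stringsAsFactors = FALSE)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 6))
      stop("malformed cytosine-report line ", which(nf < 6)[1], " in ", path,
           ": expected >= 6 tab-separated fields")
    m <- do.call(rbind, lapply(parts, function(p) p[1:7]))
    pos <- suppressWarnings(as.integer(m[, 2]))
    meth <- suppressWarnings(as.integer(m[, 4]))
    unmeth <- suppressWarnings(as.integer(m[, 5]))
    bad <- which(is.na(pos) | pos < 1 | is.na(meth) | meth < 0 |
                 is.na(unmeth) | unmeth < 0 | !(m[, 3] %in% c("+", "-")))
    if (length(bad))
      stop("malformed cytosine-report line ", bad[1], " in ", path)
    badctx <- which(!(m[, 6] %in% c("CG", "CHG", "CHH")))
    if (length(badctx))
      stop("unknown context '", m[badctx[1], 6], "' at line ", badctx[1],
           " in ", path)
    key <- paste(m[, 1], pos, m[, 3])
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      stop("duplicate (chrom,pos,strand) ", key[d], " at line ", d,
           " in ", path)
    }
    tri <- m[, 7]
    tri[is.na(tri)] <- ""
    out <- data.frame(chrom = m[, 1], pos = pos, strand = m[, 3],
                      meth = meth, unmeth = unmeth, context = m[, 6],
                      trinucleotide = tri, stringsAsFactors = FALSE)
  }
  attr(out, "sample") <- sampleName
  out
}

#' Write a cytosine report for one sample
#'
#' @param me a \linkS4class{MethylomeExperiment}
#' @param sample sample name
#' @param path output path
#' @export
writeCytosineReport <- function(me, sample, path) {
  rr <- SummarizedExperiment::rowRanges(me)
  tri <- S4Vectors::mcols(rr)$trinucleotide
  if (is.null(tri)) tri <- rep("", length(rr))
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    strand = as.character(GenomicRanges::strand(rr)),
                    meth = methCounts(me)[, sample],
                    unmeth = totalReads(me)[, sample] - methCounts(me)[, sample],
                    context = methContext(me), trinucleotide = tri)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a MethylomeExperiment from per-sample cytosine reports
#'
#' Sites are taken as the union over samples; a site absent from a sample
#' gets zero coverage there. Context disagreements across samples at the
#' same position are an error.
#'
#' @param paths named character vector, names are sample names.
#' @return a \linkS4class{MethylomeExperiment}
#' @export
readCytosineReports <- function(paths) {
  stopifnot(length(paths) > 0, !is.null(names(paths)))
  tabs <- lapply(names(paths), function(s) readCytosineReport(paths[[s]], s))
  names(tabs) <- names(paths)
  all <- do.call(rbind, tabs)
  key <- paste(all$chrom, all$pos, all$strand)
  ukey <- !duplicated(key)
  sites <- all[ukey, c("chrom", "pos", "strand", "context", "trinucleotide")]
  rownames(sites) <- key[ukey]
  if (anyDuplicated(paste(sites$chrom, sites$pos, sites$strand)) ||
      any(tapply(all$context, key, function(x) length(unique(x))) > 1))
    stop("conflicting context annotations across samples")
  n <- nrow(sites)
  meth <- cov <- matrix(0L, n, length(paths),
                        dimnames = list(rownames(sites), names(paths)))
  for (s in names(paths)) {
    t1 <- tabs[[s]]
    i <- match(paste(t1$chrom, t1$pos, t1$strand), rownames(sites))
    meth[i, s] <- t1$meth
    cov[i, s] <- t1$meth + t1$unmeth
  }
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1),
                               strand = sites$strand,
                               context = sites$context,
                               trinucleotide = sites$trinucleotide)
  MethylomeExperiment(meth, cov, gr, sampleNames = names(paths))
}

#' Read gene/transposon features from BED or GFF3
#'
#' BED input is interpreted as BED6+2 (0-based half-open): columns 7 and 8,
#' when present, give the feature kind (\code{gene}/\code{transposon}) and a
#' 0/1 te_gene flag. GFF3 input (1-based closed) takes the kind from the
#' type column (\code{gene} or any type containing \code{transposon} /
#' \code{transposable_element}) and the flag from a \code{te_gene}
#' attribute. All intervals are returned in the package's 1-based inclusive
#' convention.
#'
#' @param path file path.
#' @param dialect "BED" or "GFF3".
#' @return \code{GRanges} with mcols \code{id}, \code{kind},
#'   \code{has_te_gene}.
#' @export
readAnnotationFeatures <- function(path, dialect = c("BED", "GFF3")) {
  dialect <- match.arg(dialect)
  if (dialect == "BED") {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(kind = "character",
                                            te_gene = "integer"))
    mc <- S4Vectors::mcols(gr)
    id <- if ("name" %in% colnames(mc)) mc$name else
      paste0("feat", seq_along(gr))
    kind <- mc$kind
    flag <- !is.na(mc$te_gene) & mc$te_gene != 0
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    mc <- S4Vectors::mcols(gr)
    id <- if (!is.null(mc$ID)) mc$ID else paste0("feat", seq_along(gr))
    type <- as.character(mc$type)
    kind <- ifelse(grepl("transposon|transposable_element", type,
                         ignore.case = TRUE), "transposon",
                   ifelse(type == "gene", "gene", NA_character_))
    flag <- if (!is.null(mc$te_gene)) !is.na(mc$te_gene) & mc$te_gene %in%
      c("1", "true", "TRUE", 1) else rep(FALSE, length(gr))
  }
  if (any(is.na(kind)))
    stop("unknown feature kind at record ", which(is.na(kind))[1])
  if (!all(kind %in% c("gene", "transposon")))
    stop("unknown feature kind '", setdiff(kind, c("gene", "transposon"))[1],
         "'")
  if (length(gr) && any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
    stop("interval with end < start after conversion")
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    id = id, kind = kind, has_te_gene = flag & kind == "transposon")
  out
}

#' Write gene/transposon features as BED6+2
#'
#' Inverse of \code{readAnnotationFeatures(dialect = "BED")}.
#' @param features \code{GRanges} with mcols id, kind, has_te_gene
#' @param path output path
#' @export
writeAnnotationBed <- function(features, path) {
  strand <- as.character(GenomicRanges::strand(features))
  strand[strand == "*"] <- "."
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(features)),
                    start = GenomicRanges::start(features) - 1L,
                    end = GenomicRanges::end(features),
                    name = S4Vectors::mcols(features)$id,
                    score = 0L, strand = strand,
                    kind = S4Vectors::mcols(features)$kind,
                    te_gene = as.integer(S4Vectors::mcols(features)$has_te_gene))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes TSV (name, length)
#' @param path file path
#' @return named integer vector
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}

#' Read a two-column centromere-positions TSV (name, position)
#' @param path file path
#' @return named numeric vector
#' @export
readCentromeres <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Flag transposons containing a TE gene by interval overlap
#'
#' Fallback when the annotation input does not carry an explicit te_gene
#' flag: a transposon is flagged when it overlaps at least one interval of
#' the supplied TE-gene list.
#'
#' @param features annotation \code{GRanges} (mcols kind, has_te_gene)
#' @param teGenes \code{GRanges} of transposable-element gene intervals
#' @return \code{features} with \code{has_te_gene} updated
#' @export
flagTEGenesByOverlap <- function(features, teGenes) {
  hits <- GenomicRanges::countOverlaps(features, teGenes,
                                       ignore.strand = TRUE) > 0
  S4Vectors::mcols(features)$has_te_gene <-
    hits & S4Vectors::mcols(features)$kind == "transposon"
  features
}

#' Write result tables as headered TSVs
#'
#' Serializes each table with \code{write.table}; floating-point columns
#' keep full precision (\code{>= 6} significant digits) so a round-trip
#' read returns identical values.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory (created if missing).
#' @return invisible character vector of written paths.
#' @export
writeResultTables <- function(tables, outDir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory ", outDir)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(outDir, paste0(nm, ".tsv"))
    tab <- tables[[nm]]
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read back a result table written by \code{writeResultTables}
#' @param path TSV path
#' @return data.frame
#' @export
readResultTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA)
}
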