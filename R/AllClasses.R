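#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand granges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- keepSeqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData rowRanges<- colData<-
NULL

#' MethylomeExperiment: per-cytosine methylation counts across samples
#'
#' A \linkS4class{RangedSummarizedExperiment} holding two integer assays,
#' \code{meth} (methylated read counts) and \code{cov} (total read counts),
#' over single-cytosine positions. Row ranges are width-1 \code{GRanges}
#' carrying a \code{context} metadata column (\code{CG}, \code{CHG} or
#' \code{CHH}) and optionally a \code{trinucleotide} column. The two strands
#' of a CG dyad are kept as independent rows; they are never merged.
#'
#' Validity requires \code{meth <= cov} elementwise, non-negative counts,
#' a valid context for every site, and unique (chrom, pos, strand) keys.
#'
#' @export
setClass("MethylomeExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("MethylomeExperiment", function(object) {
  msg <- character()
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("meth", "cov") %in% an))
    return("assays must include 'meth' and 'cov'")
  meth <- SummarizedExperiment::assay(object, "meth")
  cov <- SummarizedExperiment::assay(object, "cov")
  if (any(meth < 0) || any(cov < 0))
    msg <- c(msg, "counts must be non-negative")
  if (any(meth > cov))
    msg <- c(msg, "meth must not exceed cov")
  rr <- SummarizedExperiment::rowRanges(object)
  ctx <- S4Vectors::mcols(rr)$context
  if (is.null(ctx))
    msg <- c(msg, "rowRanges must carry a 'context' metadata column")
  else if (!all(ctx %in% c("CG", "CHG", "CHH")))
    msg <- c(msg, "context must be one of CG, CHG, CHH")
  if (length(rr) && any(GenomicRanges::width(rr) != 1L))
    msg <- c(msg, "all sites must have width 1")
  key <- paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr),
               GenomicRanges::strand(rr))
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (chrom, pos, strand) site keys")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylomeExperiment
#'
#' @param meth integer matrix of methylated read counts (sites x samples).
#' @param cov integer matrix of total read counts, same shape as \code{meth}.
#' @param sites width-1 \code{GRanges} with a \code{context} metadata column.
#' @param sampleNames optional character vector; defaults to
#'   \code{colnames(meth)}.
#' @return a \linkS4class{MethylomeExperiment}, rows sorted by
#'   (chrom, pos, strand).
#' @examples
#' gr <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(c(10, 25), width = 1),
#'                              strand = "+", context = c("CG", "CHH"))
#' me <- MethylomeExperiment(meth = cbind(a = c(3L, 0L), b = c(1L, 2L)),
#'                           cov = cbind(a = c(10L, 5L), b = c(8L, 6L)),
#'                           sites = gr)
#' methLevels(me)
#' @export
MethylomeExperiment <- function(meth, cov, sites, sampleNames = colnames(meth)) {
  meth <- as.matrix(meth); cov <- as.matrix(cov)
  storage.mode(meth) <- "integer"; storage.mode(cov) <- "integer"
  if (is.null(sampleNames))
    sampleNames <- paste0("sample", seq_len(ncol(meth)))
  colnames(meth) <- colnames(cov) <- sampleNames
  o <- order(as.factor(GenomicRanges::seqnames(sites)),
             GenomicRanges::start(sites),
             as.factor(GenomicRanges::strand(sites)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth[o, , drop = FALSE], cov = cov[o, , drop = FALSE]),
    rowRanges = sites[o],
    colData = S4Vectors::DataFrame(sample = sampleNames, row.names = sampleNames))
  new("MethylomeExperiment", se)
}

#' @describeIn MethylomeExperiment methylated read counts (sites x samples)
#' @param x a \code{MethylomeExperiment}
#' @export
methCounts <- function(x) SummarizedExperiment::assay(x, "meth")

#' @describeIn MethylomeExperiment total read counts (sites x samples)
#' @export
totalReads <- function(x) SummarizedExperiment::assay(x, "cov")

#' @describeIn MethylomeExperiment context (CG/CHG/CHH) per site
#' @export
methContext <- function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$context

#' @describeIn MethylomeExperiment methylation proportions meth/cov
#'   (\code{NaN} where coverage is zero)
#' @export
methLevels <- function(x) methCounts(x) / totalReads(x)

setMethod("show", "MethylomeExperiment", function(object) {
  ctx <- table(methContext(object))
  cat("MethylomeExperiment with", nrow(object), "cytosine sites x",
      ncol(object), "samples\n")
  cat("  contexts:", paste(names(ctx), as.integer(ctx), sep = "=",
                           collapse = ", "), "\n")
  cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
})

#' GenomeAnnotation: chromosome geometry and gene/transposon intervals
#'
#' Holds named chromosome sizes, centromere positions, and a \code{GRanges}
#' of features with metadata columns \code{id}, \code{kind} (\code{gene} or
#' \code{transposon}) and \code{has_te_gene} (transposons containing a
#' transposable-element gene). Coordinates are 1-based inclusive.
#'
#' @slot chromSizes named integer vector of chromosome lengths (bp).
#' @slot centromeres named numeric vector of centromere positions (bp).
#' @slot features \code{GRanges} with mcols \code{id}, \code{kind},
#'   \code{has_te_gene}.
#' @export
setClass("GenomeAnnotation",
         representation(chromSizes = "integer",
                        centromeres = "numeric",
                        features = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  cs <- object@chromSizes
  if (is.null(names(cs)) || anyDuplicated(names(cs)))
    msg <- c(msg, "chromSizes must be uniquely named")
  if (any(cs <= 0)) msg <- c(msg, "chromosome sizes must be positive")
  cm <- object@centromeres
  if (length(cm)) {
    bad <- !(names(cm) %in% names(cs)) | cm < 1 | cm > cs[names(cm)]
    if (any(bad)) msg <- c(msg, "centromere outside chromosome bounds")
  }
  ft <- object@features
  if (length(ft)) {
    need <- c("id", "kind", "has_te_gene")
    if (!all(need %in% colnames(S4Vectors::mcols(ft))))
      return("features must carry mcols id, kind, has_te_gene")
    if (!all(S4Vectors::mcols(ft)$kind %in% c("gene", "transposon")))
      msg <- c(msg, "feature kind must be gene or transposon")
    if (any(S4Vectors::mcols(ft)$has_te_gene &
            S4Vectors::mcols(ft)$kind == "gene"))
      msg <- c(msg, "has_te_gene must be FALSE for genes")
    chr <- as.character(GenomicRanges::seqnames(ft))
    if (!all(chr %in% names(cs)))
      msg <- c(msg, "feature on unknown chromosome")
    else if (any(GenomicRanges::start(ft) < 1 |
                 GenomicRanges::end(ft) > cs[chr]))
      msg <- c(msg, "feature outside chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param chromSizes named integer vector (chromosome -> length in bp).
#' @param centromeres named numeric vector (chromosome -> position in bp);
#'   may be empty.
#' @param features \code{GRanges} with mcols \code{id}, \code{kind},
#'   \code{has_te_gene}.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(chromSizes, centromeres = numeric(),
                             features = GenomicRanges::GRanges()) {
  sizes <- stats::setNames(as.integer(chromSizes), names(chromSizes))
  if (length(features) &&
      is.null(S4Vectors::mcols(features)$has_te_gene))
    S4Vectors::mcols(features)$has_te_gene <- FALSE
  new("GenomeAnnotation", chromSizes = sizes,
      centromeres = centromeres, features = features)
}

#' @describeIn GenomeAnnotation named chromosome lengths
#' @param x a \code{GenomeAnnotation}
#' @export
chromSizes <- function(x) x@chromSizes

#' @describeIn GenomeAnnotation named centromere positions
#' @export
centromeres <- function(x) x@centromeres

#' @describeIn GenomeAnnotation feature intervals as \code{GRanges}
#' @export
annotationFeatures <- function(x) x@features

setMethod("show", "GenomeAnnotation", function(object) {
  kinds <- table(S4Vectors::mcols(object@features)$kind)
  cat("GenomeAnnotation:", length(object@chromSizes), "chromosomes,",
      length(object@features), "features\n")
  if (length(kinds))
    cat("  ", paste(names(kinds), as.integer(kinds), sep = "=",
                    collapse = ", "),
        " (te_gene transposons: ",
        sum(S4Vectors::mcols(object@features)$has_te_gene), ")\n", sep = "")
})
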