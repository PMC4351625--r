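## strand-oriented signed offsets of positions to feature start/end:
## negative = upstream of the feature's 5' boundary; unstranded features
## are treated as '+'
.strandOffsets <- function(pos, fstart, fend, fstrand) {
  minus <- fstrand == "-"
  offStart <- ifelse(minus, fend - pos, pos - fstart)
  offEnd <- ifelse(minus, fstart - pos, pos - fend)
  list(start = offStart, end = offEnd)
}

## effective kind: transposons with a TE gene report as te_gene
.effectiveKind <- function(features) {
  k <- S4Vectors::mcols(features)$kind
  ifelse(S4Vectors::mcols(features)$has_te_gene & k == "transposon",
         "te_gene", k)
}

#' Assign DMPs to genomic features
#'
#' Each position is labelled with the feature containing it; containment
#' ties are resolved by kind priority (te_gene > transposon > gene) and
#' then by the smallest containing interval. Positions contained in no
#' feature are assigned their nearest feature with kind \code{other} and a
#' signed distance. Offsets to the feature start and end are
#' strand-oriented: negative offsets lie upstream of the feature's 5'
#' boundary; unstranded features are treated as plus-strand.
#'
#' @param dmps data.frame with columns chrom, pos (e.g. from
#'   \code{\link{callDMPs}})
#' @param annotation a \linkS4class{GenomeAnnotation}, or a feature
#'   \code{GRanges}
#' @return the input with columns feature_id, feature_kind (gene,
#'   transposon, te_gene or other), contained, offset_start, offset_end
#'   appended; positions on chromosomes absent from the annotation get NA
#'   with a warning
#' @export
assignFeatures <- function(dmps, annotation) {
  features <- if (is(annotation, "GenomeAnnotation"))
    annotationFeatures(annotation) else annotation
  if (!length(features)) stop("empty annotation")
  pts <- GenomicRanges::GRanges(dmps$chrom,
                                IRanges::IRanges(dmps$pos, width = 1))
  n <- nrow(dmps)
  out <- dmps
  out$feature_id <- NA_character_
  out$feature_kind <- NA_character_
  out$contained <- FALSE
  out$offset_start <- NA_real_
  out$offset_end <- NA_real_

  known <- as.character(GenomicRanges::seqnames(pts)) %in%
    unique(as.character(GenomicRanges::seqnames(features)))
  if (any(!known))
    warning(sum(!known), " position(s) on chromosomes absent from the ",
            "annotation left unassigned")

  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pts, features, ignore.strand = TRUE))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    prio <- c(te_gene = 1L, transposon = 2L, gene = 3L)
    ek <- .effectiveKind(features)
    o <- order(qh, prio[ek[sh]], GenomicRanges::width(features)[sh])
    keep <- !duplicated(qh[o])
    qh <- qh[o][keep]; sh <- sh[o][keep]
    f <- features[sh]
    off <- .strandOffsets(dmps$pos[qh], GenomicRanges::start(f),
                          GenomicRanges::end(f),
                          as.character(GenomicRanges::strand(f)))
    out$feature_id[qh] <- S4Vectors::mcols(f)$id
    out$feature_kind[qh] <- ek[sh]
    out$contained[qh] <- TRUE
    out$offset_start[qh] <- off$start
    out$offset_end[qh] <- off$end
  }
  rest <- which(!out$contained & known)
  if (length(rest)) {
    nh <- suppressWarnings(
      GenomicRanges::distanceToNearest(pts[rest], features,
                                       ignore.strand = TRUE))
    qh <- rest[S4Vectors::queryHits(nh)]
    f <- features[S4Vectors::subjectHits(nh)]
    off <- .strandOffsets(dmps$pos[qh], GenomicRanges::start(f),
                          GenomicRanges::end(f),
                          as.character(GenomicRanges::strand(f)))
    out$feature_id[qh] <- S4Vectors::mcols(f)$id
    out$feature_kind[qh] <- "other"
    out$offset_start[qh] <- off$start
    out$offset_end[qh] <- off$end
  }
  out
}

## offsets of positions to their nearest feature within one kind subset
.nearestKindOffsets <- function(dmps, features) {
  pts <- GenomicRanges::GRanges(dmps$chrom,
                                IRanges::IRanges(dmps$pos, width = 1))
  known <- as.character(GenomicRanges::seqnames(pts)) %in%
    unique(as.character(GenomicRanges::seqnames(features)))
  offStart <- offEnd <- rep(NA_real_, nrow(dmps))
  fid <- rep(NA_character_, nrow(dmps))
  idx <- which(known)
  if (length(idx)) {
    nh <- suppressWarnings(
      GenomicRanges::distanceToNearest(pts[idx], features,
                                       ignore.strand = TRUE))
    qh <- idx[S4Vectors::queryHits(nh)]
    f <- features[S4Vectors::subjectHits(nh)]
    off <- .strandOffsets(dmps$pos[qh], GenomicRanges::start(f),
                          GenomicRanges::end(f),
                          as.character(GenomicRanges::strand(f)))
    offStart[qh] <- off$start; offEnd[qh] <- off$end
    fid[qh] <- S4Vectors::mcols(f)$id
  }
  data.frame(feature_id = fid, offset_start = offStart,
             offset_end = offEnd, stringsAsFactors = FALSE)
}

#' Boundary-bin DMP metaprofiles with length normalization and max scaling
#'
#' For each sample, context, feature kind and anchor (feature start or
#' end), DMP offsets to the nearest feature of that kind are counted in
#' non-overlapping bins of \code{bin} bp spanning [-span, +span). Offsets
#' are strand-oriented. Raw bin counts are then length-adjusted: a bin
#' whose offsets lie in the feature interior can only be hosted by
#' features at least L bp long (L = the bin's far offset from the
#' anchor), so its count is divided by the proportion of features of that
#' kind with length >= L; exterior bins use proportion 1. Finally all
#' length-adjusted values are divided by the maximum over the scaling
#' group (all samples and contexts, and across feature kinds when
#' \code{scaleAcrossKinds}).
#'
#' @param dmpTables named list of DMP data.frames (one per sample/
#'   comparison), or a single data.frame; only rows with status "DMP"
#'   are profiled
#' @param annotation \linkS4class{GenomeAnnotation}
#' @param kinds feature kinds to profile (subset of gene, transposon,
#'   te_gene); te_gene selects flagged transposons
#' @param bin bin width (bp); must divide \code{span}
#' @param span half-window (bp) around each anchor
#' @param scaleAcrossKinds share the scaling maximum across feature kinds
#' @param denominator length-adjustment denominator: proportion of all
#'   annotated features of the kind (\code{all_features}) or of only the
#'   features bearing at least one profiled DMP (\code{dmp_features})
#' @return data.frame: sample, context, feature_kind, anchor, bin (0-based
#'   index), offset_lo, offset_hi, raw, adjusted, scaled
#' @export
boundaryProfiles <- function(dmpTables, annotation,
                             kinds = c("gene", "transposon"),
                             bin = 100, span = 2000,
                             scaleAcrossKinds = TRUE,
                             denominator = c("all_features",
                                             "dmp_features")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(dmpTables)) dmpTables <- list(sample1 = dmpTables)
  stopifnot(span %% bin == 0, bin > 0)
  nbin <- 2L * span / bin
  features <- annotationFeatures(annotation)
  ek <- .effectiveKind(features)
  rows <- list()
  for (kind in kinds) {
    fk <- switch(kind,
                 gene = features[ek == "gene"],
                 transposon = features[S4Vectors::mcols(features)$kind ==
                                       "transposon"],
                 te_gene = features[ek == "te_gene"],
                 stop("unknown feature kind ", kind))
    if (!length(fk)) stop("zero mapped features of kind ", kind)
    for (s in names(dmpTables)) {
      tab <- dmpTables[[s]]
      tab <- tab[tab$status == "DMP", , drop = FALSE]
      offs <- .nearestKindOffsets(tab, fk)
      for (ctx in c("CG", "CHG", "CHH")) {
        inCtx <- tab$context == ctx
        flen <- GenomicRanges::width(fk)
        if (denominator == "dmp_features") {
          used <- unique(offs$feature_id[inCtx])
          lenSet <- flen[S4Vectors::mcols(fk)$id %in% used]
          if (!length(lenSet)) lenSet <- flen
        } else lenSet <- flen
        for (anchor in c("start", "end")) {
          o <- if (anchor == "start") offs$offset_start[inCtx]
               else offs$offset_end[inCtx]
          o <- o[!is.na(o) & o >= -span & o < span]
          b <- floor((o + span) / bin)
          raw <- tabulate(b + 1L, nbins = nbin)
          lo <- (seq_len(nbin) - 1L) * bin - span
          hi <- lo + bin
          # interior bins: beyond the start (offsets >= 0) for the start
          # anchor; before the end (offsets <= 0) for the end anchor
          Lreq <- rep(0, nbin)
          if (anchor == "start") Lreq[lo >= 0] <- hi[lo >= 0]
          else Lreq[hi <= 0] <- -lo[hi <= 0]
          prop <- vapply(Lreq, function(L)
            if (L <= 0) 1 else mean(lenSet >= L), numeric(1))
          adjusted <- ifelse(prop > 0, raw / prop,
                             ifelse(raw > 0, NA_real_, 0))
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, context = ctx, feature_kind = kind,
            anchor = anchor, bin = seq_len(nbin) - 1L,
            offset_lo = lo, offset_hi = hi, raw = raw,
            adjusted = adjusted, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (scaleAcrossKinds) {
    mx <- max(out$adjusted, na.rm = TRUE)
    out$scaled <- if (mx > 0) out$adjusted / mx else 0
  } else {
    out$scaled <- NA_real_
    for (kind in unique(out$feature_kind)) {
      i <- out$feature_kind == kind
      mx <- max(out$adjusted[i], na.rm = TRUE)
      out$scaled[i] <- if (mx > 0) out$adjusted[i] / mx else 0
    }
  }
  out
}

#' Chromosomal DMP/NDMP density tracks
#'
#' Counts DMPs and NDMPs in non-overlapping windows per chromosome and
#' normalizes each count by the genome-wide maximum window count within
#' the comparison, so all chromosomes share one scale.
#'
#' @param dmps DMP data.frame (from \code{\link{callDMPs}})
#' @param chromSizes named chromosome lengths
#' @param window window width in bp
#' @return data.frame: chrom, start, end, n_dmp, n_ndmp, dmp_scaled,
#'   ndmp_scaled
#' @export
chromosomeDensity <- function(dmps, chromSizes, window = 1e5) {
  stopifnot(window > 0)
  rows <- lapply(names(chromSizes), function(chr) {
    L <- chromSizes[[chr]]
    starts <- seq(1, L, by = window)
    ends <- pmin(starts + window - 1, L)
    sel <- dmps$chrom == chr
    w <- function(status) {
      pos <- dmps$pos[sel & dmps$status == status]
      tabulate(pmin(floor((pos - 1) / window) + 1L, length(starts)),
               nbins = length(starts))
    }
    data.frame(chrom = chr, start = starts, end = ends,
               n_dmp = w("DMP"), n_ndmp = w("NDMP"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mxD <- max(out$n_dmp); mxN <- max(out$n_ndmp)
  out$dmp_scaled <- if (mxD > 0) out$n_dmp / mxD else 0
  out$ndmp_scaled <- if (mxN > 0) out$n_ndmp / mxN else 0
  out
}

#' Transposons overlapping called DMRs
#'
#' @param dmrs data.frame with chrom, start, end (e.g. significant rows
#'   from \code{\link{callGroupDMRs}})
#' @param annotation \linkS4class{GenomeAnnotation}
#' @return \code{GRanges} of the annotation's transposons that overlap at
#'   least one DMR
#' @export
dmrAssociatedTransposons <- function(dmrs, annotation) {
  features <- annotationFeatures(annotation)
  tes <- features[S4Vectors::mcols(features)$kind == "transposon"]
  if (!nrow(dmrs)) return(tes[0])
  rg <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  tes[GenomicRanges::countOverlaps(tes, rg, ignore.strand = TRUE) > 0]
}

#' TE-gene enrichment among DMR-associated transposons
#'
#' Tests whether transposons associated with DMRs contain TE genes more
#' often than the remaining annotated transposons, with a two-sided Fisher
#' exact test on the 2x2 table (DMR-associated vs not) x (has TE gene vs
#' not). The odds ratio is the cross-product ad/bc (infinite when bc = 0).
#'
#' @param dmrTes \code{GRanges} of DMR-associated transposons (subset of
#'   \code{allTes} by id), or a 2x2 count matrix
#'   \code{rbind(c(a, b), c(c, d))}
#' @param allTes \code{GRanges} of all annotated transposons with
#'   \code{has_te_gene}; ignored when \code{dmrTes} is a matrix
#' @return list with \code{oddsRatio}, \code{p} and the 2x2 \code{table}
#' @export
teGeneEnrichment <- function(dmrTes, allTes = NULL) {
  if (is.matrix(dmrTes)) {
    tab <- dmrTes
  } else {
    if (!length(dmrTes) || is.null(allTes) || !length(allTes))
      stop("empty transposon sets")
    ids <- S4Vectors::mcols(allTes)$id
    assoc <- ids %in% S4Vectors::mcols(dmrTes)$id
    teg <- S4Vectors::mcols(allTes)$has_te_gene
    tab <- rbind(c(sum(assoc & teg), sum(assoc & !teg)),
                 c(sum(!assoc & teg), sum(!assoc & !teg)))
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (sum(tab) == 0) stop("empty transposon sets")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(oddsRatio = or, p = fisherExact2x2(a, b, c, d),
       table = tab)
}
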