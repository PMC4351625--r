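#' Cluster well-covered cytosine sites into candidate regions
#'
#' Within one context, a site qualifies when its coverage reaches
#' \code{minCoverage} in at least \code{minFractionSamples} of the
#' samples. Maximal runs of qualifying sites in which consecutive sites
#' lie at most \code{maxGap} bp apart, with at least \code{minSites}
#' sites, become candidate regions. Regions never span chromosomes.
#'
#' @param me a \linkS4class{MethylomeExperiment}
#' @param context CG, CHG or CHH
#' @param minCoverage per-sample coverage floor
#' @param minFractionSamples fraction of samples that must reach the floor
#' @param maxGap maximum spacing (bp) between consecutive member sites
#' @param minSites minimum number of member sites
#' @return data.frame: chrom, start, end, n_sites, plus a list-column
#'   \code{site_idx} of row indices into \code{me}
#' @export
clusterSites <- function(me, context, minCoverage = 4L,
                         minFractionSamples = 0.75, maxGap = 100L,
                         minSites = 5L) {
  stopifnot(minCoverage > 0, maxGap > 0, minSites > 0,
            minFractionSamples > 0, minFractionSamples <= 1)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer())
  empty$site_idx <- list()
  if (!nrow(me)) return(empty)
  rr <- SummarizedExperiment::rowRanges(me)
  qual <- which(methContext(me) == context &
                rowMeans(totalReads(me) >= minCoverage) >=
                  minFractionSamples)
  if (!length(qual)) return(empty)
  chr <- as.character(GenomicRanges::seqnames(rr))[qual]
  pos <- GenomicRanges::start(rr)[qual]
  o <- order(chr, pos)
  qual <- qual[o]; chr <- chr[o]; pos <- pos[o]
  newRun <- c(TRUE, chr[-1] != chr[-length(chr)] |
                    diff(pos) > maxGap)
  runId <- cumsum(newRun)
  keepRuns <- which(tabulate(runId) >= minSites)
  if (!length(keepRuns)) return(empty)
  rows <- lapply(keepRuns, function(rid) {
    i <- which(runId == rid)
    data.frame(chrom = chr[i[1]], start = pos[i[1]],
               end = pos[i[length(i)]], n_sites = length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$site_idx <- lapply(keepRuns, function(rid) qual[runId == rid])
  out
}

#' Call group-wise differentially methylated regions
#'
#' A transparent region caller: candidate regions come from
#' \code{\link{clusterSites}}; for each candidate, per-sample region
#' levels are pooled proportions (sum of methylated over sum of total
#' reads across member sites), group means average the member samples'
#' levels, and the test is a two-sided Fisher exact test on the two
#' groups' pooled (methylated, unmethylated) totals. p-values are
#' adjusted by the Benjamini-Hochberg step-up rule across candidates, and
#' a region is significant when q < \code{fdr} AND the absolute group
#' mean difference reaches \code{minDiff} AND the per-sample levels are
#' consistently shifted between the groups (Welch t-test on sample
#' levels, p < \code{consistencyP}). All candidates are returned with a
#' status flag.
#'
#' Two guard gates exist because the pooled exact test treats reads as
#' the replication unit and ignores between-site heterogeneity: a region
#' whose member sites mix very different baseline levels (for example one
#' straddling a transposon boundary) can show a group difference in its
#' coverage-weighted pooled level purely through read-depth fluctuations.
#' The replicate gate (Welch t-test on per-sample levels, skipped when a
#' group has fewer than two samples) requires the shift to reproduce
#' across samples; the stratified gate (Cochran-Mantel-Haenszel test with
#' one stratum per cytosine site, p < \code{stratifiedP}) conditions the
#' between-site baseline differences away entirely, so pooled-level
#' artifacts that vanish within sites are rejected.
#'
#' @param me a \linkS4class{MethylomeExperiment}
#' @param groups named character vector or data.frame(sample, group)
#'   mapping samples to exactly two groups
#' @param context CG or CHG (CHH available but not a default analysis)
#' @param fdr q-value threshold
#' @param minDiff minimum absolute group mean methylation difference
#' @param consistencyP replicate-consistency threshold (Welch t-test on
#'   per-sample levels); \code{NA} disables the gate
#' @param stratifiedP site-stratified CMH threshold; \code{NA} disables
#'   the gate
#' @param minCoverage,minFractionSamples,maxGap,minSites candidate-region
#'   parameters, see \code{\link{clusterSites}}
#' @return data.frame: chrom, start, end, context, n_sites, one
#'   \code{level_<sample>} column per sample, mean_a, mean_b, mean_diff,
#'   p, p_consistency, p_stratified, q, status (significant/ns)
#' @export
callGroupDMRs <- function(me, groups, context = "CG", fdr = 0.05,
                          minDiff = 0.1, consistencyP = 0.05,
                          stratifiedP = 0.05, minCoverage = 4L,
                          minFractionSamples = 0.75, maxGap = 100L,
                          minSites = 5L) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  gnames <- unique(groups)
  if (length(gnames) != 2)
    stop("callGroupDMRs requires exactly two groups, got ",
         length(gnames))
  if (!all(names(groups) %in% colnames(me)))
    stop("unknown sample in group map")
  cand <- clusterSites(me, context, minCoverage, minFractionSamples,
                       maxGap, minSites)
  samples <- names(groups)
  lvlCols <- paste0("level_", samples)
  base <- data.frame(chrom = character(), start = integer(),
                     end = integer(), context = character(),
                     n_sites = integer())
  for (cn in lvlCols) base[[cn]] <- numeric()
  base$mean_a <- base$mean_b <- base$mean_diff <- numeric()
  base$p <- base$p_consistency <- base$p_stratified <- base$q <- numeric()
  base$status <- character()
  if (!nrow(cand)) return(base)
  meth <- methCounts(me); cov <- totalReads(me)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    idx <- cand$site_idx[[i]]
    sm <- colSums(meth[idx, samples, drop = FALSE])
    sc <- colSums(cov[idx, samples, drop = FALSE])
    gZero <- vapply(gnames, function(g)
      sum(sc[samples[groups == g]]) == 0, logical(1))
    if (any(gZero)) {
      warning("region ", cand$chrom[i], ":", cand$start[i], "-",
              cand$end[i], " skipped: zero aggregate coverage in group ",
              gnames[gZero][1])
      next
    }
    lvl <- ifelse(sc > 0, sm / sc, NA_real_)
    gm <- vapply(gnames, function(g)
      mean(lvl[samples[groups == g]], na.rm = TRUE), numeric(1))
    pm <- vapply(gnames, function(g)
      sum(sm[samples[groups == g]]), numeric(1))
    pc <- vapply(gnames, function(g)
      sum(sc[samples[groups == g]]), numeric(1))
    p <- fisherExact2x2(pm[1], pc[1] - pm[1], pm[2], pc[2] - pm[2])
    row <- data.frame(chrom = cand$chrom[i], start = cand$start[i],
                      end = cand$end[i], context = context,
                      n_sites = cand$n_sites[i],
                      stringsAsFactors = FALSE)
    for (j in seq_along(samples)) row[[lvlCols[j]]] <- lvl[j]
    row$mean_a <- gm[1]; row$mean_b <- gm[2]
    row$mean_diff <- gm[1] - gm[2]
    row$p <- p
    lvlA <- lvl[samples[groups == gnames[1]]]
    lvlB <- lvl[samples[groups == gnames[2]]]
    row$p_consistency <- if (is.na(consistencyP) ||
                             sum(!is.na(lvlA)) < 2 ||
                             sum(!is.na(lvlB)) < 2) NA_real_
    else tryCatch(stats::t.test(lvlA, lvlB)$p.value,
                  error = function(e)  # zero within-group variance
                    if (isTRUE(all.equal(mean(lvlA, na.rm = TRUE),
                                         mean(lvlB, na.rm = TRUE)))) 1
                    else 0)
    row$p_stratified <- if (is.na(stratifiedP)) NA_real_ else {
      sA <- samples[groups == gnames[1]]; sB <- samples[groups == gnames[2]]
      strata <- lapply(idx, function(i) {
        mA <- sum(meth[i, sA]); cA <- sum(cov[i, sA])
        mB <- sum(meth[i, sB]); cB <- sum(cov[i, sB])
        rbind(c(mA, cA - mA), c(mB, cB - mB))
      })
      strata <- strata[vapply(strata, sum, numeric(1)) > 0]
      arr <- array(as.numeric(unlist(strata)), c(2, 2, length(strata)))
      tryCatch(stats::mantelhaen.test(arr)$p.value,
               error = function(e) NA_real_)
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(base)
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  consOk <- is.na(out$p_consistency) | out$p_consistency < consistencyP
  stratOk <- is.na(out$p_stratified) | out$p_stratified < stratifiedP
  out$status <- ifelse(out$q < fdr & abs(out$mean_diff) >= minDiff &
                         consOk & stratOk,
                       "significant", "ns")
  attr(out, "groups") <- gnames
  out
}

#' Fixed-width tiling-window methylation levels
#'
#' Partitions every chromosome into consecutive windows of \code{window}
#' bp starting at position 1. A site counts as covered in a window when
#' its coverage reaches \code{minCoverage} in every sample; windows with
#' at least \code{minSites} covered sites report per-sample pooled levels
#' (sum meth / sum cov over the covered sites), others are dropped.
#'
#' @param me a \linkS4class{MethylomeExperiment}
#' @param window window width in bp (default 340)
#' @param minSites minimum covered sites per retained window (default 20)
#' @param minCoverage per-sample coverage floor defining "covered"
#'   (default 1)
#' @param contexts contexts pooled into the window levels
#' @return data.frame: chrom, start, end, n_covered_sites, one
#'   \code{level_<sample>} column per sample
#' @export
tilingMethylation <- function(me, window = 340L, minSites = 20L,
                              minCoverage = 1L,
                              contexts = c("CG", "CHG", "CHH")) {
  stopifnot(window > 0, minSites > 0, minCoverage >= 0)
  rr <- SummarizedExperiment::rowRanges(me)
  meth <- methCounts(me); cov <- totalReads(me)
  samples <- colnames(me)
  keep <- methContext(me) %in% contexts &
    rowSums(cov >= minCoverage) == length(samples)
  chr <- as.character(GenomicRanges::seqnames(rr))
  win <- floor((GenomicRanges::start(rr) - 1) / window)
  keyAll <- paste0(chr, ":", win)
  rows <- list()
  for (key in unique(keyAll[keep])) {
    idx <- which(keyAll == key & keep)
    if (length(idx) < minSites) next
    sm <- colSums(meth[idx, , drop = FALSE])
    sc <- colSums(cov[idx, , drop = FALSE])
    w <- win[idx[1]]
    row <- data.frame(chrom = chr[idx[1]],
                      start = w * window + 1L,
                      end = (w + 1L) * window,
                      n_covered_sites = length(idx),
                      stringsAsFactors = FALSE)
    for (j in seq_along(samples))
      row[[paste0("level_", samples[j])]] <-
        if (sc[j] > 0) sm[j] / sc[j] else NA_real_
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    base <- data.frame(chrom = character(), start = integer(),
                       end = integer(), n_covered_sites = integer())
    for (s in samples) base[[paste0("level_", s)]] <- numeric()
    return(base)
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}
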