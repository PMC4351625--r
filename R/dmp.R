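#' Coverage eligibility mask for pairwise DMP testing
#'
#' A cytosine is eligible when it is covered by at least four reads in each
#' of the two samples and by at least two methylated reads in at least one
#' of them.
#'
#' @param me a \linkS4class{MethylomeExperiment}
#' @param sampleA,sampleB sample names
#' @param minCoverage per-sample coverage floor (default 4)
#' @param minMethylated methylated-read floor required in at least one
#'   sample (default 2)
#' @return logical vector over sites
#' @export
eligibleSites <- function(me, sampleA, sampleB, minCoverage = 4L,
                          minMethylated = 2L) {
  if (!all(c(sampleA, sampleB) %in% colnames(me)))
    stop("unknown sample name: ",
         paste(setdiff(c(sampleA, sampleB), colnames(me)), collapse = ", "))
  cov <- totalReads(me); meth <- methCounts(me)
  cov[, sampleA] >= minCoverage & cov[, sampleB] >= minCoverage &
    (meth[, sampleA] >= minMethylated | meth[, sampleB] >= minMethylated)
}

#' Two-sided Fisher's exact test for 2x2 count tables, vectorized
#'
#' For each table \code{(a, b; c, d)} with fixed margins, the two-sided
#' p-value is the sum of hypergeometric point probabilities of all tables
#' whose point probability does not exceed that of the observed table
#' (within relative tolerance 1e-7, the conventional definition).
#'
#' @param a,b,c,d non-negative integer vectors: methylated/unmethylated
#'   counts in sample 1 (\code{a}, \code{b}) and sample 2 (\code{c},
#'   \code{d}).
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' fisherExact2x2(10, 0, 0, 10)   # 2 / choose(20, 10)
#' fisherExact2x2(3, 1, 1, 3)     # 34/70
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative count")
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  m1 <- a + b   # row-1 margin (white balls)
  m2 <- c + d   # row-2 margin (black balls)
  k <- a + c    # column-1 margin (drawn)
  if (any(m1 + m2 == 0)) stop("table with all-zero margins")
  lo <- pmax(0, k - m2); hi <- pmin(k, m1)
  len <- hi - lo + 1
  idx <- rep.int(seq_len(n), len)
  x <- sequence(len) - 1 + lo[idx]
  logp <- stats::dhyper(x, m1[idx], m2[idx], k[idx], log = TRUE)
  logObs <- stats::dhyper(a, m1, m2, k, log = TRUE)
  keep <- logp <= logObs[idx] + log1p(1e-7)
  p <- as.numeric(rowsum(exp(logp) * keep, idx, reorder = TRUE))
  pmin(p, 1)
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' Estimates the null proportion pi0 by evaluating
#' \code{pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))} over a lambda
#' grid, fitting a cubic smoothing spline (df = 3) and taking the fitted
#' value at the largest lambda, clipped to (0, 1]. q-values follow the
#' step-up construction \code{q_(i) = min_(j >= i) pi0 m p_(j) / j} on the
#' sorted p-values, mapped back to input order.
#'
#' With fewer than 100 p-values the smoother is unstable and pi0 falls
#' back to 1, in which case the q-values equal the classic
#' Benjamini-Hochberg step-up adjustment.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda grid in [0, 0.95) for the pi0 smoother.
#' @param pi0 optional: force a pi0 value (e.g. 1) instead of estimating.
#' @return list with \code{qvalues} (same order as \code{p}) and
#'   \code{pi0}.
#' @examples
#' storeyQvalues(c(0.005, 0.01, 0.5, 1), pi0 = 1)$qvalues
#' @export
storeyQvalues <- function(p, lambda = seq(0, 0.90, by = 0.05), pi0 = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- 1
    } else {
      pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  list(qvalues = out, pi0 = pi0)
}

#' Context-specific FDR policy for DMP calling
#'
#' @param context CG, CHG or CHH
#' @param fdrThreshold q-value cutoff for calling a DMP
#' @param prefilterP optional raw-p cutoff applied before q-value
#'   computation (the two-stage non-CG rule); \code{NA} disables it
#' @return classed list
#' @export
fdrPolicy <- function(context, fdrThreshold, prefilterP = NA_real_) {
  stopifnot(context %in% c("CG", "CHG", "CHH"),
            fdrThreshold > 0, fdrThreshold < 1,
            is.na(prefilterP) || (prefilterP > 0 && prefilterP < 1))
  structure(list(context = context, fdrThreshold = fdrThreshold,
                 prefilterP = prefilterP), class = "FdrPolicy")
}

#' Default context policies: CG q < 0.05; CHG/CHH raw p < 0.05 then
#' q < 0.035 within the passing subset
#' @param cgFdr CG q-value threshold
#' @param nonCgPrefilter raw-p prefilter for CHG/CHH
#' @param nonCgFdr q-value threshold within the prefiltered CHG/CHH subset
#' @return named list of \code{\link{fdrPolicy}} objects
#' @export
defaultFdrPolicies <- function(cgFdr = 0.05, nonCgPrefilter = 0.05,
                               nonCgFdr = 0.035) {
  list(CG = fdrPolicy("CG", cgFdr),
       CHG = fdrPolicy("CHG", nonCgFdr, nonCgPrefilter),
       CHH = fdrPolicy("CHH", nonCgFdr, nonCgPrefilter))
}

#' Call pairwise differentially methylated positions
#'
#' Applies the eligibility filter, computes a two-sided Fisher exact
#' p-value at every eligible site, and calls DMPs per context under its
#' FDR policy. For CG, Storey q-values are computed over all eligible CG
#' sites and a site is a DMP when q falls below the threshold. For CHG and
#' CHH, sites are first restricted to raw p below the prefilter; q-values
#' are computed within that subset and compared to the (stricter)
#' threshold; sites failing the prefilter are NDMPs. Ineligible sites are
#' reported as untested. Direction is \code{hyper} when the test sample's
#' methylation proportion exceeds the reference's, \code{hypo} when lower;
#' equal proportions give p = 1 and can never be DMPs.
#'
#' @param me a \linkS4class{MethylomeExperiment}
#' @param sampleA test sample (e.g. a mutant or epi-line)
#' @param sampleB reference sample (e.g. wild type)
#' @param policies named list of \code{\link{fdrPolicy}} covering CG, CHG,
#'   CHH
#' @param genomewideNonCg if TRUE, skip the non-CG prefilter and compute
#'   q-values genome-wide for CHG/CHH as for CG
#' @param minCoverage,minMethylated eligibility floors, see
#'   \code{\link{eligibleSites}}
#' @return data.frame with one row per site: chrom, pos, strand, context,
#'   meth_a, cov_a, meth_b, cov_b, level_a, level_b, p, q, status
#'   (DMP/NDMP/untested), direction (hyper/hypo/none)
#' @export
callDMPs <- function(me, sampleA, sampleB,
                     policies = defaultFdrPolicies(),
                     genomewideNonCg = FALSE,
                     minCoverage = 4L, minMethylated = 2L) {
  ctxAll <- methContext(me)
  missing <- setdiff(unique(ctxAll), names(policies))
  if (length(missing))
    stop("missing FDR policy for context: ", paste(missing, collapse = ", "))
  elig <- eligibleSites(me, sampleA, sampleB, minCoverage, minMethylated)
  rr <- SummarizedExperiment::rowRanges(me)
  meth <- methCounts(me); cov <- totalReads(me)
  ma <- meth[, sampleA]; ca <- cov[, sampleA]
  mb <- meth[, sampleB]; cb <- cov[, sampleB]
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    strand = as.character(GenomicRanges::strand(rr)),
                    context = ctxAll,
                    meth_a = ma, cov_a = ca, meth_b = mb, cov_b = cb,
                    level_a = ifelse(ca > 0, ma / ca, NA_real_),
                    level_b = ifelse(cb > 0, mb / cb, NA_real_),
                    p = NA_real_, q = NA_real_,
                    status = "untested", direction = "none",
                    stringsAsFactors = FALSE)
  for (ctx in intersect(c("CG", "CHG", "CHH"), unique(ctxAll))) {
    pol <- policies[[ctx]]
    idx <- which(elig & ctxAll == ctx)
    if (!length(idx)) next
    p <- fisherExact2x2(ma[idx], ca[idx] - ma[idx], mb[idx], cb[idx] - mb[idx])
    out$p[idx] <- p
    out$status[idx] <- "NDMP"
    pre <- pol$prefilterP
    if (genomewideNonCg) pre <- NA_real_
    if (is.na(pre)) {
      qres <- storeyQvalues(p)
      out$q[idx] <- qres$qvalues
      sig <- qres$qvalues < pol$fdrThreshold
      sigIdx <- idx[sig]
    } else {
      pass <- p < pre
      sigIdx <- integer(0)
      if (any(pass)) {
        qres <- storeyQvalues(p[pass])
        out$q[idx[pass]] <- qres$qvalues
        sigIdx <- idx[pass][qres$qvalues < pol$fdrThreshold]
      }
    }
    if (length(sigIdx)) {
      la <- ma[sigIdx] / ca[sigIdx]; lb <- mb[sigIdx] / cb[sigIdx]
      out$status[sigIdx] <- "DMP"
      out$direction[sigIdx] <- ifelse(la > lb, "hyper", "hypo")
    }
  }
  attr(out, "samples") <- c(a = sampleA, b = sampleB)
  out
}
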