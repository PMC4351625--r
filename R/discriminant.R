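#' Sample-by-region methylation feature matrix
#'
#' Represents each sample as a vector of region methylation means: for
#' sample s and region r, the pooled proportion (sum of methylated reads /
#' sum of total reads) over the cytosine sites of the region's context
#' falling inside the region. Regions with zero coverage in any sample are
#' dropped with a message.
#'
#' @param regions data.frame with chrom, start, end and optionally context
#'   (rows from \code{\link{callGroupDMRs}} or
#'   \code{\link{tilingMethylation}})
#' @param me a \linkS4class{MethylomeExperiment}
#' @return numeric matrix samples x regions (region ids
#'   \code{chrom:start-end}); attribute \code{regions} keeps the retained
#'   rows
#' @export
regionFeatureMatrix <- function(regions, me) {
  if (!nrow(regions)) stop("no regions supplied")
  rr <- SummarizedExperiment::rowRanges(me)
  meth <- methCounts(me); cov <- totalReads(me)
  ctx <- methContext(me)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(rr), rg,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (!is.null(regions$context)) {
    ok <- ctx[qh] == regions$context[sh]
    qh <- qh[ok]; sh <- sh[ok]
  }
  samples <- colnames(me)
  X <- matrix(NA_real_, length(samples), nrow(regions),
              dimnames = list(samples,
                              paste0(regions$chrom, ":", regions$start,
                                     "-", regions$end)))
  for (j in seq_len(nrow(regions))) {
    idx <- qh[sh == j]
    if (!length(idx)) next
    sm <- colSums(meth[idx, , drop = FALSE])
    sc <- colSums(cov[idx, , drop = FALSE])
    if (all(sc > 0)) X[, j] <- sm / sc
  }
  keep <- colSums(is.na(X)) == 0
  if (!any(keep))
    stop("all regions dropped (zero coverage in some sample)")
  if (any(!keep))
    message(sum(!keep), " region(s) dropped for zero coverage in a sample")
  X <- X[, keep, drop = FALSE]
  attr(X, "regions") <- regions[keep, , drop = FALSE]
  X
}

## deterministic sign convention: flip each component so its
## largest-magnitude loading is positive
.fixSigns <- function(rotation, scores) {
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' PCA reduction of a sample-by-region matrix
#'
#' Columns are centered (not scaled by default: methylation levels share
#' the [0,1] scale) and samples are projected onto the top eigenvectors of
#' the sample covariance matrix. Components are ordered by decreasing
#' eigenvalue; each axis is signed so its largest-magnitude loading is
#' positive.
#'
#' @param X samples x features matrix
#' @param nComponents number of components retained (clipped with a
#'   warning to min(samples - 1, features))
#' @param scale. also scale columns to unit variance
#' @return list: scores (samples x k), rotation (features x k),
#'   varianceFractions, center, sdev
#' @export
pcaReduce <- function(X, nComponents = 4L, scale. = FALSE) {
  stopifnot(nrow(X) >= 2)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (nComponents > kmax) {
    warning("nComponents clipped from ", nComponents, " to ", kmax)
    nComponents <- kmax
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  k <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  fx <- .fixSigns(rot, sc)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = fx$scores, rotation = fx$rotation,
       varianceFractions = vf[seq_len(k)], center = pc$center,
       sdev = pc$sdev[seq_len(k)])
}

## between-group (H) and within-group (E) scatter matrices
.scatterMatrices <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  gnames <- unique(labels)
  p <- ncol(X)
  gm <- t(vapply(gnames, function(g)
    colMeans(X[labels == g, , drop = FALSE]), numeric(p)))
  grand <- colMeans(X)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (gi in seq_along(gnames)) {
    g <- gnames[gi]
    ng <- sum(labels == g)
    d <- gm[gi, ] - grand
    H <- H + ng * tcrossprod(d)
    Xg <- sweep(X[labels == g, , drop = FALSE], 2, gm[gi, ])
    E <- E + crossprod(Xg)
  }
  list(H = H, E = E, groupMeans = gm, groups = gnames)
}

#' Linear discriminant functions from scatter matrices
#'
#' Discriminant directions solve the generalized eigenproblem of
#' between-group versus within-group scatter. The within scatter is
#' stabilized by linear shrinkage toward a scaled identity,
#' \code{(1 - shrinkage) E + shrinkage (trace(E)/p) I}, plus a
#' \code{1e-6 * trace(E)/p} ridge floor against outright singularity:
#' with very few samples per group the raw within scatter underestimates
#' the variance along the leading discriminant directions, which inflates
#' the sphered coordinates and destabilizes held-out classification.
#' Directions are scaled so the pooled within-group covariance of the
#' discriminant coordinates is spherical, and signed so each function's
#' largest coefficient is positive.
#'
#' @param scores samples x dims matrix (typically PCA scores)
#' @param labels group label per sample (>= 2 groups)
#' @param nFunctions number of discriminant functions (clipped to
#'   min(groups - 1, dims))
#' @param rotation optional PCA rotation (features x dims); when given,
#'   discriminant loadings are also back-projected to feature space
#' @param shrinkage within-scatter shrinkage intensity in [0, 1]; 0
#'   recovers classic Fisher LDA (up to the singularity ridge)
#' @return list: coordinates (samples x k), scaling (dims x k, PC-space
#'   coefficients), regionLoadings (or NULL), eigenvalues, groupCentroids
#'   (in LD space), groups, center
#' @export
ldaFit <- function(scores, labels, nFunctions = 2L, rotation = NULL,
                   shrinkage = 0.05) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("ldaFit needs at least two groups")
  stopifnot(nrow(scores) == length(labels), shrinkage >= 0, shrinkage <= 1)
  sm <- .scatterMatrices(scores, labels)
  p <- ncol(scores)
  g <- length(sm$groups)
  k <- min(nFunctions, g - 1L, p)
  trE <- sum(diag(sm$E))
  eps <- if (trE > 0) 1e-6 * trE / p else 1e-8
  Er <- (1 - shrinkage) * sm$E + diag(shrinkage * trE / p + eps, p)
  ## symmetric reduction: eigen of E^{-1/2} H E^{-1/2}
  es <- eigen(Er, symmetric = TRUE)
  Einvhalf <- es$vectors %*% diag(1 / sqrt(pmax(es$values, eps * 1e-6)),
                                  p) %*% t(es$vectors)
  M <- Einvhalf %*% sm$H %*% Einvhalf
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- Einvhalf %*% em$vectors[, seq_len(k), drop = FALSE]
  ## spherical pooled within-class covariance in LD space
  n <- nrow(scores)
  Sw <- Er / max(n - g, 1)
  for (j in seq_len(k)) {
    s <- sqrt(drop(t(V[, j]) %*% Sw %*% V[, j]))
    if (s > 0) V[, j] <- V[, j] / s
  }
  center <- colMeans(scores)
  coords <- sweep(as.matrix(scores), 2, center) %*% V
  fx <- .fixSigns(V, coords)
  V <- fx$rotation; coords <- fx$scores
  colnames(coords) <- colnames(V) <- paste0("LD", seq_len(k))
  centroids <- t(vapply(sm$groups, function(gn)
    colMeans(coords[labels == gn, , drop = FALSE]), numeric(k)))
  regionLoadings <- if (!is.null(rotation))
    rotation %*% V else NULL
  list(coordinates = coords, scaling = V,
       regionLoadings = regionLoadings,
       eigenvalues = em$values[seq_len(k)],
       groupCentroids = centroids, groups = sm$groups, center = center)
}

#' Classify samples by nearest discriminant centroid
#' @param fit result of \code{\link{ldaFit}}
#' @param scores new samples in the same (PC) space
#' @return character vector of predicted groups
#' @export
predictLda <- function(fit, scores) {
  coords <- sweep(as.matrix(scores), 2, fit$center) %*% fit$scaling
  d2 <- vapply(seq_along(fit$groups), function(gi)
    rowSums(sweep(coords, 2, fit$groupCentroids[gi, ])^2),
    numeric(nrow(coords)))
  d2 <- matrix(d2, nrow = nrow(coords))
  fit$groups[max.col(-d2, ties.method = "first")]
}

#' Ward agglomerative clustering on squared Euclidean distances
#'
#' Ward's minimum-variance criterion applied to squared Euclidean
#' distances (hclust method \code{ward.D} on squared distances), with a
#' cut at k clusters.
#'
#' @param coordinates samples x dims matrix
#' @param k number of clusters for the cut
#' @return list: tree (hclust), labels (integer cluster per sample),
#'   heights
#' @export
wardCluster <- function(coordinates, k) {
  n <- nrow(coordinates)
  stopifnot(n >= 2)
  if (k > n) stop("k exceeds the number of samples")
  d2 <- stats::dist(coordinates)^2
  hc <- stats::hclust(d2, method = "ward.D")
  list(tree = hc, labels = stats::cutree(hc, k = k),
       heights = hc$height)
}

#' Pillai's trace MANOVA statistic with F approximation
#'
#' Computes V = trace(H (H + E)^{-1}) from the between-group (H) and
#' within-group (E) scatter matrices of \code{X} given the group labels,
#' with ridge regularization of the total scatter when singular. V is
#' bounded by s = min(groups - 1, dims). The p-value uses the standard F
#' approximation.
#'
#' @param X samples x dims matrix
#' @param labels group label per sample
#' @return list: statistic, s (upper bound), F, df1, df2, p
#' @export
pillaiTrace <- function(X, labels) {
  labels <- as.character(labels)
  X <- as.matrix(X)
  if (length(unique(labels)) < 2) stop("need >= 2 groups")
  sm <- .scatterMatrices(X, labels)
  p <- ncol(X)
  g <- length(sm$groups)
  N <- nrow(X)
  Tm <- sm$H + sm$E
  trT <- sum(diag(Tm))
  if (trT <= 0) stop("all-singular scatter (constant data)")
  eps <- 1e-6 * trT / p
  V <- sum(diag(sm$H %*% solve(Tm + diag(eps, p))))
  s <- min(g - 1, p)
  m <- (abs(p - g + 1) - 1) / 2
  nn <- (N - g - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fstat <- if (df2 > 0 && V < s)
    ((2 * nn + s + 1) / (2 * m + s + 1)) * (V / (s - V)) else NA_real_
  pv <- if (!is.na(Fstat) && df1 > 0 && df2 > 0)
    stats::pf(Fstat, df1, df2, lower.tail = FALSE) else NA_real_
  list(statistic = V, s = s, F = Fstat, df1 = df1, df2 = df2, p = pv)
}

#' Repeated stratified k-fold cross-validation of sample classification
#'
#' The fold count is capped at min(folds, smallest class size, n); when
#' the cap equals n this is leave-one-out. PCA and the classifier are
#' refit inside every training fold (no leakage). The LDA classifier
#' assigns test samples to the nearest discriminant centroid; the SVM
#' corroboration uses a linear kernel with unit cost on the training
#' fold's PCA scores.
#'
#' @param X samples x features matrix
#' @param labels group label per sample
#' @param classifier "lda" or "svm"
#' @param folds requested fold count (default 10)
#' @param repeats number of repeated cross-validations
#' @param seed RNG seed for fold assignment (and permutations)
#' @param nComponents PCA components refit per fold
#' @param nFunctions discriminant functions (lda classifier)
#' @param permute permute labels independently in every repeat
#'   (permutation null)
#' @param shrinkage within-scatter shrinkage for the LDA classifier, see
#'   \code{\link{ldaFit}}
#' @return list: mean, sd, perRepeat (accuracy per repeat), k (folds
#'   used)
#' @export
crossValidate <- function(X, labels, classifier = c("lda", "svm"),
                          folds = 10L, repeats = 50L, seed = 1L,
                          nComponents = 4L, nFunctions = 2L,
                          permute = FALSE, shrinkage = 0.05) {
  classifier <- match.arg(classifier)
  stopifnot(folds >= 2)
  labels <- as.character(labels)
  n <- nrow(X)
  minClass <- min(table(labels))
  k <- min(folds, minClass, n)
  if (k < 2) stop("smallest class too small for cross-validation")
  set.seed(seed)
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    lab <- if (permute) sample(labels) else labels
    ## stratified fold assignment, resampled if a training fold loses a
    ## class
    for (try in 1:100) {
      fold <- integer(n)
      for (g in unique(lab)) {
        i <- which(lab == g)
        fold[i] <- sample(rep_len(seq_len(k), length(i)))
      }
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(lab[fold != f])) == length(unique(lab)),
        logical(1)))
      if (ok) break
    }
    if (!ok) stop("could not build folds containing every class")
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      kc <- min(nComponents, sum(tr) - 1L, ncol(X))
      pc <- suppressWarnings(pcaReduce(X[tr, , drop = FALSE], kc))
      teScores <- sweep(X[te, , drop = FALSE], 2, pc$center) %*%
        pc$rotation
      pred <- if (classifier == "lda") {
        fit <- ldaFit(pc$scores, lab[tr], nFunctions,
                      shrinkage = shrinkage)
        predictLda(fit, teScores)
      } else {
        sv <- e1071::svm(x = pc$scores, y = factor(lab[tr]),
                         kernel = "linear", cost = 1, scale = FALSE)
        as.character(stats::predict(sv, teScores))
      }
      correct <- correct + sum(pred == lab[te])
    }
    acc[r] <- correct / n
  }
  list(mean = mean(acc), sd = stats::sd(acc), perRepeat = acc, k = k)
}

#' Adjusted Rand index between two partitions
#' @param a,b cluster label vectors of equal length
#' @return numeric in [-1, 1]; 1 for identical partitions
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nC2 <- choose(length(a), 2)
  expected <- ai * bj / nC2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

#' Full multivariate discriminant report for a feature matrix
#'
#' Runs PCA, LDA, Ward clustering, Pillai's trace and repeated
#' cross-validation (LDA and SVM) on a sample-by-region matrix.
#'
#' @param X samples x regions matrix (see
#'   \code{\link{regionFeatureMatrix}})
#' @param labels group label per sample
#' @param nComponents PCA components (default 4)
#' @param nFunctions discriminant functions (default 2)
#' @param k clusters for the Ward cut (default: number of groups)
#' @param folds,repeats,seed cross-validation settings
#' @return list: pca, lda, ward, pillai, cvLda, cvSvm
#' @export
discriminantReport <- function(X, labels, nComponents = 4L,
                               nFunctions = 2L,
                               k = length(unique(labels)),
                               folds = 10L, repeats = 50L, seed = 1L) {
  labels <- as.character(labels)
  pca <- suppressWarnings(pcaReduce(X, nComponents))
  lda <- ldaFit(pca$scores, labels, nFunctions,
                rotation = pca$rotation)
  ward <- wardCluster(lda$coordinates, k)
  pil <- pillaiTrace(lda$coordinates, labels)
  cvL <- crossValidate(X, labels, "lda", folds, repeats, seed,
                       nComponents, nFunctions)
  cvS <- crossValidate(X, labels, "svm", folds, repeats, seed + 1L,
                       nComponents, nFunctions)
  list(pca = pca, lda = lda, ward = ward, pillai = pil,
       cvLda = cvL, cvSvm = cvS, labels = labels)
}
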