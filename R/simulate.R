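#' Simulation configuration for synthetic methylomes
#'
#' Parameterizes a toy multi-chromosome genome (arm genes, pericentromerically
#' enriched transposons, a fraction of which contain TE genes), a cytosine
#' scaffold in CG/CHG/CHH contexts, negative-binomial read coverage, and
#' group methylation profiles with planted differential effects. Defaults
#' emulate an Arabidopsis-like methylome at desk scale: heavily CG/CHG
#' methylated transposons concentrated around centromeres, moderately
#' CG-methylated gene bodies, sparse intergenic methylation.
#'
#' The three default group profiles plant (i) nothing (\code{wildtype});
#' (ii) non-CG (CHG/CHH) hypermethylation restricted to pericentromeric
#' transposons (\code{mutant}); (iii) genic CG gain together with transposon
#' CG loss and transposon CHH gain (\code{epiline}).
#'
#' @param nChroms number of chromosomes.
#' @param chromLength chromosome length (bp).
#' @param pericentromereHalfwidth half-width (bp) of the pericentromeric
#'   zone around the midpoint centromere.
#' @param nGenes,geneLengthRange gene count and length range (bp); genes are
#'   placed on chromosome arms.
#' @param nTransposons,teLengthRange transposon count and length range (bp);
#'   placement density increases toward the centromere.
#' @param teGeneFraction fraction of transposons flagged as containing a TE
#'   gene.
#' @param siteDensity named vector, scattered cytosine sites per bp for CG,
#'   CHG, CHH.
#' @param coverageMean,coverageDispersion negative-binomial read-depth mean
#'   and size parameter.
#' @param baselines methylation baselines in [0,1]: a 3x3 matrix with rows
#'   CG/CHG/CHH and columns gene/transposon/intergenic.
#' @param samplesPerGroup named integer vector; names are group names and
#'   must match \code{groupProfiles}.
#' @param groupProfiles named list of effect-descriptor lists. Each
#'   descriptor has fields \code{context}, \code{featureClass}
#'   (\code{gene}/\code{transposon}), \code{pericentromeric}
#'   (TRUE/FALSE/NA = anywhere), \code{direction} (\code{hyper}/\code{hypo})
#'   and optional \code{delta}.
#' @param dmpFraction fraction of matching scattered sites planted as
#'   group-level DMPs.
#' @param effectSize default methylation-difference delta for descriptors
#'   without their own.
#' @param nIslands,islandSites,islandSpacing dense CG/CHG site clusters
#'   hosted inside features; planted group DMRs live on these islands.
#' @param dmrFraction fraction of profile-matching islands planted as DMRs
#'   per group.
#' @param seed integer seed governing all randomness downstream.
#' @return a classed list of validated parameters.
#' @export
simulationConfig <- function(nChroms = 2L,
                             chromLength = 1e6,
                             pericentromereHalfwidth = 150000,
                             nGenes = 200L,
                             geneLengthRange = c(1000, 4000),
                             nTransposons = 150L,
                             teLengthRange = c(800, 3000),
                             teGeneFraction = 0.6,
                             siteDensity = c(CG = 0.008, CHG = 0.004,
                                             CHH = 0.012),
                             coverageMean = 30,
                             coverageDispersion = 5,
                             baselines = NULL,
                             samplesPerGroup = c(wildtype = 3L, mutant = 3L,
                                                 epiline = 3L),
                             groupProfiles = NULL,
                             dmpFraction = 0.2,
                             effectSize = 0.5,
                             nIslands = 40L,
                             islandSites = 25L,
                             islandSpacing = 25L,
                             dmrFraction = 0.5,
                             seed = 1L) {
  if (is.null(baselines)) {
    baselines <- matrix(c(0.20, 0.85, 0.05,
                          0.05, 0.60, 0.05,
                          0.05, 0.15, 0.05),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("CG", "CHG", "CHH"),
                                        c("gene", "transposon", "intergenic")))
  }
  if (is.null(groupProfiles)) {
    groupProfiles <- list(
      wildtype = list(),
      mutant = list(
        list(context = "CHG", featureClass = "transposon",
             pericentromeric = TRUE, direction = "hyper", delta = 0.3),
        list(context = "CHH", featureClass = "transposon",
             pericentromeric = TRUE, direction = "hyper", delta = 0.4)),
      epiline = list(
        list(context = "CG", featureClass = "gene",
             pericentromeric = NA, direction = "hyper", delta = 0.3),
        list(context = "CG", featureClass = "transposon",
             pericentromeric = NA, direction = "hypo", delta = 0.4),
        list(context = "CHH", featureClass = "transposon",
             pericentromeric = NA, direction = "hyper", delta = 0.3)))
  }
  stopifnot(nChroms >= 1, chromLength > 0,
            pericentromereHalfwidth > 0,
            pericentromereHalfwidth < chromLength / 2,
            all(siteDensity >= 0), coverageMean > 0,
            coverageDispersion > 0,
            all(baselines >= 0 & baselines <= 1),
            teGeneFraction >= 0, teGeneFraction <= 1,
            dmpFraction >= 0, dmpFraction <= 1,
            dmrFraction >= 0, dmrFraction <= 1,
            effectSize > 0, effectSize <= 1,
            all(names(samplesPerGroup) %in% names(groupProfiles)))
  for (g in names(groupProfiles))
    for (ef in groupProfiles[[g]]) {
      if (!all(c("context", "featureClass", "direction") %in% names(ef)))
        stop("group effect descriptor for '", g,
             "' needs context, featureClass, direction")
      if (!ef$context %in% c("CG", "CHG", "CHH") ||
          !ef$featureClass %in% c("gene", "transposon", "intergenic") ||
          !ef$direction %in% c("hyper", "hypo"))
        stop("unknown group effect descriptor field value in profile '",
             g, "'")
    }
  structure(list(nChroms = as.integer(nChroms),
                 chromLength = chromLength,
                 pericentromereHalfwidth = pericentromereHalfwidth,
                 nGenes = as.integer(nGenes),
                 geneLengthRange = geneLengthRange,
                 nTransposons = as.integer(nTransposons),
                 teLengthRange = teLengthRange,
                 teGeneFraction = teGeneFraction,
                 siteDensity = siteDensity,
                 coverageMean = coverageMean,
                 coverageDispersion = coverageDispersion,
                 baselines = baselines,
                 samplesPerGroup = samplesPerGroup,
                 groupProfiles = groupProfiles,
                 dmpFraction = dmpFraction,
                 effectSize = effectSize,
                 nIslands = as.integer(nIslands),
                 islandSites = as.integer(islandSites),
                 islandSpacing = as.integer(islandSpacing),
                 dmrFraction = dmrFraction,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$nChroms, "chromosomes x",
      format(x$chromLength, big.mark = ","), "bp;",
      x$nGenes, "genes,", x$nTransposons, "transposons;",
      "groups:", paste(names(x$samplesPerGroup), x$samplesPerGroup,
                       sep = "x", collapse = ", "),
      "; seed", x$seed, "\n")
  invisible(x)
}

#' Build a toy genome: annotation plus cytosine scaffold
#'
#' Genes are placed uniformly on chromosome arms; transposons are placed
#' with density decaying away from the midpoint centromere (half-normal
#' offsets with sd equal to the pericentromere half-width). Scattered
#' cytosine sites are laid down per context at the configured densities,
#' and dense CG/CHG "islands" (contiguous evenly spaced site clusters
#' hosted inside features) provide substrate for planted DMRs.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{annotation}
#'   (\linkS4class{GenomeAnnotation}), \code{sites} (\code{GRanges} with
#'   mcols context, featureClass, pericentromeric, island), \code{islands}
#'   (data.frame of island intervals) and \code{config}.
#' @export
buildToyGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  L <- config$chromLength
  chroms <- paste0("Chr", seq_len(config$nChroms))
  chromSizes <- stats::setNames(rep(as.integer(L), config$nChroms), chroms)
  cents <- stats::setNames(rep(L / 2, config$nChroms), chroms)
  hw <- config$pericentromereHalfwidth

  feats <- list()
  ## genes on arms (outside centromere +/- halfwidth)
  if (config$nGenes > 0) {
    glen <- as.integer(round(stats::runif(config$nGenes,
                                          config$geneLengthRange[1],
                                          config$geneLengthRange[2])))
    gchr <- sample(chroms, config$nGenes, replace = TRUE)
    gstart <- integer(config$nGenes)
    for (i in seq_len(config$nGenes)) {
      armL <- c(1, L / 2 - hw - glen[i])
      armR <- c(L / 2 + hw, L - glen[i])
      if (armL[2] < armL[1] && armR[2] < armR[1])
        stop("features cannot fit in chromosome")
      if (stats::runif(1) < 0.5 && armL[2] >= armL[1])
        gstart[i] <- as.integer(round(stats::runif(1, armL[1], armL[2])))
      else
        gstart[i] <- as.integer(round(stats::runif(1, armR[1], armR[2])))
    }
    feats$genes <- GenomicRanges::GRanges(
      gchr, IRanges::IRanges(gstart, width = glen),
      strand = sample(c("+", "-"), config$nGenes, replace = TRUE),
      id = sprintf("gene%03d", seq_len(config$nGenes)),
      kind = "gene", has_te_gene = FALSE)
  }
  ## transposons: half-normal distance from centromere
  if (config$nTransposons > 0) {
    tlen <- as.integer(round(stats::runif(config$nTransposons,
                                          config$teLengthRange[1],
                                          config$teLengthRange[2])))
    tchr <- sample(chroms, config$nTransposons, replace = TRUE)
    tstart <- integer(config$nTransposons)
    for (i in seq_len(config$nTransposons)) {
      ok <- FALSE
      for (tr in 1:100) {
        d <- abs(stats::rnorm(1, 0, hw)) * sample(c(-1, 1), 1)
        s <- as.integer(round(L / 2 + d - tlen[i] / 2))
        if (s >= 1 && s + tlen[i] - 1 <= L) { ok <- TRUE; break }
      }
      if (!ok) stop("features cannot fit in chromosome")
      tstart[i] <- s
    }
    feats$tes <- GenomicRanges::GRanges(
      tchr, IRanges::IRanges(tstart, width = tlen),
      strand = sample(c("+", "-"), config$nTransposons, replace = TRUE),
      id = sprintf("te%03d", seq_len(config$nTransposons)),
      kind = "transposon",
      has_te_gene = stats::runif(config$nTransposons) < config$teGeneFraction)
  }
  features <- if (length(feats)) suppressWarnings(do.call(c, unname(feats)))
              else GenomicRanges::GRanges()
  ann <- GenomeAnnotation(chromSizes, cents, features)

  ## scattered sites per context
  scatter <- lapply(names(config$siteDensity), function(ctx) {
    n <- as.integer(round(config$siteDensity[[ctx]] * L * config$nChroms))
    if (n == 0) return(NULL)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               pos = as.integer(ceiling(stats::runif(n, 0, L))),
               strand = sample(c("+", "-"), n, replace = TRUE),
               context = ctx, island = NA_integer_,
               stringsAsFactors = FALSE)
  })
  scatter <- do.call(rbind, scatter)

  ## islands: dense evenly spaced clusters inside features
  islands <- NULL
  if (config$nIslands > 0 && length(features)) {
    span <- (config$islandSites - 1L) * config$islandSpacing
    hosts <- which(GenomicRanges::width(features) >= span + 20L)
    if (!length(hosts)) stop("no feature can host an island")
    ## one island per host where possible, so islands do not abut
    pickHosts <- if (length(hosts) >= config$nIslands)
      sample(hosts, config$nIslands)
    else sample(hosts, config$nIslands, replace = TRUE)
    isl <- vector("list", config$nIslands)
    for (k in seq_len(config$nIslands)) {
      h <- features[pickHosts[k]]
      off <- as.integer(round(stats::runif(
        1, 0, GenomicRanges::width(h) - span - 1)))
      p0 <- GenomicRanges::start(h) + off
      ctx <- sample(c("CG", "CHG"), 1)
      isl[[k]] <- data.frame(
        island = k, chrom = as.character(GenomicRanges::seqnames(h)),
        start = p0, end = p0 + span, context = ctx,
        featureClass = S4Vectors::mcols(h)$kind,
        stringsAsFactors = FALSE)
    }
    islands <- do.call(rbind, isl)
    isites <- do.call(rbind, lapply(seq_len(config$nIslands), function(k) {
      data.frame(chrom = islands$chrom[k],
                 pos = seq(islands$start[k], islands$end[k],
                           by = config$islandSpacing),
                 strand = "+", context = islands$context[k],
                 island = k, stringsAsFactors = FALSE)
    }))
    scatter <- rbind(scatter, isites)
  }

  ## island sites win collisions with background scatter
  scatter <- scatter[order(is.na(scatter$island)), ]
  scatter <- scatter[!duplicated(paste(scatter$chrom, scatter$pos,
                                       scatter$strand)), ]

  gr <- GenomicRanges::GRanges(scatter$chrom,
                               IRanges::IRanges(scatter$pos, width = 1),
                               strand = scatter$strand,
                               context = scatter$context,
                               island = scatter$island)
  GenomeInfoDb::seqlevels(gr) <- chroms
  gr <- sort(gr, ignore.strand = TRUE)
  ## feature class: transposon wins over gene where nested
  fclass <- rep("intergenic", length(gr))
  if (length(features)) {
    inGene <- GenomicRanges::countOverlaps(
      gr, features[S4Vectors::mcols(features)$kind == "gene"],
      ignore.strand = TRUE) > 0
    inTE <- GenomicRanges::countOverlaps(
      gr, features[S4Vectors::mcols(features)$kind == "transposon"],
      ignore.strand = TRUE) > 0
    fclass[inGene] <- "gene"
    fclass[inTE] <- "transposon"
  }
  S4Vectors::mcols(gr)$featureClass <- fclass
  S4Vectors::mcols(gr)$pericentromeric <-
    abs(GenomicRanges::start(gr) -
        cents[as.character(GenomicRanges::seqnames(gr))]) <= hw
  if (!is.null(islands)) {
    islands$pericentromeric <-
      abs((islands$start + islands$end) / 2 - cents[islands$chrom]) <= hw
  }
  structure(list(annotation = ann, sites = gr, islands = islands,
                 config = config),
            class = "toyGenome")
}

#' @export
print.toyGenome <- function(x, ...) {
  cat("toyGenome:", length(chromSizes(x$annotation)), "chromosomes,",
      length(annotationFeatures(x$annotation)), "features,",
      length(x$sites), "cytosine sites,",
      if (is.null(x$islands)) 0 else nrow(x$islands), "islands\n")
  invisible(x)
}

## effect descriptor matcher over site metadata
.matchesEffect <- function(ctx, fclass, peri, ef) {
  m <- ctx == ef$context & fclass == ef$featureClass
  if (!is.na(ef$pericentromeric)) m <- m & (peri == ef$pericentromeric)
  m
}

#' Simulate multi-sample methylomes with planted truth
#'
#' For every sample and cytosine site, read coverage is drawn from a
#' negative binomial with the configured mean, and the methylated count is
#' binomial given a per-site methylation level. Levels start at the
#' context-by-feature-class baseline and are shifted by each group's
#' planted effects: scattered group-level DMPs (at \code{dmpFraction} of
#' profile-matching sites) and island-wide group DMRs (at
#' \code{dmrFraction} of profile-matching islands). Shifted levels are
#' clipped to [0.01, 0.99]; with the default baselines and deltas no
#' clipping occurs, so every planted effect has a true level difference of
#' exactly its delta.
#'
#' @param scaffold result of \code{\link{buildToyGenome}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @return list with \code{me} (a \linkS4class{MethylomeExperiment} whose
#'   colData carries \code{group}), \code{truth} (list of data.frames
#'   \code{dmps}, \code{dmrs}, \code{labels}) and \code{levels} (true
#'   per-site, per-sample methylation levels).
#' @export
simulateSamples <- function(scaffold, config = scaffold$config) {
  stopifnot(inherits(scaffold, "toyGenome"),
            inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  gr <- scaffold$sites
  ## match the row order MethylomeExperiment() will use, so the returned
  ## true-level matrix aligns with the experiment's rows
  o <- order(as.factor(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr),
             as.factor(GenomicRanges::strand(gr)))
  gr <- gr[o]
  n <- length(gr)
  ctx <- S4Vectors::mcols(gr)$context
  fclass <- S4Vectors::mcols(gr)$featureClass
  peri <- S4Vectors::mcols(gr)$pericentromeric
  islandId <- S4Vectors::mcols(gr)$island

  groups <- names(config$samplesPerGroup)
  sampleNames <- unlist(lapply(groups, function(g)
    paste0(g, "_", seq_len(config$samplesPerGroup[[g]]))))
  sampleGroup <- rep(groups, config$samplesPerGroup[groups])

  base <- config$baselines[cbind(ctx, fclass)]
  levels <- matrix(rep(base, length(sampleNames)), nrow = n,
                   dimnames = list(NULL, sampleNames))

  truthDmps <- list(); truthDmrs <- list()
  for (g in groups) {
    effs <- config$groupProfiles[[g]]
    if (!length(effs)) next
    gsamples <- sampleNames[sampleGroup == g]
    plantedSites <- logical(n)
    plantedIslands <- integer(0)
    for (ef in effs) {
      delta <- if (!is.null(ef$delta)) ef$delta else config$effectSize
      sgn <- if (ef$direction == "hyper") 1 else -1
      ## scattered DMPs (non-island sites only)
      cand <- which(.matchesEffect(ctx, fclass, peri, ef) &
                    is.na(islandId) & !plantedSites)
      nPick <- floor(config$dmpFraction * length(cand))
      if (nPick > 0) {
        pick <- sample(cand, nPick)
        plantedSites[pick] <- TRUE
        target <- pmin(0.99, pmax(0.01, base[pick] + sgn * delta))
        levels[pick, gsamples] <- target
        truthDmps[[length(truthDmps) + 1L]] <- data.frame(
          chrom = as.character(GenomicRanges::seqnames(gr))[pick],
          pos = GenomicRanges::start(gr)[pick],
          strand = as.character(GenomicRanges::strand(gr))[pick],
          context = ctx[pick], group = g,
          direction = ifelse(target >= base[pick], "hyper", "hypo"),
          delta = abs(target - base[pick]),
          stringsAsFactors = FALSE)
      }
      ## island DMRs
      if (!is.null(scaffold$islands)) {
        isl <- scaffold$islands
        mIsl <- which(isl$context == ef$context &
                      isl$featureClass == ef$featureClass &
                      (is.na(ef$pericentromeric) |
                       isl$pericentromeric == ef$pericentromeric) &
                      !(isl$island %in% plantedIslands))
        nIsl <- floor(config$dmrFraction * length(mIsl))
        if (nIsl > 0) {
          pickI <- sample(mIsl, nIsl)
          plantedIslands <- c(plantedIslands, isl$island[pickI])
          for (k in isl$island[pickI]) {
            idx <- which(!is.na(islandId) & islandId == k)
            target <- pmin(0.99, pmax(0.01, base[idx] + sgn * delta))
            levels[idx, gsamples] <- target
            truthDmrs[[length(truthDmrs) + 1L]] <- data.frame(
              chrom = isl$chrom[isl$island == k],
              start = isl$start[isl$island == k],
              end = isl$end[isl$island == k],
              context = ef$context, group = g,
              direction = ef$direction,
              delta = abs(target[1] - base[idx][1]),
              island = k, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  cov <- matrix(stats::rnbinom(n * length(sampleNames),
                               mu = config$coverageMean,
                               size = config$coverageDispersion),
                nrow = n, dimnames = list(NULL, sampleNames))
  meth <- matrix(stats::rbinom(n * length(sampleNames), as.vector(cov),
                               as.vector(levels)),
                 nrow = n, dimnames = list(NULL, sampleNames))
  me <- MethylomeExperiment(meth, cov, gr, sampleNames = sampleNames)
  SummarizedExperiment::colData(me)$group <- sampleGroup

  emptyDmp <- data.frame(chrom = character(), pos = integer(),
                         strand = character(), context = character(),
                         group = character(), direction = character(),
                         delta = numeric(), stringsAsFactors = FALSE)
  emptyDmr <- data.frame(chrom = character(), start = integer(),
                         end = integer(), context = character(),
                         group = character(), direction = character(),
                         delta = numeric(), island = integer(),
                         stringsAsFactors = FALSE)
  truth <- list(
    dmps = if (length(truthDmps)) do.call(rbind, truthDmps) else emptyDmp,
    dmrs = if (length(truthDmrs)) do.call(rbind, truthDmrs) else emptyDmr,
    labels = data.frame(sample = sampleNames, group = sampleGroup,
                        stringsAsFactors = FALSE))
  list(me = me, truth = truth, levels = levels)
}

#' One-call synthetic methylome: build genome and simulate samples
#' @param config a \code{\link{simulationConfig}}
#' @return list with \code{scaffold}, \code{me}, \code{truth}, \code{levels}
#' @export
simulateMethylomes <- function(config = simulationConfig()) {
  scaffold <- buildToyGenome(config)
  sim <- simulateSamples(scaffold, config)
  c(list(scaffold = scaffold), sim)
}
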