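#' Run the full synthetic-methylome analysis pipeline
#'
#' Orchestrates simulate -> write/read standard formats -> pairwise DMP
#' calling against a reference sample -> feature annotation, boundary
#' profiles and chromosome density -> group-wise CG/CHG DMRs and TE-gene
#' enrichment -> tiling windows -> multivariate discriminant report. Every
#' stage consumes files in standard formats written by the previous one,
#' all randomness derives from the configuration seed, and a manifest
#' records per-stage parameters and row counts.
#'
#' @param config a \code{\link{simulationConfig}}
#' @param outDir output directory
#' @param referenceSample reference (wild-type) sample for pairwise DMP
#'   calls; defaults to the first sample of the first group
#' @param policies DMP FDR policies (\code{\link{defaultFdrPolicies}})
#' @param dmrFdr,dmrMinDiff group-DMR significance settings
#' @param cvRepeats repeated cross-validations in the discriminant stage
#' @param verbose log one line per stage
#' @return invisible list: paths of written tables, the manifest
#'   data.frame, and the in-memory results (dmps, dmrs, report, ...)
#' @export
runPipeline <- function(config = simulationConfig(), outDir,
                        referenceSample = NULL,
                        policies = defaultFdrPolicies(),
                        dmrFdr = 0.05, dmrMinDiff = 0.1,
                        cvRepeats = 20L, verbose = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  groups <- names(config$samplesPerGroup)
  expectedSamples <- unlist(lapply(groups, function(g)
    paste0(g, "_", seq_len(config$samplesPerGroup[[g]]))))
  if (is.null(referenceSample))
    referenceSample <- expectedSamples[1]
  if (!referenceSample %in% expectedSamples)
    stop("referenceSample '", referenceSample,
         "' is not among the configured samples")
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory ", outDir)
  log1 <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s", stage, paste0(...)))
  manifest <- list()
  note <- function(stage, table, n, params = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, table = table, n_rows = n, params = params,
      stringsAsFactors = FALSE)
  }

  ## stage 1: simulate and emit standard formats
  sim <- simulateMethylomes(config)
  me0 <- sim$me
  repDir <- file.path(outDir, "cytosine_reports")
  dir.create(repDir, showWarnings = FALSE)
  reportPaths <- stats::setNames(
    file.path(repDir, paste0(colnames(me0), ".cx.txt")), colnames(me0))
  for (s in colnames(me0)) writeCytosineReport(me0, s, reportPaths[[s]])
  writeAnnotationBed(annotationFeatures(sim$scaffold$annotation),
                     file.path(outDir, "annotation.bed"))
  cs <- chromSizes(sim$scaffold$annotation)
  utils::write.table(data.frame(names(cs), unname(cs)),
                     file.path(outDir, "chrom_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cm <- centromeres(sim$scaffold$annotation)
  utils::write.table(data.frame(names(cm), unname(cm)),
                     file.path(outDir, "centromeres.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeResultTables(list(truth_dmps = sim$truth$dmps,
                         truth_dmrs = sim$truth$dmrs,
                         sample_groups = sim$truth$labels), outDir)
  note("simulate", "cytosine_reports", nrow(me0),
       sprintf("samples=%d seed=%d", ncol(me0), config$seed))
  note("simulate", "truth_dmps", nrow(sim$truth$dmps))
  note("simulate", "truth_dmrs", nrow(sim$truth$dmrs))
  log1("simulate", nrow(me0), " sites x ", ncol(me0), " samples")

  ## stage 2: read back through the standard-format readers
  me <- readCytosineReports(reportPaths)
  ann <- GenomeAnnotation(
    readChromSizes(file.path(outDir, "chrom_sizes.tsv")),
    readCentromeres(file.path(outDir, "centromeres.tsv")),
    readAnnotationFeatures(file.path(outDir, "annotation.bed"), "BED"))
  labels <- stats::setNames(sim$truth$labels$group,
                            sim$truth$labels$sample)

  ## stage 3: pairwise DMPs vs the reference sample
  dmpTables <- list()
  for (s in setdiff(colnames(me), referenceSample)) {
    tab <- callDMPs(me, s, referenceSample, policies)
    dmpTables[[s]] <- tab
    note("call-dmps", paste0("dmps_", s), nrow(tab),
         sprintf("a=%s b=%s", s, referenceSample))
  }
  writeResultTables(stats::setNames(
    dmpTables, paste0("dmps_", names(dmpTables))), outDir)
  nDmp <- vapply(dmpTables, function(t) sum(t$status == "DMP"), numeric(1))
  log1("call-dmps", sum(nDmp), " DMPs across ", length(dmpTables),
       " comparisons")

  ## stage 4: annotation, boundary profiles, chromosome density
  annotated <- lapply(dmpTables, assignFeatures, annotation = ann)
  profiles <- boundaryProfiles(dmpTables, ann)
  density <- lapply(dmpTables, chromosomeDensity,
                    chromSizes = chromSizes(ann),
                    window = config$chromLength / 10)
  densityTab <- do.call(rbind, lapply(names(density), function(s)
    cbind(sample = s, density[[s]])))
  writeResultTables(list(boundary_profiles = profiles,
                         chromosome_density = densityTab), outDir)
  note("annotate", "boundary_profiles", nrow(profiles))
  note("annotate", "chromosome_density", nrow(densityTab))
  log1("annotate", nrow(profiles), " profile bins")

  ## stage 5: group-wise DMRs (reference group vs each other group)
  refGroup <- labels[[referenceSample]]
  dmrTables <- list()
  for (g in setdiff(unique(labels), refGroup)) {
    pair <- labels[labels %in% c(refGroup, g)]
    for (ctx in c("CG", "CHG")) {
      nm <- paste0("dmrs_", g, "_", ctx)
      dmrTables[[nm]] <- callGroupDMRs(me, pair, context = ctx,
                                       fdr = dmrFdr, minDiff = dmrMinDiff)
      note("call-dmrs", nm, nrow(dmrTables[[nm]]),
           sprintf("groups=%s/%s context=%s", refGroup, g, ctx))
    }
  }
  dropLevels <- function(t) t[, !grepl("^level_", colnames(t)),
                              drop = FALSE]
  writeResultTables(lapply(dmrTables, identity), outDir)
  sig <- do.call(rbind, lapply(dmrTables, function(t) {
    t <- t[t$status == "significant",
           c("chrom", "start", "end", "context"), drop = FALSE]
    t
  }))
  sig <- unique(sig)
  log1("call-dmrs", nrow(sig), " significant group DMRs")

  ## TE-gene enrichment among DMR-associated transposons
  tes <- annotationFeatures(ann)
  tes <- tes[S4Vectors::mcols(tes)$kind == "transposon"]
  enrich <- if (nrow(sig) && length(tes)) {
    assoc <- dmrAssociatedTransposons(sig, ann)
    if (length(assoc)) teGeneEnrichment(assoc, tes) else NULL
  } else NULL
  if (!is.null(enrich)) {
    enrichTab <- data.frame(odds_ratio = enrich$oddsRatio, p = enrich$p,
                            assoc_te_gene = enrich$table[1, 1],
                            assoc_other = enrich$table[1, 2],
                            rest_te_gene = enrich$table[2, 1],
                            rest_other = enrich$table[2, 2])
    writeResultTables(list(te_gene_enrichment = enrichTab), outDir)
    note("enrichment", "te_gene_enrichment", 1L)
  }

  ## stage 6: tiling windows
  tiles <- tilingMethylation(me)
  writeResultTables(list(tiling_windows = tiles), outDir)
  note("tiles", "tiling_windows", nrow(tiles), "window=340 min_sites=20")
  log1("tiles", nrow(tiles), " retained windows")

  ## stage 7: discriminant analysis on DMR methylation vectors
  report <- NULL
  if (nrow(sig) >= 2) {
    X <- suppressMessages(regionFeatureMatrix(sig, me))
    report <- discriminantReport(X, labels[rownames(X)],
                                 repeats = cvRepeats,
                                 seed = config$seed)
    repTabs <- list(
      pc_scores = data.frame(sample = rownames(report$pca$scores),
                             report$pca$scores,
                             check.names = FALSE),
      ld_coordinates = data.frame(
        sample = rownames(report$lda$coordinates),
        group = report$labels, report$lda$coordinates,
        cluster = report$ward$labels, check.names = FALSE),
      ld_region_loadings = data.frame(
        region = rownames(report$lda$regionLoadings),
        report$lda$regionLoadings, check.names = FALSE),
      cv_summary = data.frame(
        classifier = c("lda", "svm"),
        mean_accuracy = c(report$cvLda$mean, report$cvSvm$mean),
        sd_accuracy = c(report$cvLda$sd, report$cvSvm$sd),
        folds_used = c(report$cvLda$k, report$cvSvm$k)),
      pillai = data.frame(statistic = report$pillai$statistic,
                          s_bound = report$pillai$s,
                          F = report$pillai$F, p = report$pillai$p))
    writeResultTables(repTabs, outDir)
    for (nm in names(repTabs)) note("discriminate", nm, nrow(repTabs[[nm]]))
    log1("discriminate", sprintf(
      "cv accuracy lda=%.3f svm=%.3f, Pillai=%.4f",
      report$cvLda$mean, report$cvSvm$mean, report$pillai$statistic))
  } else log1("discriminate", "skipped: fewer than 2 significant DMRs")

  manifestTab <- do.call(rbind, manifest)
  writeResultTables(list(manifest = manifestTab), outDir)
  invisible(list(outDir = outDir, manifest = manifestTab, me = me,
                 annotation = ann, truth = sim$truth,
                 dmps = dmpTables, profiles = profiles,
                 dmrs = dmrTables, significantDmrs = sig,
                 tiles = tiles, enrichment = enrich, report = report))
}
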