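## Pipeline orchestration: simulate -> call-emulate -> merge -> filter ->
## landscape -> diversity -> selection, with a manifest of every dataset
## produced (the dataset-ledger analogue of the study's filtering figure).

#' Validate a pipeline configuration
#'
#' Checks every parameter object's invariants before any stage runs, and
#' warns about user overrides of field conventions (e.g. a minimum SV
#' length other than 30 bp).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param mergeParamsPerSample,mergeParamsAcross merge-stage parameters.
#' @param filterSettings filter-stage parameters.
#' @return invisibly, a list of the validated parameter objects.
#' @export
validateConfig <- function(config,
                           mergeParamsPerSample = mergeParams(),
                           mergeParamsAcross = mergeParams(minSupport = 1L,
                             requireGenotypeAgreement = FALSE),
                           filterSettings = filterParams()) {
  validObject(config)
  validObject(mergeParamsPerSample)
  validObject(mergeParamsAcross)
  validObject(filterSettings)
  if (mergeParamsPerSample@minLen != 30)
    warning("minimum SV length ", mergeParamsPerSample@minLen,
            " bp differs from the conventional 30 bp")
  if (mergeParamsPerSample@maxDist != mergeParamsAcross@maxDist)
    warning("per-sample and cross-sample merges use different maxDist")
  invisible(list(config = config,
                 mergePerSample = mergeParamsPerSample,
                 mergeAcross = mergeParamsAcross,
                 filter = filterSettings))
}

.manifestRow <- function(dataset, n, file = NA_character_,
                         note = NA_character_) {
  data.frame(dataset = dataset, nVariants = n, file = file, note = note,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on a synthetic study
#'
#' Executes, in order: genome + truth simulation, caller emulation (VCFs
#' written per sample per caller), genotype-aware consensus merging
#' (producing the unfiltered SV dataset), filtering (the popgen-filtered
#' SV dataset; the whole-genome, linkage-pruned and thinned SNP datasets
#' with a kinship screen), the density landscape, diversity statistics and
#' the selection scans.  Re-running with the same config and seed
#' reproduces all outputs.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outdir output directory.
#' @param stages subset of
#'   \code{c("simulate","call","merge","filter","landscape","diversity","selection")};
#'   later stages require the earlier ones in the same call.
#' @param focalPop native population used for the balancing-selection scan.
#' @param contrasts list of 2-vectors of population names for the outlier
#'   scans; flags are unioned across contrasts.
#' @param excludePops populations excluded from the invader-specific and
#'   selection analyses (the range-edge deme).
#' @param nPod,podQuantile pseudo-observed-data calibration settings.
#' @param verbose print stage timings.
#' @return a list of stage results including \code{manifest}.
#' @export
runPipeline <- function(config, outdir,
                        stages = c("simulate", "call", "merge", "filter",
                                   "landscape", "diversity", "selection"),
                        focalPop = "UK",
                        contrasts = list(c("UK", "AU_EAST"),
                                         c("UK", "AU_SOUTH")),
                        excludePops = "MGL",
                        nPod = 5000L, podQuantile = 0.99,
                        verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  validateConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  manifest <- NULL
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%T"),
                                            "] ", ...)
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' needs '", what,
           "', whose producing stage was not run")
    res[[what]]
  }

  if ("simulate" %in% stages) {
    say("simulate: genome and truth")
    res$genome <- simulateGenome(config, dir = file.path(outdir, "genome"))
    res$truth <- simulatePopulationVariants(config, res$genome)
    popmapPath <- file.path(outdir, "popmap.tsv")
    writePopulationMap(res$truth, popmapPath)
    res$populationMap <- readPopulationMap(popmapPath)
    snpVcf <- file.path(outdir, "snps.vcf")
    writeGenotypeVcf(truthSnp(res$truth), snpVcf)
    res$snpRaw <- readGenotypeVcf(snpVcf, res$populationMap)
    manifest <- rbind(manifest,
      .manifestRow("truth_snp", nrow(truthSnp(res$truth)), snpVcf),
      .manifestRow("truth_sv", nrow(truthSv(res$truth))))
  }
  if ("call" %in% stages) {
    truth <- need("truth", "call")
    say("call: emulating ", length(config@callerProfiles), " callers")
    res$calls <- emulateCallers(truth)
    callDir <- file.path(outdir, "calls")
    res$callFiles <- writeCallerVcfs(res$calls, callDir)
    manifest <- rbind(manifest,
      .manifestRow("caller_vcfs", length(res$callFiles), callDir))
  }
  if ("merge" %in% stages) {
    need("callFiles", "merge")
    say("merge: per-sample genotype-aware consensus")
    callsets <- readCallerVcfs(file.path(outdir, "calls"), passOnly = TRUE)
    perSample <- lapply(callsets, mergePerSample)
    say("merge: cross-sample")
    res$svUnfiltered <- mergeAcrossSamples(
      perSample, populationMap = res$populationMap)
    cohortVcf <- file.path(outdir, "sv_unfiltered.vcf")
    writeGenotypeVcf(res$svUnfiltered, cohortVcf)
    manifest <- rbind(manifest,
      .manifestRow("sv_unfiltered", nrow(res$svUnfiltered), cohortVcf,
                   "consensus merge, all samples"))
  }
  if ("filter" %in% stages) {
    say("filter: missingness/MAF, LD prune, thinning, kinship")
    snpRaw <- need("snpRaw", "filter")
    res$snpWholeGenome <- ldPrune(filterMissingMaf(snpRaw))
    res$snpThinned <- thinSites(res$snpWholeGenome)
    res$kinship <- relatednessCheck(res$snpThinned)
    sv <- need("svUnfiltered", "filter")
    res$svPopgen <- filterMissingMaf(sv)
    popgenVcf <- file.path(outdir, "sv_popgen.vcf")
    writeGenotypeVcf(res$svPopgen, popgenVcf)
    manifest <- rbind(manifest,
      .manifestRow("snp_wholegenome", nrow(res$snpWholeGenome), NA,
                   "missingness/MAF + LD-pruned"),
      .manifestRow("snp_thinned", nrow(res$snpThinned), NA,
                   paste0("thin > ", filterParams()@thinDistance, " bp; ",
                          sum(res$kinship$flagged), " kinship flags")),
      .manifestRow("sv_popgen", nrow(res$svPopgen), popgenVcf,
                   "missingness/MAF filtered"))
  }
  if ("landscape" %in% stages) {
    say("landscape: density bins, regression, break-end classes")
    snp <- need("snpWholeGenome", "landscape")
    sv <- need("svUnfiltered", "landscape")
    res$windows <- binCounts(snp, sv)
    res$densityFit <- densityRegression(res$windows)
    res$subtelomere <- subtelomereEnrichment(
      res$windows, res$densityFit$residuals, config@subtelomereFrac)
    genes <- need("genome", "landscape")$genes
    allVars <- c(granges(rowRanges(snp)), granges(rowRanges(sv)))
    mcols(allVars)$type <- c(variantType(snp), variantType(sv))
    mcols(allVars)$svlen <- c(mcols(rowRanges(snp))$svlen,
                              mcols(rowRanges(sv))$svlen)
    res$sizeClassTable <- overlapBySizeClass(allVars, genes)
    res$breakendClasses <- classifyBreakends(
      rowRanges(sv)[variantType(sv) != "SNP"], res$genome$repeats)
    res$heterozygosity <- list(
      snp = individualHeterozygosity(need("snpThinned", "landscape")),
      sv = individualHeterozygosity(need("svPopgen", "landscape")))
  }
  if ("diversity" %in% stages) {
    say("diversity: per-population tables, PCA, invader-specific SFS")
    snpT <- need("snpThinned", "diversity")
    svP <- need("svPopgen", "diversity")
    res$diversity <- list(snp = diversityTable(snpT),
                          sv = diversityTable(svP))
    res$pca <- list(snp = pcaGenotypes(snpT), sv = pcaGenotypes(svP))
    excl <- colnames(svP)[samplePopulation(svP) %in% excludePops]
    invPops <- setdiff(config@invaderPops, excludePops)
    res$invaderSpecificSv <- invaderSpecific(svP, invPops, excl)
    res$invaderCommonSv <- commonFilter(
      svP, res$invaderSpecificSv,
      samples = setdiff(colnames(svP), excl))
    genes <- need("genome", "diversity")$genes
    res$svSfs <- foldedSfs(svP, genes = genes)
    res$candidateGenes <- unique(unlist(intersectAnnotation(
      rowRanges(svP)[res$invaderCommonSv], genes, mode = "within_1kb")))
    manifest <- rbind(manifest,
      .manifestRow("sv_invader_specific", length(res$invaderSpecificSv)),
      .manifestRow("sv_invader_common", length(res$invaderCommonSv),
                   note = "MAF > 0.15"))
  }
  if ("selection" %in% stages) {
    say("selection: outlier scans, beta(1), pseudo-beta, group test")
    snpW <- need("snpWholeGenome", "selection")
    svP <- need("svPopgen", "selection")
    pop <- samplePopulation(snpW)
    keepS <- !(pop %in% excludePops)
    scanOne <- function(gm, label) {
      flags <- rep(FALSE, nrow(gm))
      scans <- list()
      for (ct in contrasts) {
        gA <- colnames(gm)[samplePopulation(gm) == ct[1]]
        gB <- colnames(gm)[samplePopulation(gm) == ct[2]]
        sc <- podThreshold(gm, gA, gB, nPod = nPod, probs = podQuantile,
                           seed = config@seed,
                           contrast = paste0(label, ".", ct[1], "_vs_",
                                             ct[2]))
        flags <- flags | sc$flagged
        scans[[sc$contrast]] <- sc
      }
      list(flags = flags, scans = scans)
    }
    res$snpOutliers <- scanOne(snpW[, keepS], "snp")
    keepV <- !(samplePopulation(svP) %in% excludePops)
    res$svOutliers <- scanOne(svP[, keepV], "sv")
    focal <- colnames(snpW)[samplePopulation(snpW) == focalPop]
    res$betaScores <- betaScan(snpW, samples = focal)
    svRec <- rowRanges(svP)
    res$pseudoBeta <- pseudoBeta(svRec, res$betaScores)
    snpOut <- res$snpOutliers$flags[match(res$betaScores$core,
                                          rownames(snpW))]
    svOut <- setNames(res$svOutliers$flags, rownames(svP))
    svTy <- setNames(variantType(svP), rownames(svP))
    res$groupTest <- tryCatch(
      sevenGroupTest(res$betaScores, snpOut, res$pseudoBeta$scores,
                     svOut, svTy),
      error = function(e) {
        warning("seven-group test not run: ", conditionMessage(e))
        NULL
      })
    manifest <- rbind(manifest,
      .manifestRow("snp_outliers", sum(res$snpOutliers$flags)),
      .manifestRow("sv_outliers", sum(res$svOutliers$flags)),
      .manifestRow("snp_beta_scores", nrow(res$betaScores)),
      .manifestRow("sv_pseudo_beta", nrow(res$pseudoBeta$scores)))
  }
  res$manifest <- manifest
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("done")
  res
}
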