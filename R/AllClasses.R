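#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps pintersect granges sort
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   colData rowRanges<- colData<-
NULL

SV_TYPES <- c("DEL", "DUP", "INV", "INS", "TRA")

## ---------------------------------------------------------------------------
## CallerProfile
## ---------------------------------------------------------------------------

#' CallerProfile: error model of one pseudo SV caller
#'
#' Describes how one emulated short-read SV caller corrupts the truth set:
#' per-type detection probability, uniform positional jitter of reported
#' break ends, genotype miscall rate, density of false-positive calls, and
#' the probability that a call receives the PASS filter.
#'
#' @slot name caller identifier.
#' @slot detectProb named numeric, detection probability per SV type
#'   (DEL, DUP, INV, INS, TRA), each in \code{[0, 1]}.
#' @slot posJitter integer, maximum absolute break-end jitter in bp.  Must be
#'   below 1000 bp so replicate calls of one true SV stay mergeable under the
#'   1-kb consensus rule.
#' @slot genotypeErrorRate probability that a reported genotype is corrupted
#'   to a different genotype.
#' @slot falsePositiveRate expected false-positive calls per Mb of genome.
#' @slot passFilterProb probability a call is annotated FILTER=PASS.
#' @aliases CallerProfile-class
#' @exportClass CallerProfile
setClass("CallerProfile",
  representation(
    name = "character",
    detectProb = "numeric",
    posJitter = "integer",
    genotypeErrorRate = "numeric",
    falsePositiveRate = "numeric",
    passFilterProb = "numeric"
  )
)

setValidity("CallerProfile", function(object) {
  msg <- character()
  if (!identical(sort(names(object@detectProb)), sort(SV_TYPES)))
    msg <- c(msg, "detectProb must be named with DEL, DUP, INV, INS, TRA")
  if (any(object@detectProb < 0 | object@detectProb > 1))
    msg <- c(msg, "detectProb values must lie in [0, 1]")
  if (object@posJitter < 0L || object@posJitter >= 1000L)
    msg <- c(msg, "posJitter must lie in [0, 1000) bp")
  for (s in c("genotypeErrorRate", "passFilterProb")) {
    v <- slot(object, s)
    if (length(v) != 1L || v < 0 || v > 1)
      msg <- c(msg, paste(s, "must be a single value in [0, 1]"))
  }
  if (object@falsePositiveRate < 0)
    msg <- c(msg, "falsePositiveRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CallerProfile
#'
#' @param name caller id.
#' @param detectProb single probability recycled over SV types, or a named
#'   vector with entries DEL, DUP, INV, INS, TRA.
#' @param posJitter maximum absolute positional jitter (bp, < 1000).
#' @param genotypeErrorRate genotype miscall probability.
#' @param falsePositiveRate false positives per Mb.
#' @param passFilterProb probability of FILTER=PASS.
#' @return a \linkS4class{CallerProfile}.
#' @examples
#' identityCallerProfile("exact")
#' callerProfile("sloppy", detectProb = 0.8, posJitter = 150L,
#'               genotypeErrorRate = 0.05, falsePositiveRate = 2)
#' @export
callerProfile <- function(name, detectProb = 0.85, posJitter = 100L,
                          genotypeErrorRate = 0.02, falsePositiveRate = 1,
                          passFilterProb = 0.95) {
  if (length(detectProb) == 1L && is.null(names(detectProb)))
    detectProb <- setNames(rep(detectProb, 5L), SV_TYPES)
  new("CallerProfile", name = as.character(name),
      detectProb = detectProb[SV_TYPES],
      posJitter = as.integer(posJitter),
      genotypeErrorRate = genotypeErrorRate,
      falsePositiveRate = falsePositiveRate,
      passFilterProb = passFilterProb)
}

#' @describeIn callerProfile a perfect caller: every SV detected at its true
#'   position with its true genotype, no false positives, always PASS.
#' @export
identityCallerProfile <- function(name) {
  callerProfile(name, detectProb = 1, posJitter = 0L, genotypeErrorRate = 0,
                falsePositiveRate = 0, passFilterProb = 1)
}

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' SimConfig: the stated world of the synthetic study design
#'
#' Parameters of the synthetic-data generator.  The defaults emulate the
#' study design the pipeline targets: a native source population, a second
#' invasive range, a structured invasive range split in two subgroups, and a
#' small extreme-drift range-edge deme, genotyped for SNPs and five SV
#' classes by three imperfect callers.
#'
#' @slot seed master seed; all randomness forks named substreams off it.
#' @slot chromLengths integer vector of chromosome lengths (bp).
#' @slot populations data.frame with columns \code{name}, \code{n},
#'   \code{F} (Balding-Nichols drift parameter in [0,1)), \code{batch}.
#' @slot nSnps,nSvs locus counts.
#' @slot svTypeWeights named probabilities over DEL/DUP/INV/INS/TRA.
#' @slot svLengthRange log-uniform SV length range (bp, min >= 30).
#' @slot geneDensity,repeatDensity features per Mb.
#' @slot geneLengthRange,repeatLengthRange uniform feature length ranges.
#' @slot subtelomereFrac fraction of each chromosome end treated as
#'   subtelomeric.
#' @slot svSubtelomereEnrichment multiplier (>= 1) on SV placement density
#'   inside subtelomeric windows.
#' @slot callerProfiles list of three \linkS4class{CallerProfile}s.
#' @slot nBalancedLoci number of planted balanced-polymorphism clusters.
#' @slot balancedUpstreamOfSv when TRUE, balanced-cluster cores are placed
#'   in the 1-kb window upstream of deletion break ends instead of at
#'   random SNP positions.
#' @slot nDivergentLoci number of planted divergent SNPs.
#' @slot invaderSpecificSvFrac fraction of SVs private to the invasive
#'   populations.
#' @slot ancestralRange uniform range of ancestral allele frequencies.
#' @slot invaderPops population names treated as the invasive range.
#' @slot divergentPair two population names between which divergent loci are
#'   planted.
#' @slot svDropoutBatch,svDropoutProb optional batch label whose samples lose
#'   each SV call (across all callers) with the given probability.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "integer",
    chromLengths = "numeric",
    populations = "data.frame",
    nSnps = "integer",
    nSvs = "integer",
    svTypeWeights = "numeric",
    svLengthRange = "numeric",
    geneDensity = "numeric",
    repeatDensity = "numeric",
    geneLengthRange = "numeric",
    repeatLengthRange = "numeric",
    subtelomereFrac = "numeric",
    svSubtelomereEnrichment = "numeric",
    callerProfiles = "list",
    nBalancedLoci = "integer",
    balancedUpstreamOfSv = "logical",
    nDivergentLoci = "integer",
    invaderSpecificSvFrac = "numeric",
    ancestralRange = "numeric",
    invaderPops = "character",
    divergentPair = "character",
    svDropoutBatch = "character",
    svDropoutProb = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (any(object@chromLengths <= 0)) msg <- c(msg, "chromosome lengths must be positive")
  p <- object@populations
  if (!all(c("name", "n", "F", "batch") %in% names(p)))
    msg <- c(msg, "populations needs columns name, n, F, batch")
  else {
    if (any(p$F < 0 | p$F >= 1))
      msg <- c(msg, "population drift F must lie in [0, 1)")
    if (any(p$n < 1)) msg <- c(msg, "population sizes must be >= 1")
    if (anyDuplicated(p$name)) msg <- c(msg, "population names must be unique")
  }
  if (abs(sum(object@svTypeWeights) - 1) > 1e-8)
    msg <- c(msg, "svTypeWeights must sum to 1")
  if (!identical(sort(names(object@svTypeWeights)), sort(SV_TYPES)))
    msg <- c(msg, "svTypeWeights must be named DEL, DUP, INV, INS, TRA")
  if (object@svLengthRange[1] < 30)
    msg <- c(msg, "minimum SV length must be >= 30 bp")
  if (object@svLengthRange[2] < object@svLengthRange[1])
    msg <- c(msg, "svLengthRange must be increasing")
  if (object@subtelomereFrac < 0 || object@subtelomereFrac > 0.5)
    msg <- c(msg, "subtelomereFrac must lie in [0, 0.5]")
  if (object@svSubtelomereEnrichment < 1)
    msg <- c(msg, "svSubtelomereEnrichment must be >= 1")
  if (any(2 * object@subtelomereFrac * object@chromLengths >= object@chromLengths + 1e-9) &&
      object@subtelomereFrac > 0.5)
    msg <- c(msg, "chromosome shorter than twice the subtelomere window")
  if (length(object@callerProfiles) != 3L ||
      !all(vapply(object@callerProfiles, is, logical(1), "CallerProfile")))
    msg <- c(msg, "callerProfiles must be a list of three CallerProfile objects")
  if (object@invaderSpecificSvFrac < 0 || object@invaderSpecificSvFrac > 1)
    msg <- c(msg, "invaderSpecificSvFrac must lie in [0, 1]")
  if (length(object@ancestralRange) != 2L ||
      object@ancestralRange[1] <= 0 || object@ancestralRange[2] >= 1 ||
      diff(object@ancestralRange) < 0)
    msg <- c(msg, "ancestralRange must be an increasing range inside (0, 1)")
  if (!all(object@invaderPops %in% p$name))
    msg <- c(msg, "invaderPops must name populations")
  if (length(object@divergentPair) != 2L || !all(object@divergentPair %in% p$name))
    msg <- c(msg, "divergentPair must name two populations")
  if (object@svDropoutProb < 0 || object@svDropoutProb > 1)
    msg <- c(msg, "svDropoutProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults describe the emulated study: 8 native (UK), 8 second-range
#' invasive (NA), 30 structured invasive (AU east/south) plus a 3-sample
#' extreme-drift range edge (MGL), on a 3-chromosome 12-Mb genome, with
#' three imperfect callers.  See the package vignette for the rationale behind each
#' default.
#'
#' @param seed master seed.
#' @param chromLengths chromosome lengths in bp.
#' @param populations data.frame(name, n, F, batch).
#' @param nSnps,nSvs locus counts.
#' @param svTypeWeights named sampling weights over SV types.
#' @param svLengthRange log-uniform SV length range in bp.
#' @param geneDensity,repeatDensity features per Mb.
#' @param geneLengthRange,repeatLengthRange feature length ranges in bp.
#' @param subtelomereFrac per-end subtelomeric fraction of chromosome length.
#' @param svSubtelomereEnrichment SV placement multiplier in subtelomeres.
#' @param callerProfiles list of three \linkS4class{CallerProfile}s.
#' @param nBalancedLoci planted balanced clusters.
#' @param balancedUpstreamOfSv plant balanced cores upstream of DELs.
#' @param nDivergentLoci planted divergent SNPs.
#' @param invaderSpecificSvFrac fraction of SVs private to the invasive range.
#' @param ancestralRange uniform ancestral allele-frequency range.
#' @param invaderPops invasive population names.
#' @param divergentPair populations between which divergence is planted.
#' @param svDropoutBatch,svDropoutProb optional batch-specific SV dropout.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 7, nSnps = 500, nSvs = 50)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      chromLengths = c(5e6, 4e6, 3e6),
                      populations = data.frame(
                        name = c("UK", "NA_R", "AU_EAST", "AU_SOUTH", "MGL"),
                        n = c(8L, 8L, 15L, 15L, 3L),
                        F = c(0.03, 0.08, 0.12, 0.12, 0.35),
                        batch = c("b1", "b1", "b2", "b2", "b2"),
                        stringsAsFactors = FALSE),
                      nSnps = 5000L, nSvs = 400L,
                      svTypeWeights = c(DEL = 0.45, DUP = 0.15, INV = 0.10,
                                        INS = 0.05, TRA = 0.25),
                      svLengthRange = c(50, 20000),
                      geneDensity = 8, repeatDensity = 20,
                      geneLengthRange = c(1000, 10000),
                      repeatLengthRange = c(50, 500),
                      subtelomereFrac = 0.1,
                      svSubtelomereEnrichment = 3,
                      callerProfiles = list(
                        callerProfile("lumpyoid",
                          detectProb = c(DEL = 0.90, DUP = 0.80, INV = 0.75,
                                         INS = 0.60, TRA = 0.75),
                          posJitter = 150L, genotypeErrorRate = 0.03,
                          falsePositiveRate = 2, passFilterProb = 0.95),
                        callerProfile("dellyoid",
                          detectProb = c(DEL = 0.85, DUP = 0.75, INV = 0.80,
                                         INS = 0.50, TRA = 0.80),
                          posJitter = 100L, genotypeErrorRate = 0.05,
                          falsePositiveRate = 3, passFilterProb = 0.90),
                        callerProfile("mantoid",
                          detectProb = c(DEL = 0.90, DUP = 0.70, INV = 0.70,
                                         INS = 0.65, TRA = 0.65),
                          posJitter = 200L, genotypeErrorRate = 0.02,
                          falsePositiveRate = 1.5, passFilterProb = 0.97)),
                      nBalancedLoci = 5L, balancedUpstreamOfSv = FALSE,
                      nDivergentLoci = 20L,
                      invaderSpecificSvFrac = 0.10,
                      ancestralRange = c(0.05, 0.95),
                      invaderPops = c("AU_EAST", "AU_SOUTH", "MGL"),
                      divergentPair = c("UK", "AU_EAST"),
                      svDropoutBatch = NA_character_,
                      svDropoutProb = 0) {
  new("SimConfig", seed = as.integer(seed),
      chromLengths = as.numeric(chromLengths),
      populations = populations,
      nSnps = as.integer(nSnps), nSvs = as.integer(nSvs),
      svTypeWeights = svTypeWeights[SV_TYPES],
      svLengthRange = as.numeric(svLengthRange),
      geneDensity = geneDensity, repeatDensity = repeatDensity,
      geneLengthRange = as.numeric(geneLengthRange),
      repeatLengthRange = as.numeric(repeatLengthRange),
      subtelomereFrac = subtelomereFrac,
      svSubtelomereEnrichment = svSubtelomereEnrichment,
      callerProfiles = callerProfiles,
      nBalancedLoci = as.integer(nBalancedLoci),
      balancedUpstreamOfSv = balancedUpstreamOfSv,
      nDivergentLoci = as.integer(nDivergentLoci),
      invaderSpecificSvFrac = invaderSpecificSvFrac,
      ancestralRange = as.numeric(ancestralRange),
      invaderPops = invaderPops,
      divergentPair = divergentPair,
      svDropoutBatch = as.character(svDropoutBatch),
      svDropoutProb = svDropoutProb)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@chromLengths), "chromosomes (",
      sprintf("%.1f", sum(object@chromLengths) / 1e6), "Mb ),",
      object@nSnps, "SNPs,", object@nSvs, "SVs\n")
  cat("  populations:",
      paste(sprintf("%s(n=%d,F=%.2f)", object@populations$name,
                    object@populations$n, object@populations$F),
            collapse = " "), "\n")
  cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## MergeParams / FilterParams
## ---------------------------------------------------------------------------

#' MergeParams: consensus SV merge parameters
#'
#' The per-sample defaults encode the merge rule "1-kb maximum break-end
#' distance, 2-caller support, type and strand agreement, 30-bp minimum
#' length" with the genotype-agreement modification; the cross-sample stage
#' uses the same rule at 1-caller support without genotype agreement (see
#' \code{\link{mergeAcrossSamples}}).
#'
#' @slot maxDist maximum allowed distance between predicted break ends (bp).
#' @slot minSupport minimum number of distinct supporting callers.
#' @slot requireType,requireStrand must members agree on type / strand pair.
#' @slot minLen minimum SV length (bp); TRA break ends carry no length and
#'   are exempt.
#' @slot requireGenotypeAgreement merge within genotype partitions only.
#' @aliases MergeParams-class
#' @exportClass MergeParams
setClass("MergeParams",
  representation(maxDist = "numeric", minSupport = "integer",
                 requireType = "logical", requireStrand = "logical",
                 minLen = "numeric", requireGenotypeAgreement = "logical"))

setValidity("MergeParams", function(object) {
  msg <- character()
  if (object@maxDist <= 0) msg <- c(msg, "maxDist must be > 0")
  if (object@minSupport < 1L) msg <- c(msg, "minSupport must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname MergeParams-class
#' @param maxDist,minSupport,requireType,requireStrand,minLen,requireGenotypeAgreement
#'   see slots.
#' @return a \linkS4class{MergeParams}.
#' @export
mergeParams <- function(maxDist = 1000, minSupport = 2L, requireType = TRUE,
                        requireStrand = TRUE, minLen = 30,
                        requireGenotypeAgreement = TRUE) {
  new("MergeParams", maxDist = maxDist, minSupport = as.integer(minSupport),
      requireType = requireType, requireStrand = requireStrand,
      minLen = minLen, requireGenotypeAgreement = requireGenotypeAgreement)
}

#' FilterParams: dataset-construction filter thresholds
#'
#' Defaults reproduce the study's vcftools-convention thresholds: drop sites
#' with more than 50\% missing genotypes or minor allele frequency below
#' 0.03; prune one of each site pair with squared genotype correlation above
#' 0.6 within 1000 bp; thin to sites more than 5000 bp apart; "common"
#' variants are those with MAF strictly above 0.15.
#'
#' @slot maxMissing maximum tolerated missing fraction per site.
#' @slot minMaf minimum minor allele frequency (inclusive).
#' @slot ldR2Max maximum tolerated r-squared within the LD window.
#' @slot ldWindow LD window in bp (pairwise site distance).
#' @slot thinDistance minimum spacing for the thinned set (strict).
#' @slot commonMaf strict MAF lower bound defining "common" variants.
#' @aliases FilterParams-class
#' @exportClass FilterParams
setClass("FilterParams",
  representation(maxMissing = "numeric", minMaf = "numeric",
                 ldR2Max = "numeric", ldWindow = "numeric",
                 thinDistance = "numeric", commonMaf = "numeric"))

setValidity("FilterParams", function(object) {
  msg <- character()
  for (s in c("maxMissing", "minMaf", "commonMaf")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, paste(s, "must lie in [0, 1]"))
  }
  if (object@ldR2Max < 0 || object@ldR2Max > 1)
    msg <- c(msg, "ldR2Max must lie in [0, 1]")
  if (object@ldWindow <= 0 || object@thinDistance < 0)
    msg <- c(msg, "windows must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterParams-class
#' @param maxMissing,minMaf,ldR2Max,ldWindow,thinDistance,commonMaf see slots.
#' @return a \linkS4class{FilterParams}.
#' @export
filterParams <- function(maxMissing = 0.5, minMaf = 0.03, ldR2Max = 0.6,
                         ldWindow = 1000, thinDistance = 5000,
                         commonMaf = 0.15) {
  new("FilterParams", maxMissing = maxMissing, minMaf = minMaf,
      ldR2Max = ldR2Max, ldWindow = ldWindow, thinDistance = thinDistance,
      commonMaf = commonMaf)
}

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' GenotypeMatrix: sites-by-samples dosage container
#'
#' A \linkS4class{RangedSummarizedExperiment} subclass holding one assay
#' \code{"dosage"} (integer alternate-allele counts 0/1/2, \code{NA} for
#' missing), variant metadata on \code{rowRanges} (\code{type}, \code{svlen})
#' and sample metadata (\code{population}, \code{batch}) on \code{colData}.
#' SVs are treated as biallelic presence/absence alleles, exactly like SNPs,
#' so every downstream statistic applies to either variant class.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (!all(c("population", "batch") %in% colnames(colData(object))))
    msg <- c(msg, "colData needs 'population' and 'batch'")
  if (!"type" %in% colnames(mcols(rowRanges(object))))
    msg <- c(msg, "rowRanges mcols need 'type'")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix (sites x samples) of alternate-allele counts,
#'   entries 0/1/2/NA.
#' @param rowRanges \linkS4class{GRanges} of variant loci with mcols
#'   \code{type} (SNP or an SV class) and optionally \code{svlen}.
#' @param population,batch per-sample annotations (recycled if length 1).
#' @param sampleIds sample names; defaults to \code{colnames(dosage)}.
#' @return a \linkS4class{GenotypeMatrix}, rows sorted by (chrom, pos).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'                              type = "SNP")
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, NA), 2,
#'                             dimnames = list(NULL, c("s1", "s2"))),
#'                      gr, population = c("A", "B"), batch = "b1")
#' dosage(gm)
#' @export
GenotypeMatrix <- function(dosage, rowRanges, population, batch = "b1",
                           sampleIds = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(dosage)))
  colnames(dosage) <- sampleIds
  if (is.null(names(rowRanges)))
    names(rowRanges) <- sprintf("site%06d", seq_along(rowRanges))
  rownames(dosage) <- names(rowRanges)
  if (!"svlen" %in% colnames(mcols(rowRanges)))
    mcols(rowRanges)$svlen <- NA_integer_
  cd <- DataFrame(population = rep(population, length.out = ncol(dosage)),
                  batch = rep(batch, length.out = ncol(dosage)),
                  row.names = sampleIds)
  se <- SummarizedExperiment(assays = SimpleList(dosage = dosage),
                             rowRanges = rowRanges, colData = cd)
  ord <- order(as.factor(seqnames(rowRanges)), start(rowRanges))
  new("GenotypeMatrix", se[ord, ])
}

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dosage(object)
  cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
  tt <- table(variantType(object))
  cat("  types:", paste(names(tt), tt, sep = "=", collapse = " "), "\n")
  cat("  populations:",
      paste(names(table(colData(object)$population)),
            table(colData(object)$population), sep = "=", collapse = " "), "\n")
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(d))))
})

#' @rdname GenotypeMatrix
#' @param x a GenotypeMatrix.
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @rdname GenotypeMatrix
#' @export
variantType <- function(x) mcols(rowRanges(x))$type

#' @rdname GenotypeMatrix
#' @export
samplePopulation <- function(x) as.character(colData(x)$population)

#' @rdname GenotypeMatrix
#' @export
sampleBatch <- function(x) as.character(colData(x)$batch)

## ---------------------------------------------------------------------------
## TruthSet
## ---------------------------------------------------------------------------

#' TruthSet: simulated ground truth
#'
#' True SNP and SV genotypes plus the generative per-population allele
#' frequencies and the labels of planted loci (balanced clusters, divergent
#' loci, invader-specific SVs).
#'
#' @slot snp,sv \linkS4class{GenotypeMatrix} of true genotypes.
#' @slot snpFreq,svFreq loci x populations matrices of the Balding-Nichols
#'   population allele frequencies that generated the genotypes.
#' @slot balancedCore integer row indices (into \code{snp}) of planted
#'   balanced-cluster core SNPs.
#' @slot balancedCompanions list of integer vectors, companion SNPs per core.
#' @slot divergentLoci integer row indices of planted divergent SNPs.
#' @slot invaderSpecificSv integer row indices (into \code{sv}) of SVs
#'   private to the invasive range.
#' @slot config the generating \linkS4class{SimConfig}.
#' @aliases TruthSet-class
#' @exportClass TruthSet
setClass("TruthSet",
  representation(snp = "GenotypeMatrix", sv = "GenotypeMatrix",
                 snpFreq = "matrix", svFreq = "matrix",
                 balancedCore = "integer", balancedCompanions = "list",
                 divergentLoci = "integer", invaderSpecificSv = "integer",
                 config = "SimConfig"))

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@snp), "SNPs,", nrow(object@sv), "SVs,",
      ncol(object@snp), "samples\n")
  cat("  planted: ", length(object@balancedCore), " balanced clusters, ",
      length(object@divergentLoci), " divergent loci, ",
      length(object@invaderSpecificSv), " invader-specific SVs\n", sep = "")
})

#' @rdname TruthSet-class
#' @param x a TruthSet.
#' @export
truthSnp <- function(x) x@snp

#' @rdname TruthSet-class
#' @export
truthSv <- function(x) x@sv
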