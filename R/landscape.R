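#' @importFrom stats glm quasipoisson residuals coef kruskal.test wilcox.test
#'   quantile median p.adjust pchisq pnorm var cor
NULL

#' Windowed SNP and SV counts
#'
#' Tiles every chromosome with fixed bins (default 1 Mb, last bin
#' truncated).  SNPs are counted by position; SVs are counted in every bin
#' their interval overlaps (coverage semantics), so a spanning SV can
#' contribute to several bins; TRA and INS records occupy a single
#' coordinate.  A \code{countMode = "start"} alternative counts SVs at their
#' start position only.
#'
#' @param snp SNP loci (\linkS4class{GRanges} or \linkS4class{GenotypeMatrix}).
#' @param sv SV records (\linkS4class{GRanges} or \linkS4class{GenotypeMatrix}).
#' @param binSize bin width in bp.
#' @param seqinfo genome \linkS4class{Seqinfo} (default: from \code{snp}).
#' @param countMode \code{"coverage"} or \code{"start"}.
#' @return \linkS4class{GRanges} of bins with mcols \code{snpCount},
#'   \code{svCount}.
#' @export
binCounts <- function(snp, sv, binSize = 1e6, seqinfo = NULL,
                      countMode = c("coverage", "start")) {
  countMode <- match.arg(countMode)
  if (is(snp, "GenotypeMatrix")) snp <- rowRanges(snp)
  if (is(sv, "GenotypeMatrix")) sv <- rowRanges(sv)
  if (is.null(seqinfo)) seqinfo <- seqinfo(snp)
  bins <- GenomicRanges::tileGenome(seqlengths(seqinfo),
                                    tilewidth = binSize,
                                    cut.last.tile.in.chrom = TRUE)
  snpPos <- GRanges(seqnames(snp), IRanges(start(snp), width = 1L))
  svQ <- if (countMode == "start")
    GRanges(seqnames(sv), IRanges(start(sv), width = 1L)) else sv
  mcols(bins)$snpCount <- countOverlaps(bins, snpPos, ignore.strand = TRUE)
  mcols(bins)$svCount <- countOverlaps(bins, svQ, ignore.strand = TRUE)
  bins
}

#' Quasi-Poisson regression of SV density on SNP density
#'
#' Fits \code{svCount ~ snpCount} with \code{glm(family = quasipoisson)}
#' (log link; point estimates equal the Poisson fit, standard errors scaled
#' by the Pearson-dispersion estimate) and retains per-window residuals.
#'
#' @param windows output of \code{\link{binCounts}}.
#' @param residualType deviance (default) or Pearson residuals.
#' @return list with \code{model}, \code{slope}, \code{intercept},
#'   \code{tValue} (slope / quasi-SE), \code{dispersion}, \code{fitted} and
#'   \code{residuals} (parallel to \code{windows}).
#' @export
densityRegression <- function(windows,
                              residualType = c("deviance", "pearson")) {
  residualType <- match.arg(residualType)
  df <- data.frame(sv = mcols(windows)$svCount,
                   snp = mcols(windows)$snpCount)
  if (nrow(df) < 10L)
    warning("fewer than 10 windows; the regression is poorly constrained")
  fit <- suppressWarnings(glm(sv ~ snp, family = quasipoisson(), data = df))
  sm <- suppressWarnings(summary(fit))
  tVal <- if ("snp" %in% rownames(sm$coefficients))
    unname(sm$coefficients["snp", "t value"]) else NA_real_
  list(model = fit,
       slope = unname(coef(fit)["snp"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       tValue = tVal,
       dispersion = sm$dispersion,
       fitted = unname(fitted(fit)),
       residuals = unname(residuals(fit, type = residualType)))
}

#' Subtelomeric enrichment of SV density residuals
#'
#' Compares density-regression residuals between bins overlapping the
#' subtelomeric windows (the first and last \code{subtelomereFrac} of each
#' chromosome) and interior bins, with a Wilcoxon rank-sum test.
#'
#' @param windows output of \code{\link{binCounts}}.
#' @param residuals residual vector from \code{\link{densityRegression}}.
#' @param subtelomereFrac per-end subtelomeric fraction.
#' @return list with per-class means, their difference, the rank-sum
#'   p-value and the bin classification; \code{NULL} (with a message) when
#'   either class has fewer than 2 bins.
#' @export
subtelomereEnrichment <- function(windows, residuals, subtelomereFrac = 0.1) {
  si <- seqinfo(windows)
  L <- as.numeric(seqlengths(si))
  s <- floor(subtelomereFrac * L)
  keep <- s >= 1
  subGr <- GRanges(rep(seqnames(si)[keep], 2L),
                   IRanges(start = c(rep(1, sum(keep)), (L - s + 1)[keep]),
                           end = c(s[keep], L[keep])))
  isSub <- countOverlaps(windows, subGr, ignore.strand = TRUE) > 0L
  if (sum(isSub) < 2L || sum(!isSub) < 2L) {
    message("fewer than 2 bins in one class; enrichment summary omitted")
    return(NULL)
  }
  wt <- suppressWarnings(wilcox.test(residuals[isSub], residuals[!isSub]))
  list(meanSubtelomeric = mean(residuals[isSub]),
       meanInterior = mean(residuals[!isSub]),
       difference = mean(residuals[isSub]) - mean(residuals[!isSub]),
       pValue = wt$p.value,
       subtelomeric = isSub)
}

#' Gene overlap by variant size class
#'
#' Size classes: \code{1bp} (SNPs), then SV lengths [30,100), [100,1k),
#' [1k,10k) and >= 10k bp.  TRA break ends have undefined size and are
#' reported as their own class.  Per class, the proportion of variants
#' whose genomic interval overlaps 0, 1, or >= 2 whole gene spans.
#'
#' @param records variant \linkS4class{GRanges} (mcols \code{type},
#'   \code{svlen}).
#' @param genes gene \linkS4class{GRanges}.
#' @param breaks SV size-class boundaries.
#' @return data.frame(sizeClass, n, p0, p1, p2plus); empty classes omitted.
#' @export
overlapBySizeClass <- function(records, genes,
                               breaks = c(30, 100, 1000, 10000, Inf)) {
  type <- mcols(records)$type
  svlen <- mcols(records)$svlen
  labs <- c("[30,100)", "[100,1k)", "[1k,10k)", ">=10k")
  cls <- rep(NA_character_, length(records))
  cls[type == "SNP"] <- "1bp"
  cls[type == "TRA"] <- "TRA"
  svSel <- !(type %in% c("SNP", "TRA"))
  cls[svSel] <- labs[findInterval(svlen[svSel], breaks,
                                  rightmost.closed = FALSE)]
  nGenes <- countOverlaps(records, genes, ignore.strand = TRUE)
  cat3 <- cut(nGenes, c(-1, 0, 1, Inf), labels = c("0", "1", "2+"))
  out <- list()
  for (cl in c("1bp", labs, "TRA")) {
    sel <- which(cls == cl)
    if (!length(sel)) next
    tt <- table(cat3[sel]) / length(sel)
    out[[length(out) + 1L]] <- data.frame(
      sizeClass = cl, n = length(sel),
      p0 = unname(tt["0"]), p1 = unname(tt["1"]),
      p2plus = unname(tt["2+"]))
  }
  do.call(rbind, out)
}

#' Classify SV break ends by repeat-annotation overlap
#'
#' The 30-bp window starting at each SV's first break end (truncated at the
#' chromosome end) is intersected with the repeat annotation; when at least
#' 1 bp overlaps, the SV takes the class of the repeat interval with the
#' largest overlap, otherwise \code{"none"}.  This replaces a homology
#' search with annotation overlap: the repeat track is treated as ground
#' truth and the 30-bp first-break-end rule is what is exercised.
#'
#' @param svRecords SV \linkS4class{GRanges}.
#' @param repeats repeat \linkS4class{GRanges} with mcols
#'   \code{repeat_class}.
#' @param windowBp window length from the first break end.
#' @return list with \code{classes} (data.frame: sv, class,
#'   matchedInterval, overlapBp) and \code{repeatFraction} (share of SVs
#'   with any repeat hit).
#' @export
classifyBreakends <- function(svRecords, repeats, windowBp = 30L) {
  L <- as.numeric(seqlengths(seqinfo(svRecords)))[
    match(as.character(seqnames(svRecords)), seqlevels(svRecords))]
  winEnd <- pmin(start(svRecords) + windowBp - 1L, L)
  win <- GRanges(seqnames(svRecords),
                 IRanges(start(svRecords), end = winEnd))
  hits <- findOverlaps(win, repeats, ignore.strand = TRUE)
  ovl <- width(pintersect(win[S4Vectors::queryHits(hits)],
                          repeats[S4Vectors::subjectHits(hits)]))
  cls <- rep("none", length(svRecords))
  matched <- rep(NA_integer_, length(svRecords))
  bestOvl <- rep(0L, length(svRecords))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    i <- qh[k]
    ## largest overlap wins; earlier interval on ties
    if (ovl[k] > bestOvl[i]) {
      bestOvl[i] <- ovl[k]
      matched[i] <- sh[k]
      cls[i] <- mcols(repeats)$repeat_class[sh[k]]
    }
  }
  ids <- if (!is.null(names(svRecords))) names(svRecords)
         else as.character(seq_along(svRecords))
  list(classes = data.frame(sv = ids, class = cls,
                            matchedInterval = matched,
                            overlapBp = bestOvl),
       repeatFraction = mean(cls != "none"))
}

#' Per-individual heterozygosity and batch screen
#'
#' Proportion of heterozygous genotypes among non-missing sites per sample,
#' with a Kruskal-Wallis test across sequencing batches as the batch-effect
#' screen.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return list with \code{perSample} (data.frame: sample, population,
#'   batch, nSites, heterozygosity) and \code{batchTest} (htest, or NULL
#'   with fewer than 2 batches).
#' @export
individualHeterozygosity <- function(gm) {
  d <- dosage(gm)
  nOk <- colSums(!is.na(d))
  het <- colSums(d == 1L, na.rm = TRUE) / nOk
  het[nOk == 0L] <- NA_real_
  perSample <- data.frame(sample = colnames(d),
                          population = samplePopulation(gm),
                          batch = sampleBatch(gm),
                          nSites = nOk, heterozygosity = het,
                          row.names = NULL)
  batch <- factor(perSample$batch)
  ok <- !is.na(perSample$heterozygosity)
  test <- if (nlevels(droplevels(batch[ok])) >= 2L)
    kruskal.test(perSample$heterozygosity[ok], droplevels(batch[ok]))
  else NULL
  list(perSample = perSample, batchTest = test)
}
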