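#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @importFrom stats rbeta rbinom rpois runif setNames
NULL

REPEAT_CLASSES <- c("Simple_repeat", "Low_complexity", "LINE", "LTR",
                    "Unclassified")
STRAND_BY_TYPE <- c(DEL = "+-", DUP = "-+", INS = "+-")

.chromNames <- function(config) paste0("chr", seq_along(config@chromLengths))

.seqinfoOf <- function(config) {
  Seqinfo(.chromNames(config), as.integer(config@chromLengths))
}

#' Subtelomeric windows of a genome
#'
#' @param config a \linkS4class{SimConfig}.
#' @return \linkS4class{GRanges} covering the first and last
#'   \code{subtelomereFrac} of each chromosome.
#' @export
subtelomereWindows <- function(config) {
  si <- .seqinfoOf(config)
  L <- as.numeric(seqlengths(si))
  s <- floor(config@subtelomereFrac * L)
  keep <- s >= 1
  gr <- GRanges(
    rep(seqnames(si)[keep], 2L),
    IRanges(start = c(rep(1, sum(keep)), (L - s + 1)[keep]),
            end = c(s[keep], L[keep])),
    seqinfo = si)
  sort(gr)
}

.placeFeatures <- function(si, densityPerMb, lengthRange, nonOverlapping) {
  chroms <- seqnames(si)
  L <- as.numeric(seqlengths(si))
  out <- GRanges(seqinfo = si)
  for (i in seq_along(chroms)) {
    n <- rpois(1L, densityPerMb * L[i] / 1e6)
    if (n == 0L) next
    len <- pmin(round(runif(n, lengthRange[1], lengthRange[2])), L[i])
    st <- floor(runif(n, 1, L[i] - len + 1))
    o <- order(st)
    st <- st[o]; len <- len[o]
    if (nonOverlapping && n > 1L) {
      keep <- logical(n); lastEnd <- 0
      for (j in seq_len(n)) {
        if (st[j] > lastEnd) { keep[j] <- TRUE; lastEnd <- st[j] + len[j] - 1 }
      }
      st <- st[keep]; len <- len[keep]
    }
    if (!length(st)) next
    gr <- GRanges(chroms[i], IRanges(start = st, width = len), seqinfo = si)
    out <- c(out, gr)
  }
  out
}

#' Simulate a small annotated genome
#'
#' Generates chromosome metadata, a non-overlapping gene annotation, a
#' labelled repeat annotation and (optionally) random nucleotide sequence.
#' When \code{dir} is given, FASTA / GFF3 / BED files are written there.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param dir optional output directory for genome.fa, genes.gff3,
#'   repeats.bed.
#' @param sequence generate nucleotide sequence (needed only for FASTA
#'   output); defaults to \code{!is.null(dir)}.
#' @return a list with \code{seqinfo}, \code{genes} (GRanges with
#'   \code{gene_id}), \code{repeats} (GRanges with \code{repeat_class}),
#'   \code{sequence} (DNAStringSet or NULL) and \code{files}.
#' @examples
#' g <- simulateGenome(simConfig(seed = 1, chromLengths = c(2e6, 1e6)))
#' length(g$genes)
#' @export
simulateGenome <- function(config, dir = NULL, sequence = !is.null(dir)) {
  validObject(config)
  si <- .seqinfoOf(config)
  genes <- withSubstream(config@seed, "genome.genes",
    .placeFeatures(si, config@geneDensity, config@geneLengthRange, TRUE))
  if (length(genes)) {
    mcols(genes)$gene_id <- sprintf("gene%05d", seq_along(genes))
    mcols(genes)$type <- "gene"
  } else {
    mcols(genes)$gene_id <- character(0)
    mcols(genes)$type <- character(0)
  }
  repeats <- withSubstream(config@seed, "genome.repeats",
    .placeFeatures(si, config@repeatDensity, config@repeatLengthRange, FALSE))
  mcols(repeats)$repeat_class <- if (length(repeats))
    withSubstream(config@seed, "genome.repeatclass",
      sample(REPEAT_CLASSES, length(repeats), replace = TRUE,
             prob = c(0.40, 0.15, 0.20, 0.15, 0.10)))
    else character(0)
  seqs <- NULL
  if (sequence) {
    seqs <- withSubstream(config@seed, "genome.sequence", {
      DNAStringSet(setNames(vapply(as.numeric(seqlengths(si)), function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1)), seqnames(si)))
    })
  }
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    writeXStringSet(seqs, fa)
    gff <- file.path(dir, "genes.gff3")
    rtracklayer::export(genes, gff, format = "gff3")
    bed <- file.path(dir, "repeats.bed")
    bedGr <- repeats
    mcols(bedGr)$name <- mcols(repeats)$repeat_class
    rtracklayer::export(bedGr, bed, format = "bed")
    files <- c(fasta = fa, gff3 = gff, bed = bed)
  }
  list(seqinfo = si, genes = genes, repeats = repeats, sequence = seqs,
       files = files, config = config)
}

.sampleIdsOf <- function(config) {
  p <- config@populations
  unlist(lapply(seq_len(nrow(p)), function(i)
    sprintf("%s_%02d", p$name[i], seq_len(p$n[i]))))
}

.samplePopOf <- function(config) {
  p <- config@populations
  rep(p$name, p$n)
}

## Balding-Nichols population frequency draw: Beta(p(1-F)/F, (1-p)(1-F)/F),
## degenerate at p when F = 0.
.bnDraw <- function(p, F) {
  if (F == 0) return(p)
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

## Draw variant positions, SV positions over-sampled in subtelomeres by the
## configured multiplier.
.drawPositions <- function(config, n, enrich = 1) {
  L <- config@chromLengths
  s <- floor(config@subtelomereFrac * L)
  mass <- L + (enrich - 1) * 2 * s
  chromIdx <- sample.int(length(L), n, replace = TRUE, prob = mass)
  pos <- numeric(n)
  for (i in seq_len(n)) {
    ci <- chromIdx[i]
    if (enrich > 1 && s[ci] >= 1) {
      inSub <- runif(1) < (enrich * 2 * s[ci]) / mass[ci]
      if (inSub) {
        x <- floor(runif(1, 0, 2 * s[ci]))
        pos[i] <- if (x < s[ci]) x + 1 else L[ci] - (x - s[ci])
      } else pos[i] <- floor(runif(1, s[ci] + 1, L[ci] - s[ci] + 1))
    } else pos[i] <- floor(runif(1, 1, L[ci] + 1))
  }
  data.frame(chrom = .chromNames(config)[chromIdx], pos = pos)
}

#' Simulate population-structured SNP and SV genotypes
#'
#' Ancestral allele frequencies are uniform on \code{ancestralRange}; each
#' population's frequency is a Balding-Nichols draw with its drift parameter
#' F, and genotypes are binomial(2, p_pop) per sample.  Planted structure:
#' divergent SNPs with an allele-frequency gap of at least 0.6 between the
#' \code{divergentPair} populations; balanced clusters (a core SNP at folded
#' frequency 0.4 in every population, with 12 companion SNPs within 1 kb
#' whose folded frequencies lie within 0.05 of the core); invader-specific
#' SVs with frequency 0 outside \code{invaderPops} and at least one observed
#' alternate allele inside them.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param genome output of \code{\link{simulateGenome}} (defaults to
#'   regenerating it from \code{config}).
#' @return a \linkS4class{TruthSet}.
#' @examples
#' ts <- simulatePopulationVariants(simConfig(seed = 1, nSnps = 200, nSvs = 40))
#' ts
#' @export
simulatePopulationVariants <- function(config, genome = simulateGenome(config)) {
  validObject(config)
  si <- genome$seqinfo
  pops <- config@populations
  sampleIds <- .sampleIdsOf(config)
  samplePop <- .samplePopOf(config)
  nP <- nrow(pops)

  ## ----- SV loci (drawn first: balanced clusters may target DELs) --------
  ## Distinct same-type/strand SVs are kept > 1 kb apart at both break
  ## ends: closer pairs would be indistinguishable under the 1-kb consensus
  ## merge rule, so the stated world excludes them (conflicting draws are
  ## redrawn).
  nSv <- config@nSvs
  minSep <- 1000
  svMeta <- withSubstream(config@seed, "variants.sv.pos", {
    type <- sample(SV_TYPES, nSv, replace = TRUE, prob = config@svTypeWeights)
    len <- round(exp(runif(nSv, log(config@svLengthRange[1]),
                           log(config@svLengthRange[2]))))
    strands <- ifelse(type %in% names(STRAND_BY_TYPE),
                      STRAND_BY_TYPE[type],
                      sample(c("++", "--", "+-", "-+"), nSv, replace = TRUE))
    len[type == "TRA"] <- NA_integer_
    pos <- .drawPositions(config, nSv, config@svSubtelomereEnrichment)
    chromLen <- function(ch) as.numeric(seqlengths(si))[
      match(ch, seqnames(si))]
    spansv <- type %in% c("DEL", "DUP", "INV")
    for (iter in seq_len(50L)) {
      ## clamp spanning SVs inside their chromosome
      L <- chromLen(pos$chrom)
      over <- spansv & !is.na(len) & (pos$pos + len - 1 > L)
      pos$pos[over] <- pmax(1, L[over] - len[over] + 1)
      ## find conflicts (both break ends within minSep, same type/strand)
      endv <- ifelse(spansv, pos$pos + len - 1, pos$pos)
      conflict <- rep(FALSE, nSv)
      for (grp in split(seq_len(nSv), paste(pos$chrom, type, strands))) {
        if (length(grp) < 2L) next
        g <- grp[order(pos$pos[grp])]
        for (i in 2:length(g)) {
          for (j in (i - 1):1) {
            if (pos$pos[g[i]] - pos$pos[g[j]] > minSep) break
            if (!conflict[g[j]] &&
                max(abs(pos$pos[g[i]] - pos$pos[g[j]]),
                    abs(endv[g[i]] - endv[g[j]])) <= minSep) {
              conflict[g[i]] <- TRUE
              break
            }
          }
        }
      }
      if (!any(conflict)) break
      pos[conflict, ] <- .drawPositions(config, sum(conflict),
                                        config@svSubtelomereEnrichment)
    }
    data.frame(chrom = pos$chrom, pos = pos$pos, type = type, len = len,
               strands = strands, stringsAsFactors = FALSE)
  })
  spans <- svMeta$type %in% c("DEL", "DUP", "INV")

  ## ----- SNP loci ---------------------------------------------------------
  snpCore <- withSubstream(config@seed, "variants.snp.pos",
    .drawPositions(config, config@nSnps))
  planted <- withSubstream(config@seed, "variants.planted", {
    nDiv <- config@nDivergentLoci
    div <- if (nDiv > 0) sort(sample.int(config@nSnps, nDiv)) else integer(0)
    divA <- runif(nDiv, 0.05, 0.20)
    divB <- divA + runif(nDiv, 0.60, 0.72)
    nBal <- config@nBalancedLoci
    balCore <- if (nBal > 0) sample.int(config@nSnps, nBal) else integer(0)
    comp <- lapply(seq_len(nBal), function(i) {
      k <- 12L
      offs <- sample(c(-1000:-1, 1:1000), k)
      folded <- runif(k, 0.35, 0.45)
      flip <- runif(k) < 0.5
      data.frame(off = offs, freq = ifelse(flip, 1 - folded, folded))
    })
    list(div = div, divA = divA, divB = divB, balCore = balCore, comp = comp)
  })

  snpChrom <- snpCore$chrom
  snpPos <- snpCore$pos
  labBalCore <- planted$balCore
  labDiv <- planted$div
  ## optionally relocate balanced cores into the 1-kb window upstream of
  ## deletion break ends (range-linked balancing-selection design)
  if (config@balancedUpstreamOfSv && length(labBalCore)) {
    delIdx <- which(svMeta$type == "DEL" & svMeta$pos > 1100)
    up <- withSubstream(config@seed, "variants.planted.upstream", {
      tgt <- sample(delIdx, min(length(labBalCore), length(delIdx)))
      list(tgt = tgt, off = sample(100:900, length(tgt), replace = TRUE))
    })
    ii <- seq_along(up$tgt)
    snpChrom[labBalCore[ii]] <- svMeta$chrom[up$tgt]
    snpPos[labBalCore[ii]] <- svMeta$pos[up$tgt] - up$off
  }
  ## companions appended after the core loci
  compChrom <- character(0); compPos <- numeric(0); compFreq <- numeric(0)
  compOwner <- integer(0)
  for (i in seq_along(labBalCore)) {
    ci <- labBalCore[i]
    L <- as.numeric(seqlengths(si))[match(snpChrom[ci], seqnames(si))]
    p <- pmin(pmax(snpPos[ci] + planted$comp[[i]]$off, 1), L)
    compChrom <- c(compChrom, rep(snpChrom[ci], length(p)))
    compPos <- c(compPos, p)
    compFreq <- c(compFreq, planted$comp[[i]]$freq)
    compOwner <- c(compOwner, rep(i, length(p)))
  }
  nCore <- config@nSnps
  nSnpAll <- nCore + length(compPos)

  snpFreq <- withSubstream(config@seed, "variants.snp.freq", {
    anc <- runif(nCore, config@ancestralRange[1], config@ancestralRange[2])
    fq <- matrix(0, nSnpAll, nP, dimnames = list(NULL, pops$name))
    for (j in seq_len(nP)) fq[seq_len(nCore), j] <- .bnDraw(anc, pops$F[j])
    ## planted divergent pair overrides
    a <- match(config@divergentPair[1], pops$name)
    b <- match(config@divergentPair[2], pops$name)
    fq[labDiv, a] <- planted$divA
    fq[labDiv, b] <- planted$divB
    ## balanced cores: folded frequency 0.4 everywhere
    fq[labBalCore, ] <- 0.4
    ## companions: planted frequency in every population
    if (length(compFreq))
      fq[nCore + seq_along(compFreq), ] <- matrix(compFreq, ncol = nP,
                                                  nrow = length(compFreq))
    fq
  })
  allSnpChrom <- c(snpChrom, compChrom)
  allSnpPos <- c(snpPos, compPos)
  snpGeno <- withSubstream(config@seed, "variants.snp.geno", {
    g <- matrix(0L, nSnpAll, length(sampleIds),
                dimnames = list(NULL, sampleIds))
    for (j in seq_len(nP)) {
      cols <- which(samplePop == pops$name[j])
      g[, cols] <- rbinom(nSnpAll * length(cols), 2L, snpFreq[, j])
    }
    g
  })

  ## ----- SV frequencies and genotypes -------------------------------------
  nInv <- floor(config@invaderSpecificSvFrac * nSv)
  invaderIdx <- withSubstream(config@seed, "variants.sv.invader",
    if (nInv > 0) sort(sample.int(nSv, nInv)) else integer(0))
  invaderCols <- which(samplePop %in% config@invaderPops)

  svFreq <- withSubstream(config@seed, "variants.sv.freq", {
    anc <- runif(nSv, config@ancestralRange[1], config@ancestralRange[2])
    fq <- matrix(0, nSv, nP, dimnames = list(NULL, pops$name))
    for (j in seq_len(nP)) fq[, j] <- .bnDraw(anc, pops$F[j])
    fq[invaderIdx, !(pops$name %in% config@invaderPops)] <- 0
    fq
  })
  svGeno <- withSubstream(config@seed, "variants.sv.geno", {
    g <- matrix(0L, nSv, length(sampleIds), dimnames = list(NULL, sampleIds))
    for (j in seq_len(nP)) {
      cols <- which(samplePop == pops$name[j])
      g[, cols] <- rbinom(nSv * length(cols), 2L, svFreq[, j])
    }
    ## ascertainment: a truth SV exists because it was discovered in the
    ## cohort, so condition every SV on carrying >= 1 alternate allele
    ## (invader-specific SVs are conditioned within the invasive range)
    for (i in seq_len(nSv)) {
      cols <- if (i %in% invaderIdx) invaderCols else seq_along(sampleIds)
      tries <- 0L
      while (sum(g[i, cols]) == 0L && tries < 50L) {
        for (j in seq_len(nP)) {
          pc <- intersect(cols, which(samplePop == pops$name[j]))
          if (length(pc))
            g[i, pc] <- rbinom(length(pc), 2L, svFreq[i, j])
        }
        tries <- tries + 1L
      }
      if (sum(g[i, cols]) == 0L)
        g[i, sample(cols, 1L)] <- 1L
    }
    g
  })

  ## ----- assemble ---------------------------------------------------------
  snpGr <- GRanges(allSnpChrom, IRanges(allSnpPos, width = 1L), seqinfo = si)
  mcols(snpGr)$type <- "SNP"
  mcols(snpGr)$svlen <- NA_integer_
  names(snpGr) <- sprintf("snp%06d", seq_len(nSnpAll))

  svWidth <- ifelse(spans, svMeta$len, 1L)
  svGr <- GRanges(svMeta$chrom, IRanges(svMeta$pos, width = svWidth),
                  seqinfo = si)
  mcols(svGr)$type <- svMeta$type
  mcols(svGr)$svlen <- as.integer(svMeta$len)
  mcols(svGr)$strands <- svMeta$strands
  names(svGr) <- sprintf("sv%05d", seq_len(nSv))

  ## GenotypeMatrix sorts by position; recover post-sort indices for labels
  snpOrd <- order(as.factor(seqnames(snpGr)), start(snpGr))
  svOrd <- order(as.factor(seqnames(svGr)), start(svGr))
  snpRank <- match(seq_len(nSnpAll), snpOrd)
  svRank <- match(seq_len(nSv), svOrd)

  snpGm <- GenotypeMatrix(snpGeno, snpGr, population = samplePop,
                          batch = rep(pops$batch, pops$n),
                          sampleIds = sampleIds)
  svGm <- GenotypeMatrix(svGeno, svGr, population = samplePop,
                         batch = rep(pops$batch, pops$n),
                         sampleIds = sampleIds)
  comps <- lapply(seq_along(labBalCore), function(i)
    unname(snpRank[nCore + which(compOwner == i)]))
  new("TruthSet",
      snp = snpGm, sv = svGm,
      snpFreq = snpFreq[snpOrd, , drop = FALSE],
      svFreq = svFreq[svOrd, , drop = FALSE],
      balancedCore = unname(snpRank[labBalCore]),
      balancedCompanions = comps,
      divergentLoci = sort(unname(snpRank[labDiv])),
      invaderSpecificSv = sort(unname(svRank[invaderIdx])),
      config = config)
}

GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Emulate imperfect SV callers
#'
#' Each caller independently detects each carrier call (sample genotype 0/1
#' or 1/1) of each true SV with its per-type detection probability, jitters
#' both break ends by one shared uniform offset in
#' \code{[-posJitter, posJitter]}, corrupts the genotype to a different
#' genotype with \code{genotypeErrorRate}, adds uniformly placed false
#' positives at \code{falsePositiveRate} per Mb, and assigns FILTER=PASS
#' with \code{passFilterProb} (else "LowQual").  If the config requests
#' batch-specific SV dropout, affected (sample, SV) pairs are silently
#' missed by every caller.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param profiles list of \linkS4class{CallerProfile}s (default: from the
#'   truth's config).
#' @param seed master seed (default: from the config).
#' @return nested list \code{calls[[sample]][[caller]]}, each a
#'   \linkS4class{GRanges} of calls with mcols \code{type, svlen, strands,
#'   gt, filter, caller, sample}.
#' @export
emulateCallers <- function(truth, profiles = truth@config@callerProfiles,
                           seed = truth@config@seed) {
  config <- truth@config
  sv <- truth@sv
  gr <- rowRanges(sv)
  d <- dosage(sv)
  si <- seqinfo(gr)
  genomeMb <- sum(as.numeric(seqlengths(si))) / 1e6
  sampleIds <- colnames(sv)

  drop <- matrix(FALSE, nrow(sv), ncol(sv))
  if (!is.na(config@svDropoutBatch) && config@svDropoutProb > 0) {
    cols <- which(sampleBatch(sv) == config@svDropoutBatch)
    drop[, cols] <- withSubstream(seed, "callers.dropout",
      matrix(runif(nrow(sv) * length(cols)) < config@svDropoutProb,
             nrow(sv), length(cols)))
  }

  out <- setNames(vector("list", length(sampleIds)), sampleIds)
  for (s in seq_along(sampleIds)) {
    sampleCalls <- list()
    for (prof in profiles) {
      calls <- withSubstream(seed,
                             paste0("callers.", prof@name, ".", sampleIds[s]), {
        carrier <- which(d[, s] > 0L & !drop[, s])
        det <- carrier[runif(length(carrier)) <
                         prof@detectProb[mcols(gr)$type[carrier]]]
        n <- length(det)
        g <- gr[det]
        jit <- if (prof@posJitter > 0L && n > 0L)
          sample(seq(-prof@posJitter, prof@posJitter), n, replace = TRUE)
          else integer(n)
        st <- pmax(1L, start(g) + jit)
        gt <- GT_STRINGS[d[det, s] + 1L]
        err <- runif(n) < prof@genotypeErrorRate
        if (any(err)) {
          gt[err] <- vapply(gt[err], function(x)
            sample(setdiff(GT_STRINGS, x), 1L), character(1))
        }
        ## false positives
        nFp <- rpois(1L, prof@falsePositiveRate * genomeMb)
        fpPos <- .drawPositions(config, nFp)
        fpType <- sample(SV_TYPES, nFp, replace = TRUE,
                         prob = config@svTypeWeights)
        fpLen <- round(exp(runif(nFp, log(config@svLengthRange[1]),
                                 log(config@svLengthRange[2]))))
        fpLen[fpType == "TRA"] <- NA_integer_
        fpStr <- ifelse(fpType %in% names(STRAND_BY_TYPE),
                        STRAND_BY_TYPE[fpType],
                        sample(c("++", "--", "+-", "-+"), nFp, replace = TRUE))
        fpGt <- sample(c("0/1", "1/1"), nFp, replace = TRUE)
        chrom <- c(as.character(seqnames(g)), fpPos$chrom)
        pos <- c(st, fpPos$pos)
        typ <- c(mcols(g)$type, fpType)
        len <- c(mcols(g)$svlen, as.integer(fpLen))
        strd <- c(mcols(g)$strands, fpStr)
        gts <- c(gt, fpGt)
        wid <- ifelse(typ %in% c("DEL", "DUP", "INV") & !is.na(len), len, 1L)
        Lc <- as.numeric(seqlengths(si))[match(chrom, seqnames(si))]
        pos <- pmin(pos, pmax(1, Lc - wid + 1))
        res <- GRanges(chrom, IRanges(pos, width = wid), seqinfo = si)
        mcols(res)$type <- typ
        mcols(res)$svlen <- len
        mcols(res)$strands <- strd
        mcols(res)$gt <- gts
        mcols(res)$filter <- ifelse(runif(length(res)) < prof@passFilterProb,
                                    "PASS", "LowQual")
        mcols(res)$caller <- prof@name
        mcols(res)$sample <- sampleIds[s]
        sort(res)
      })
      sampleCalls[[prof@name]] <- calls
    }
    out[[sampleIds[s]]] <- sampleCalls
  }
  out
}

#' Write the population map
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param path output TSV path (columns sample, population, batch).
#' @return the path, invisibly.
#' @export
writePopulationMap <- function(truth, path) {
  df <- data.frame(sample = colnames(truth@snp),
                   population = samplePopulation(truth@snp),
                   batch = sampleBatch(truth@snp))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-sample per-caller SV VCFs
#'
#' @param calls output of \code{\link{emulateCallers}}.
#' @param dir output directory; files are named
#'   \code{<sample>.<caller>.vcf}.
#' @return named character vector of paths.
#' @export
writeCallerVcfs <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in names(calls)) {
    for (cl in names(calls[[s]])) {
      gr <- calls[[s]][[cl]]
      path <- file.path(dir, paste0(s, ".", cl, ".vcf"))
      gt <- matrix(mcols(gr)$gt, ncol = 1, dimnames = list(NULL, s))
      writeSVVcf(gr, path, genotypes = gt, filter = mcols(gr)$filter)
      paths[paste0(s, ".", cl)] <- path
    }
  }
  paths
}
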