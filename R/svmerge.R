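## Genotype-aware consensus SV merging.
##
## Stage 1 (per sample): calls from the three callers are split by genotype
## (0/0, 0/1, 1/1); within a genotype partition, calls agreeing on type and
## strand whose break ends all lie within maxDist of each other are
## clustered, and clusters supported by >= minSupport distinct callers
## become consensus calls -- the "1000 2 1 1 0 30" rule plus the
## genotype-agreement modification.  Stage 2 (across samples): per-sample
## consensus calls are clustered by the same distance/type/strand rule at
## 1-caller support without genotype agreement ("1000 1 1 1 0 30").

.callsToDf <- function(gr, unitField) {
  df <- data.frame(
    id = if (!is.null(names(gr))) names(gr) else
      sprintf("call%05d", seq_along(gr)),
    chrom = as.character(seqnames(gr)),
    pos = start(gr),
    end = end(gr),
    type = mcols(gr)$type,
    svlen = if ("svlen" %in% colnames(mcols(gr))) mcols(gr)$svlen
            else NA_integer_,
    strands = if ("strands" %in% colnames(mcols(gr))) mcols(gr)$strands
              else NA_character_,
    gt = if ("gt" %in% colnames(mcols(gr))) mcols(gr)$gt else NA_character_,
    unit = mcols(gr)[[unitField]],
    sample = if ("sample" %in% colnames(mcols(gr))) mcols(gr)$sample
             else NA_character_,
    stringsAsFactors = FALSE)
  ## spanning types have informative second break ends
  df$hasEnd <- df$type %in% c("DEL", "DUP", "INV")
  df
}

.pairCompatible <- function(df, i, j, params) {
  if (df$chrom[i] != df$chrom[j]) return(FALSE)
  if (params@requireType && df$type[i] != df$type[j]) return(FALSE)
  if (params@requireStrand &&
      !identical(df$strands[i], df$strands[j])) return(FALSE)
  if (params@requireGenotypeAgreement &&
      !identical(df$gt[i], df$gt[j])) return(FALSE)
  if (df$unit[i] == df$unit[j]) return(FALSE)
  d <- abs(df$pos[i] - df$pos[j])
  if (df$hasEnd[i] && df$hasEnd[j])
    d <- max(d, abs(df$end[i] - df$end[j]))
  d <= params@maxDist
}

## Exact search: assign calls (in canonical order) to blocks, maximizing the
## number of calls in blocks with >= minSupport distinct units; among optima
## the lexicographically smallest assignment vector (blocks labelled by
## first appearance) is returned, which makes the result independent of
## input order.
.solveComponentExact <- function(compat, units, minSupport) {
  n <- nrow(compat)
  bestAssign <- NULL
  bestScore <- -1L
  assign <- integer(n)
  recurse <- function(i, nBlocks, blocks) {
    if (i > n) {
      sizes <- tabulate(assign, nBlocks)
      nUnits <- vapply(blocks, length, integer(1))
      score <- sum(sizes[nUnits >= minSupport])
      if (score > bestScore) {
        bestScore <<- score
        bestAssign <<- assign
      }
      return(invisible())
    }
    for (b in seq_len(nBlocks)) {
      members <- which(assign[seq_len(i - 1L)] == b)
      if (all(compat[members, i]) && !(units[i] %in% units[members])) {
        assign[i] <<- b
        nb <- blocks
        nb[[b]] <- c(nb[[b]], units[i])
        recurse(i + 1L, nBlocks, nb)
      }
    }
    assign[i] <<- nBlocks + 1L
    recurse(i + 1L, nBlocks + 1L, c(blocks, list(units[i])))
    assign[i] <<- 0L
    invisible()
  }
  recurse(1L, 0L, list())
  bestAssign
}

## Greedy earliest-block assignment: used where every call is retained
## regardless of the partition (minSupport == 1, when the exact objective is
## degenerate and earliest-block *is* the lexicographic minimum) and as a
## fallback for oversized components.
.solveComponentGreedy <- function(compat, units, minSupport) {
  n <- nrow(compat)
  assign <- integer(n)
  nBlocks <- 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (b in seq_len(nBlocks)) {
      members <- which(assign[seq_len(i - 1L)] == b)
      if (all(compat[members, i]) && !(units[i] %in% units[members])) {
        assign[i] <- b
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      nBlocks <- nBlocks + 1L
      assign[i] <- nBlocks
    }
  }
  assign
}

.mergeEngine <- function(df, params, exactLimit = 12L) {
  if (!nrow(df)) return(list())
  ## canonical order
  df <- df[order(df$chrom, df$pos, df$end, df$unit, df$id), , drop = FALSE]
  key <- paste(df$chrom,
               if (params@requireType) df$type else "",
               if (params@requireStrand) df$strands else "",
               if (params@requireGenotypeAgreement) df$gt else "",
               sep = "\r")
  clusters <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    ## gap-split: no valid block can span a position gap > maxDist
    gaps <- which(diff(sub$pos) > params@maxDist)
    compStart <- c(1L, gaps + 1L)
    compEnd <- c(gaps, nrow(sub))
    for (ci in seq_along(compStart)) {
      comp <- sub[compStart[ci]:compEnd[ci], , drop = FALSE]
      n <- nrow(comp)
      compat <- matrix(TRUE, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
        compat[i, j] <- compat[j, i] <- .pairCompatible(comp, i, j, params)
      }
      assign <- if (params@minSupport == 1L || n > exactLimit) {
        if (n > exactLimit && params@minSupport > 1L)
          warning("component of ", n,
                  " calls exceeds the exact-search limit; greedy fallback")
        .solveComponentGreedy(compat, comp$unit, params@minSupport)
      } else {
        .solveComponentExact(compat, comp$unit, params@minSupport)
      }
      for (b in seq_len(max(assign, 0L))) {
        clusters[[length(clusters) + 1L]] <-
          comp[assign == b, , drop = FALSE]
      }
    }
  }
  clusters
}

.medianLow <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

.emptyRecordDf <- function() {
  data.frame(chrom = character(0), pos = integer(0), end = integer(0),
             type = character(0), svlen = integer(0),
             strands = character(0), gt = character(0),
             support = character(0), nSupport = integer(0),
             sample = character(0), members = character(0),
             stringsAsFactors = FALSE)
}

.clusterToRecord <- function(cl) {
  if (!nrow(cl)) return(.emptyRecordDf())
  data.frame(
    chrom = cl$chrom[1],
    pos = .medianLow(cl$pos),
    end = if (cl$hasEnd[1]) .medianLow(cl$end) else NA_integer_,
    type = cl$type[1],
    svlen = if (all(is.na(cl$svlen))) NA_integer_
            else as.integer(.medianLow(cl$svlen[!is.na(cl$svlen)])),
    strands = cl$strands[1],
    gt = cl$gt[1],
    support = paste(sort(cl$unit), collapse = ","),
    nSupport = length(unique(cl$unit)),
    sample = cl$sample[1],
    members = paste(sort(cl$id), collapse = ","),
    stringsAsFactors = FALSE)
}

## Resolve the rare case where one locus survives in two genotype
## partitions (possible with jitter + false positives): keep the cluster
## with more supporting callers, then the one with the smaller coordinate.
.dedupGenotypePartitions <- function(rec, params) {
  if (nrow(rec) < 2L) return(rec)
  rec <- rec[order(rec$chrom, rec$pos, rec$end, rec$gt), , drop = FALSE]
  keep <- rep(TRUE, nrow(rec))
  for (i in seq_len(nrow(rec) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(rec)) {
      if (!keep[j]) next
      if (rec$chrom[i] != rec$chrom[j]) break
      if (rec$pos[j] - rec$pos[i] > params@maxDist) break
      if (rec$type[i] != rec$type[j]) next
      if (!identical(rec$strands[i], rec$strands[j])) next
      if (identical(rec$gt[i], rec$gt[j])) next
      d <- abs(rec$pos[i] - rec$pos[j])
      if (!is.na(rec$end[i]) && !is.na(rec$end[j]))
        d <- max(d, abs(rec$end[i] - rec$end[j]))
      if (d > params@maxDist) next
      ## conflict: same locus, different genotype
      if (rec$nSupport[j] > rec$nSupport[i] ||
          (rec$nSupport[j] == rec$nSupport[i] &&
           rec$pos[j] < rec$pos[i])) {
        keep[i] <- FALSE
        break
      } else keep[j] <- FALSE
    }
  }
  rec[keep, , drop = FALSE]
}

.recordOrder <- function(rec, lev) {
  order(match(rec$chrom, lev), rec$pos, rec$end, rec$gt, rec$members)
}

.recordsToGRanges <- function(rec, si = NULL, presorted = FALSE) {
  lev <- if (!is.null(si)) seqlevels(si) else sort(unique(rec$chrom))
  if (!presorted)
    rec <- rec[.recordOrder(rec, lev), , drop = FALSE]
  w <- ifelse(!is.na(rec$end), rec$end - rec$pos + 1L, 1L)
  gr <- GRanges(factor(rec$chrom, levels = lev),
                IRanges(rec$pos, width = w))
  if (!is.null(si)) suppressWarnings(seqinfo(gr) <- si)
  mc <- rec[, c("type", "svlen", "strands", "gt", "support", "nSupport",
                "sample", "members"), drop = FALSE]
  rownames(mc) <- NULL
  mcols(gr) <- S4Vectors::DataFrame(mc)
  gr
}

#' Per-sample genotype-aware consensus merge
#'
#' Merges one sample's calls from the three callers under the rule: maximum
#' break-end distance \code{maxDist} (default 1 kb), at least
#' \code{minSupport} (default 2) distinct callers, agreeing type and strand,
#' minimum SV length 30 bp, and -- the genotype-aware modification --
#' agreement on the sample's genotype, enforced by merging within genotype
#' partitions and concatenating the retained clusters.  Calls with missing
#' genotypes cannot enter a genotype partition and are dropped when
#' genotype agreement is required.
#'
#' @param callsets list of per-caller call \linkS4class{GRanges} (mcols
#'   \code{type, svlen, strands, gt, caller}), or a single GRanges with a
#'   \code{caller} column.
#' @param params a \linkS4class{MergeParams}.
#' @return \linkS4class{GRanges} of consensus calls with mcols \code{type,
#'   svlen, strands, gt, support, nSupport, members}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10000, 10400),
#'         width = 500), type = "DEL", svlen = 500L, strands = "+-",
#'         gt = "0/1", caller = c("a", "b"), sample = "s1")
#' mergePerSample(gr)
#' @export
mergePerSample <- function(callsets, params = mergeParams()) {
  validObject(params)
  gr <- if (is(callsets, "GRanges")) callsets
        else do.call(c, unname(callsets))
  si <- seqinfo(gr)
  df <- .callsToDf(gr, "caller")
  ## minimum SV length; TRA break ends carry no length and are exempt
  df <- df[is.na(df$svlen) | df$svlen >= params@minLen, , drop = FALSE]
  if (params@requireGenotypeAgreement)
    df <- df[df$gt %in% GT_STRINGS, , drop = FALSE]
  clusters <- .mergeEngine(df, params)
  retained <- Filter(function(cl)
    length(unique(cl$unit)) >= params@minSupport, clusters)
  if (!length(retained)) {
    rec <- .emptyRecordDf()
    return(.recordsToGRanges(rec, si))
  }
  rec <- do.call(rbind, lapply(retained, .clusterToRecord))
  if (params@requireGenotypeAgreement)
    rec <- .dedupGenotypePartitions(rec, params)
  .recordsToGRanges(rec, si)
}

#' Cross-sample consensus merge
#'
#' Combines per-sample consensus calls into a cohort call set using the same
#' distance/type/strand rule at 1-caller support, without genotype
#' agreement.  Each cohort SV carries one genotype per sample; samples
#' contributing no member call default to homozygous reference
#' (\code{absentGenotype = "0/0"}), matching the convention under which
#' site-level missingness and MAF are computed on the merged set.
#'
#' @param perSample list of \linkS4class{GRanges} from
#'   \code{\link{mergePerSample}} (each with a \code{sample} mcol).
#' @param params a \linkS4class{MergeParams}; defaults to the cross-sample
#'   rule (1-caller support, no genotype agreement).
#' @param absentGenotype genotype string for samples without a member call
#'   (\code{"0/0"} or \code{"./."}).
#' @param populationMap optional data.frame(sample, population, batch); when
#'   given, a \linkS4class{GenotypeMatrix} is returned.
#' @return \linkS4class{GRanges} with a \code{GT} matrix column (samples in
#'   \code{names(perSample)} order), or a \linkS4class{GenotypeMatrix}.
#' @export
mergeAcrossSamples <- function(perSample,
                               params = mergeParams(minSupport = 1L,
                                 requireGenotypeAgreement = FALSE),
                               absentGenotype = "0/0",
                               populationMap = NULL) {
  validObject(params)
  perSample <- as.list(perSample)
  gr <- do.call(c, unname(perSample))
  si <- seqinfo(gr)
  samples <- names(perSample)
  if (is.null(samples))
    samples <- sort(unique(mcols(gr)$sample))
  df <- .callsToDf(gr, "sample")
  df <- df[is.na(df$svlen) | df$svlen >= params@minLen, , drop = FALSE]
  clusters <- .mergeEngine(df, params)
  retained <- Filter(function(cl)
    length(unique(cl$unit)) >= params@minSupport, clusters)
  rec <- if (length(retained))
    do.call(rbind, lapply(retained, .clusterToRecord))
  else .emptyRecordDf()
  gt <- matrix(absentGenotype, nrow(rec), length(samples),
               dimnames = list(NULL, samples))
  for (i in seq_along(retained)) {
    cl <- retained[[i]]
    gt[i, cl$unit] <- cl$gt
  }
  ord <- .recordOrder(rec, seqlevels(si))
  rec <- rec[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  out <- .recordsToGRanges(rec, si, presorted = TRUE)
  names(out) <- sprintf("cohortsv%05d", seq_along(out))
  if (!is.null(populationMap)) {
    mcols(out)$GT <- gt
    return(buildGenotypeMatrix(out, populationMap))
  }
  mcols(out)$GT <- gt
  out
}

#' Brute-force consensus-merge oracle
#'
#' Independent reference implementation for small instances: enumerates
#' every set partition of the calls, keeps partitions whose blocks satisfy
#' all pairwise constraints (break-end distance, type, strand, genotype
#' where required, distinct callers), and among them returns the one
#' maximizing the number of retained calls (calls in blocks with at least
#' \code{minSupport} distinct callers), breaking ties by the
#' lexicographically smallest block assignment over position-sorted calls.
#'
#' @param calls a call \linkS4class{GRanges} (at most 10 calls).
#' @param params a \linkS4class{MergeParams}.
#' @param unitField mcols column naming the support unit (\code{"caller"}
#'   per sample, \code{"sample"} across samples).
#' @return same record layout as \code{\link{mergePerSample}}.
#' @export
bruteForceMergeOracle <- function(calls, params = mergeParams(),
                                  unitField = "caller") {
  if (length(calls) > 10L)
    stop("oracle refuses more than 10 calls")
  df <- .callsToDf(calls, unitField)
  df <- df[is.na(df$svlen) | df$svlen >= params@minLen, , drop = FALSE]
  if (params@requireGenotypeAgreement)
    df <- df[df$gt %in% GT_STRINGS, , drop = FALSE]
  df <- df[order(df$chrom, df$pos, df$end, df$unit, df$id), , drop = FALSE]
  n <- nrow(df)
  if (n == 0L) {
    rec <- .emptyRecordDf()
    return(.recordsToGRanges(rec, seqinfo(calls)))
  }
  ok <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    ok[i, j] <- ok[j, i] <- .pairCompatible(df, i, j, params)
  best <- NULL
  bestScore <- -1L
  ## enumerate restricted growth strings a[1..n], pruning blocks that
  ## violate a pairwise constraint as soon as they do
  a <- integer(n)
  enum <- function(i, m) {
    if (i > n) {
      score <- 0L
      for (b in seq_len(m)) {
        mem <- which(a == b)
        if (length(unique(df$unit[mem])) >= params@minSupport)
          score <- score + length(mem)
      }
      if (score > bestScore) {
        bestScore <<- score
        best <<- a
      }
      return(invisible())
    }
    for (b in seq_len(m + 1L)) {
      mem <- which(a[seq_len(i - 1L)] == b)
      if (length(mem) && !all(ok[mem, i])) next
      a[i] <<- b
      enum(i + 1L, max(m, b))
    }
    a[i] <<- 0L
    invisible()
  }
  enum(1L, 0L)
  retained <- list()
  for (b in seq_len(max(best))) {
    mem <- which(best == b)
    if (length(unique(df$unit[mem])) >= params@minSupport)
      retained[[length(retained) + 1L]] <- df[mem, , drop = FALSE]
  }
  rec <- if (length(retained))
    do.call(rbind, lapply(retained, .clusterToRecord))
  else .emptyRecordDf()
  if (params@requireGenotypeAgreement)
    rec <- .dedupGenotypePartitions(rec, params)
  .recordsToGRanges(rec, seqinfo(calls))
}
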