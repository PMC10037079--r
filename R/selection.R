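## Differentiation-outlier scanning with pseudo-observed-data calibration,
## the folded beta(1) balancing-selection scan, SV pseudo-beta aggregation,
## and the seven-group comparison.

#' Per-locus Weir-Cockerham F_ST
#'
#' The two-population Weir-Cockerham theta estimator from genotype counts
#' (variance components a, b, c including the heterozygote correction).
#' Monomorphic loci have an undefined estimate and return NA; negative
#' estimates are retained raw and floored at 0 only for thresholding (see
#' \code{\link{podThreshold}}).
#'
#' @param gm a \linkS4class{GenotypeMatrix}, or a dosage matrix.
#' @param groupA,groupB character vectors of sample ids (or column
#'   indices) forming the two groups.
#' @return list with per-locus \code{theta}, and the variance-component
#'   sums \code{a}, \code{abc} from which the multi-locus estimate
#'   \code{sum(a)/sum(abc)} is formed.
#' @export
fstPerLocus <- function(gm, groupA, groupB) {
  d <- if (is(gm, "GenotypeMatrix")) dosage(gm) else gm
  dA <- d[, groupA, drop = FALSE]
  dB <- d[, groupB, drop = FALSE]
  n1 <- rowSums(!is.na(dA)); n2 <- rowSums(!is.na(dB))
  p1 <- rowSums(dA, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(dB, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(dA == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(dB == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  abc <- a + b + cc
  theta <- ifelse(abc == 0 | !is.finite(abc), NA_real_, a / abc)
  bad <- n1 < 1 | n2 < 1 | pbar %in% c(0, 1)
  theta[bad] <- NA_real_
  list(theta = theta, a = a, abc = abc)
}

#' Differentiation-outlier scan with a pseudo-observed-data threshold
#'
#' Implements the empirical-threshold calibration: the multi-locus
#' Weir-Cockerham estimate of the genome-wide differentiation F-hat is fit
#' on the observed loci; \code{nPod} neutral loci are then simulated
#' (ancestral frequency resampled from the observed minor-allele-frequency
#' distribution, group frequencies via Balding-Nichols with F-hat,
#' genotypes binomial at the observed group sample sizes, monomorphic draws
#' redrawn), the per-locus statistic is computed exactly as for the
#' observed data, and the empirical \code{quantile} (default 99th
#' percentile, the "1\% threshold") of the pseudo-observed statistics
#' becomes the outlier threshold.  Observed loci whose (zero-floored)
#' statistic exceeds it are flagged.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param groupA,groupB sample ids of the two groups.
#' @param nPod number of pseudo-observed loci.
#' @param probs threshold quantile.
#' @param seed RNG seed for the pseudo-observed draws.
#' @param contrast label stored with the scan.
#' @return list with \code{stat} (raw per-locus theta), \code{threshold},
#'   \code{flagged}, \code{fHat}, \code{podStats} and \code{contrast}.
#' @export
podThreshold <- function(gm, groupA, groupB, nPod = 5000L, probs = 0.99,
                         seed = 1L, contrast = "A_vs_B") {
  obs <- fstPerLocus(gm, groupA, groupB)
  ok <- !is.na(obs$theta)
  fHat <- sum(obs$a[ok]) / sum(obs$abc[ok])
  if (!is.finite(fHat) || fHat <= 0) {
    warning("multi-locus F-hat <= 0; floored at 1e-4")
    fHat <- 1e-4
  }
  mafPool <- siteMaf(gm)
  mafPool <- mafPool[!is.nan(mafPool) & mafPool > 0]
  nA <- length(groupA); nB <- length(groupB)
  podStats <- withSubstream(seed, paste0("pod.", contrast), {
    stats <- numeric(0)
    while (length(stats) < nPod) {
      m <- ceiling((nPod - length(stats)) * 1.3) + 10L
      p0 <- sample(mafPool, m, replace = TRUE)
      pA <- .bnDraw(p0, fHat)
      pB <- .bnDraw(p0, fHat)
      gA <- matrix(rbinom(m * nA, 2L, rep(pA, nA)), nrow = m)
      gB <- matrix(rbinom(m * nB, 2L, rep(pB, nB)), nrow = m)
      st <- fstPerLocus(cbind(gA, gB), seq_len(nA), nA + seq_len(nB))$theta
      stats <- c(stats, st[!is.na(st)])
    }
    stats[seq_len(nPod)]
  })
  ## empirical threshold via the (r+1)/(n+1) order-statistic convention: a
  ## fresh neutral locus exceeds it with probability <= 1 - probs, which
  ## avoids the anti-conservative bias of interpolated tail quantiles
  k <- min(nPod, ceiling((nPod + 1) * probs))
  threshold <- sort(podStats, partial = k)[k]
  flagged <- !is.na(obs$theta) & pmax(obs$theta, 0) > threshold
  list(stat = obs$theta, threshold = threshold, flagged = flagged,
       fHat = fHat, podStats = podStats, contrast = contrast)
}

.betaConstants <- function(n, fc, p = 2) {
  ## folded-class constants for allele count n and core folded frequency fc
  ks <- seq_len(floor(n / 2))
  fk <- ks / n
  Mc <- max(abs(fk - fc))
  g <- (1 - abs(fk - fc) / Mc)^p
  cnk <- (1 / ks + 1 / (n - ks)) / (1 + as.numeric(ks == n - ks))
  list(Mc = Mc, bn = sum(g * cnk), an = sum(1 / seq_len(n - 1)))
}

#' Folded beta(1) balancing-selection scan
#'
#' For each core SNP with folded frequency f_c = k/n and minor allele
#' frequency at least \code{minMaf} (default 0.15, the false-positive
#' guard), all other polymorphic sites within \code{window} bp (default
#' 1000) contribute a similarity kernel
#' g(f) = (1 - |f - f_c| / M_c)^p with M_c the largest possible folded
#' distance from f_c, giving theta_beta = sum_i g(f_i) / b_n(f_c) with the
#' unbiasedness-enforcing normalizer
#' b_n(f_c) = sum_k g(k/n) (1/k + 1/(n-k)) / (1 + [k = n-k]); Watterson's
#' theta_W = S / a_n uses the same window.  beta(1) = theta_beta - theta_W:
#' positive values flag an excess of window SNPs at frequencies similar to
#' the core, the signature of balancing selection.  Sites fixed in the
#' focal samples are excluded; empty windows report beta = 0 with S = 0.
#'
#' @param gm a \linkS4class{GenotypeMatrix} restricted (or restrictable via
#'   \code{samples}) to the focal population.
#' @param samples optional focal sample ids.
#' @param window half-window in bp.
#' @param minMaf minimum core folded frequency (inclusive).
#' @param p kernel exponent.
#' @return data.frame(core, chrom, pos, fCore, S, thetaBeta, thetaW, beta).
#' @export
betaScan <- function(gm, samples = NULL, window = 1000, minMaf = 0.15,
                     p = 2) {
  if (!is.null(samples)) gm <- gm[, samples]
  d <- dosage(gm)
  nAllele <- 2L * rowSums(!is.na(d))
  if (max(nAllele) < 4L) stop("need at least 4 alleles in the focal set")
  j <- rowSums(d, na.rm = TRUE)
  poly <- nAllele > 0L & j > 0L & j < nAllele
  gm <- gm[poly, ]
  nAllele <- nAllele[poly]; j <- j[poly]
  folded <- pmin(j, nAllele - j) / nAllele
  chrom <- as.character(seqnames(rowRanges(gm)))
  pos <- start(rowRanges(gm))
  coreIdx <- which(folded >= minMaf & nAllele >= 4L)
  res <- vector("list", length(coreIdx))
  constCache <- new.env(parent = emptyenv())
  for (ii in seq_along(coreIdx)) {
    i <- coreIdx[ii]
    sel <- which(chrom == chrom[i] & abs(pos - pos[i]) <= window)
    sel <- setdiff(sel, i)
    S <- length(sel)
    if (S == 0L) {
      res[[ii]] <- data.frame(core = rownames(gm)[i], chrom = chrom[i],
                              pos = pos[i], fCore = folded[i], S = 0L,
                              thetaBeta = 0, thetaW = 0, beta = 0)
      next
    }
    key <- paste(nAllele[i], round(folded[i], 10))
    konst <- if (!is.null(constCache[[key]])) constCache[[key]]
             else constCache[[key]] <- .betaConstants(nAllele[i], folded[i], p)
    g <- (1 - abs(folded[sel] - folded[i]) / konst$Mc)^p
    thetaBeta <- sum(g) / konst$bn
    thetaW <- S / konst$an
    res[[ii]] <- data.frame(core = rownames(gm)[i], chrom = chrom[i],
                            pos = pos[i], fCore = folded[i], S = S,
                            thetaBeta = thetaBeta, thetaW = thetaW,
                            beta = thetaBeta - thetaW)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(core = character(0), chrom = character(0),
                      pos = integer(0), fCore = numeric(0), S = integer(0),
                      thetaBeta = numeric(0), thetaW = numeric(0),
                      beta = numeric(0))
  out
}

#' Trimmed mean with floor(0.05 k)-per-tail trimming
#'
#' The "0.1 trimming, middle 90\% data" rule: with k scores,
#' floor(0.05 k) values are discarded at each tail and the rest averaged;
#' for k < 20 no value is discarded.
#'
#' @param x numeric scores.
#' @return the trimmed mean.
#' @export
trimmedMean10 <- function(x) {
  k <- length(x)
  if (k == 0L) return(NA_real_)
  t <- floor(0.05 * k)
  x <- sort(x)
  mean(x[(t + 1):(k - t)])
}

#' Pseudo-beta(1) scores for SVs
#'
#' Collects the SNP beta(1) scores falling in the 1000-bp window upstream
#' of each SV's first break end -- positions in
#' \code{[breakend - windowBp, breakend)}, half-open, on the
#' lower-coordinate side, strand ignored -- and either summarizes them per
#' SV by the \code{\link{trimmedMean10}} rule (\code{"per_sv_trimmed"}) or
#' emits the raw collected scores tagged by SV (\code{"pooled"}).  SVs with
#' no upstream score are excluded and counted.
#'
#' @param svRecords SV \linkS4class{GRanges}.
#' @param betaScores data.frame from \code{\link{betaScan}}.
#' @param mode aggregation mode.
#' @param windowBp upstream window length.
#' @return list with \code{scores} (per_sv_trimmed: data.frame(sv, k,
#'   pseudoBeta); pooled: data.frame(sv, beta)) and \code{nExcluded}.
#' @export
pseudoBeta <- function(svRecords, betaScores,
                       mode = c("per_sv_trimmed", "pooled"),
                       windowBp = 1000) {
  mode <- match.arg(mode)
  ids <- if (!is.null(names(svRecords))) names(svRecords)
         else as.character(seq_along(svRecords))
  be <- start(svRecords)
  chrom <- as.character(seqnames(svRecords))
  perSv <- lapply(seq_along(svRecords), function(i) {
    sel <- betaScores$chrom == chrom[i] &
      betaScores$pos >= be[i] - windowBp & betaScores$pos < be[i]
    betaScores$beta[sel]
  })
  k <- lengths(perSv)
  if (mode == "per_sv_trimmed") {
    keep <- k > 0L
    scores <- data.frame(sv = ids[keep], k = k[keep],
                         pseudoBeta = vapply(perSv[keep], trimmedMean10,
                                             numeric(1)))
  } else {
    keep <- k > 0L
    scores <- data.frame(sv = rep(ids[keep], k[keep]),
                         beta = unlist(perSv[keep]))
  }
  list(scores = scores, nExcluded = sum(k == 0L))
}

#' Dunn's post hoc test on pooled ranks
#'
#' Pairwise z statistics on the pooled ranks with the tie correction, with
#' Benjamini-Hochberg adjustment by default.
#'
#' @param values numeric vector.
#' @param groups factor of group labels.
#' @param method \code{stats::p.adjust} method.
#' @return data.frame(group1, group2, z, p, pAdjusted).
#' @export
dunnPosthoc <- function(values, groups, method = "BH") {
  groups <- droplevels(factor(groups))
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  meanRank <- tapply(rk, groups, mean)
  ns <- table(groups)
  lv <- levels(groups)
  prs <- utils::combn(lv, 2L)
  z <- p <- numeric(ncol(prs))
  for (q in seq_len(ncol(prs))) {
    g1 <- prs[1, q]; g2 <- prs[2, q]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[g1] + 1 / ns[g2]))
    z[q] <- (meanRank[g1] - meanRank[g2]) / se
    p[q] <- 2 * pnorm(-abs(z[q]))
  }
  data.frame(group1 = prs[1, ], group2 = prs[2, ], z = z, p = p,
             pAdjusted = p.adjust(p, method = method))
}

#' Seven-group balancing-selection comparison
#'
#' Tests whether beta(1) scores differ across the seven groups: outlier
#' SNPs, non-outlier SNPs, outlier SVs, and non-outlier DEL / DUP / TRA /
#' INV (outlier SVs are not split by type; variant classes with fewer than
#' 2 scored members are dropped with a warning, mirroring the removal of a
#' singleton class).  Kruskal-Wallis with tie correction, then Dunn's
#' pairwise z tests with Benjamini-Hochberg adjustment.
#'
#' @param snpScores data.frame with column \code{beta} (one row per scored
#'   SNP) -- e.g. \code{\link{betaScan}} output.
#' @param snpOutlier logical, parallel to \code{snpScores}.
#' @param svScores data.frame with the SV score column (\code{pseudoBeta}
#'   or pooled \code{beta}) and column \code{sv}.
#' @param svOutlier named logical (by SV id).
#' @param svType named character (by SV id).
#' @param adjustMethod Dunn adjustment method.
#' @return list with \code{groupSummary} (n, mean, se per group),
#'   \code{kruskal} (htest), \code{dunn} (data.frame) and the per-value
#'   \code{data}.
#' @export
sevenGroupTest <- function(snpScores, snpOutlier, svScores, svOutlier,
                           svType, adjustMethod = "BH") {
  scoreCol <- if ("pseudoBeta" %in% names(svScores)) "pseudoBeta" else "beta"
  svOut <- svOutlier[svScores$sv]
  svTy <- svType[svScores$sv]
  ## INS is not part of the seven-group design (outlier SVs are not split
  ## by type; non-outlier SVs are split into DEL/DUP/TRA/INV only)
  keepSv <- svTy %in% c("DEL", "DUP", "TRA", "INV")
  svScores <- svScores[keepSv, , drop = FALSE]
  svOut <- svOut[keepSv]; svTy <- svTy[keepSv]
  svGroup <- ifelse(svOut, "SV_outlier",
                    paste0(svTy, "_nonoutlier"))
  df <- rbind(
    data.frame(value = snpScores$beta,
               group = ifelse(snpOutlier, "SNP_outlier", "SNP_nonoutlier")),
    data.frame(value = svScores[[scoreCol]], group = svGroup))
  tab <- table(df$group)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("group(s) with < 2 members dropped: ",
            paste(small, collapse = ", "))
    df <- df[!(df$group %in% small), , drop = FALSE]
  }
  df$group <- droplevels(factor(df$group))
  if (nlevels(df$group) < 2L)
    stop("fewer than 2 groups remain; comparison refused")
  kw <- kruskal.test(df$value, df$group)
  if (length(unique(df$value)) == 1L) {
    ## every observation tied: H is 0 by convention (kruskal.test's tie
    ## correction is 0/0 here)
    kw$statistic[] <- 0
    kw$p.value <- 1
  }
  dunn <- dunnPosthoc(df$value, df$group, method = adjustMethod)
  gs <- do.call(rbind, lapply(levels(df$group), function(g) {
    v <- df$value[df$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))
  }))
  list(groupSummary = gs, kruskal = kw, dunn = dunn, data = df)
}
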