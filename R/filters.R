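## Dataset-construction filters: site missingness / minor allele frequency,
## linkage pruning, physical thinning, and the kinship screen.  All operate
## on the GenotypeMatrix dosage assay so SNP and SV sets are handled
## identically.

#' Per-site minor allele frequency
#'
#' Computed over non-missing alleles only.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (or a dosage matrix).
#' @return numeric vector of per-site MAF (NaN for all-missing sites).
#' @export
siteMaf <- function(gm) {
  d <- if (is(gm, "GenotypeMatrix")) dosage(gm) else gm
  nAllele <- 2L * rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / nAllele
  pmin(p, 1 - p)
}

.filterLog <- function(gm, rule, removed) {
  log <- metadata(gm)$filterLog
  log <- rbind(log, data.frame(rule = rule, sitesIn = nrow(gm),
                               removed = removed,
                               sitesOut = nrow(gm) - removed))
  log
}

#' Missingness and MAF filter
#'
#' Removes sites whose missing-genotype fraction exceeds
#' \code{maxMissing} (default 0.5) and sites with minor allele frequency
#' below \code{minMaf} (default 0.03, inclusive retention at the threshold,
#' following the vcftools \code{--maf} convention).  All-missing and
#' monomorphic sites are removed by the same two rules.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param params a \linkS4class{FilterParams}.
#' @return the filtered \linkS4class{GenotypeMatrix}; cumulative per-rule
#'   removal counts are appended to \code{metadata()$filterLog}.
#' @export
filterMissingMaf <- function(gm, params = filterParams()) {
  d <- dosage(gm)
  missFrac <- rowMeans(is.na(d))
  keep1 <- missFrac <= params@maxMissing
  log <- .filterLog(gm, "missingness", sum(!keep1))
  gm <- gm[keep1, ]
  maf <- siteMaf(gm)
  keep2 <- !is.nan(maf) & maf >= params@minMaf
  log <- rbind(log, data.frame(rule = "maf", sitesIn = nrow(gm),
                               removed = sum(!keep2),
                               sitesOut = sum(keep2)))
  gm <- gm[keep2, ]
  metadata(gm)$filterLog <- log
  gm
}

.siteR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  vx <- stats::var(x[ok]); vy <- stats::var(y[ok])
  if (vx == 0 || vy == 0) return(0)  # r2 undefined at a zero-variance site
  stats::cor(x[ok], y[ok])^2
}

#' Linkage pruning
#'
#' Scans sites in position order per chromosome; for every pair of retained
#' sites within \code{ldWindow} bp (pairwise site distance, default 1000),
#' the squared Pearson correlation of genotype dosages (composite genotype
#' r-squared, over samples non-missing at both sites) is computed, and the
#' later site is removed when it exceeds \code{ldR2Max} (default 0.6);
#' first-retained-wins.
#'
#' @inheritParams filterMissingMaf
#' @return the pruned \linkS4class{GenotypeMatrix}.
#' @export
ldPrune <- function(gm, params = filterParams()) {
  d <- dosage(gm)
  chrom <- as.character(seqnames(rowRanges(gm)))
  pos <- start(rowRanges(gm))
  keep <- rep(TRUE, nrow(d))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)   # already position-sorted
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (!keep[i]) next
      b <- a + 1L
      while (b <= length(idx) && pos[idx[b]] - pos[i] <= params@ldWindow) {
        j <- idx[b]
        if (keep[j] && .siteR2(d[i, ], d[j, ]) > params@ldR2Max)
          keep[j] <- FALSE
        b <- b + 1L
      }
    }
  }
  log <- .filterLog(gm, "ld_prune", sum(!keep))
  gm <- gm[keep, ]
  metadata(gm)$filterLog <- log
  gm
}

#' Physical thinning
#'
#' Greedy scan per chromosome keeping a site only if it lies strictly more
#' than \code{thinDistance} bp (default 5000) after the last kept site.
#'
#' @inheritParams filterMissingMaf
#' @param thinDistance override of the params slot.
#' @return the thinned \linkS4class{GenotypeMatrix}.
#' @export
thinSites <- function(gm, params = filterParams(),
                      thinDistance = params@thinDistance) {
  chrom <- as.character(seqnames(rowRanges(gm)))
  pos <- start(rowRanges(gm))
  keep <- rep(FALSE, nrow(gm))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (pos[i] - last > thinDistance) {
        keep[i] <- TRUE
        last <- pos[i]
      }
    }
  }
  log <- .filterLog(gm, "thin", sum(!keep))
  gm <- gm[keep, ]
  metadata(gm)$filterLog <- log
  gm
}

#' KING-robust kinship screen
#'
#' For each sample pair, phi = (N_het,het - 2 N_opp_hom) /
#' (N_het,i + N_het,j) over sites non-missing in both samples, where
#' N_het,het counts sites heterozygous in both and N_opp_hom counts
#' opposite homozygotes.  A self-pair (or duplicate) gives phi = 0.5;
#' full siblings and parent-offspring pairs are near 0.25, the
#' no-full-siblings screening threshold.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (ideally >= 100 sites).
#' @param threshold flag pairs with phi at or above this value.
#' @return data.frame(sample1, sample2, nSites, kinship, flagged), one row
#'   per unordered pair; kinship is NA when the denominator is zero.
#' @export
relatednessCheck <- function(gm, threshold = 0.25) {
  d <- dosage(gm)
  n <- ncol(d)
  res <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      x <- d[ok, i]; y <- d[ok, j]
      hetHet <- sum(x == 1L & y == 1L)
      oppHom <- sum((x == 0L & y == 2L) | (x == 2L & y == 0L))
      den <- sum(x == 1L) + sum(y == 1L)
      phi <- if (den == 0L) NA_real_ else (hetHet - 2 * oppHom) / den
      res[[length(res) + 1L]] <- data.frame(
        sample1 = colnames(d)[i], sample2 = colnames(d)[j],
        nSites = sum(ok), kinship = phi,
        flagged = !is.na(phi) && phi >= threshold)
    }
  }
  do.call(rbind, res)
}

#' Cumulative filter ledger of a GenotypeMatrix
#'
#' @param gm a \linkS4class{GenotypeMatrix} that has passed through filters.
#' @return data.frame(rule, sitesIn, removed, sitesOut), one row per applied
#'   rule, with input = output + removed per stage.
#' @export
filterLog <- function(gm) {
  log <- metadata(gm)$filterLog
  if (is.null(log))
    data.frame(rule = character(0), sitesIn = integer(0),
               removed = integer(0), sitesOut = integer(0))
  else log
}
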