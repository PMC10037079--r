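## Shared fixtures and independent oracles.  Everything is generated in
## code; no stored data.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## Construct a call GRanges the way the caller emulator would emit it.
makeCalls <- function(pos, caller, gt = "0/1", type = "DEL", svlen = 500L,
                      strands = "+-", sample = "s1", chrom = "chr1",
                      seqlen = 10e6) {
  n <- length(pos)
  type <- rep(type, length.out = n)
  svlen <- rep(as.integer(svlen), length.out = n)
  w <- ifelse(type %in% c("DEL", "DUP", "INV") & !is.na(svlen), svlen, 1L)
  gr <- GRanges(rep(chrom, length.out = n), IRanges(pos, width = w),
                seqinfo = GenomeInfoDb::Seqinfo("chr1", seqlen))
  mcols(gr)$type <- type
  mcols(gr)$svlen <- svlen
  mcols(gr)$strands <- rep(strands, length.out = n)
  mcols(gr)$gt <- rep(gt, length.out = n)
  mcols(gr)$caller <- rep(caller, length.out = n)
  mcols(gr)$sample <- rep(sample, length.out = n)
  names(gr) <- sprintf("c%03d", seq_len(n))
  gr
}

## Random small merge instance (for oracle-equivalence checks).
randMergeInstance <- function(seed, maxN = 8L, posRange = 4000L) {
  set.seed(seed)
  n <- sample(2:maxN, 1L)
  makeCalls(pos = sample(seq_len(posRange), n, replace = TRUE),
            caller = sample(c("a", "b", "c"), n, replace = TRUE),
            gt = sample(c("0/1", "1/1", "0/0"), n, replace = TRUE,
                        prob = c(.6, .3, .1)),
            type = sample(c("DEL", "DUP"), n, replace = TRUE,
                          prob = c(.8, .2)),
            svlen = sample(c(25L, 100L, 500L), n, replace = TRUE,
                           prob = c(.1, .5, .4)),
            strands = sample(c("+-", "-+"), n, replace = TRUE,
                             prob = c(.9, .1)))
}

## Canonical comparable form of a merge result.
mergeResultDf <- function(gr) {
  df <- data.frame(pos = start(gr), type = mcols(gr)$type,
                   gt = mcols(gr)$gt, support = mcols(gr)$support,
                   members = mcols(gr)$members)
  df <- df[order(df$pos, df$type, df$gt, df$members), ]
  rownames(df) <- NULL
  df
}

## Build a GenotypeMatrix from a dosage matrix and positions.
makeGm <- function(d, pos = seq_len(nrow(d)) * 100L, chrom = "chr1",
                   population = "A", batch = "b1", type = "SNP",
                   svlen = NA_integer_, seqlen = max(pos) + 1e6) {
  d <- as.matrix(d)
  if (is.null(colnames(d))) colnames(d) <- paste0("s", seq_len(ncol(d)))
  gr <- GRanges(rep(chrom, length.out = nrow(d)),
                IRanges(pos, width = 1L),
                seqinfo = GenomeInfoDb::Seqinfo(
                  unique(rep(chrom, length.out = nrow(d))), seqlen))
  mcols(gr)$type <- rep(type, length.out = nrow(d))
  mcols(gr)$svlen <- rep(svlen, length.out = nrow(d))
  GenotypeMatrix(d, gr, population = population, batch = batch)
}

## Independent Weir-Cockerham theta for ONE locus from two dosage vectors,
## transcribed term by term from the published variance-component
## definitions (scalar, loop-free of the package's vectorized code path).
wcThetaOracle <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  r <- 2
  n_i <- c(length(gA), length(gB))
  p_i <- c(sum(gA) / (2 * n_i[1]), sum(gB) / (2 * n_i[2]))
  h_i <- c(mean(gA == 1), mean(gB == 1))
  nbar <- mean(n_i)
  CV2num <- sum(n_i^2)
  nc <- (r * nbar - CV2num / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
    (2 * nbar - 1) / (4 * nbar) * hbar)
  cterm <- hbar / 2
  if (a + b + cterm == 0) return(NA_real_)
  a / (a + b + cterm)
}

## Nucleotide diversity of one site by exhaustive pairwise-difference
## enumeration over the observed alleles.
piEnumOracle <- function(g) {
  g <- g[!is.na(g)]
  alleles <- unlist(lapply(g, function(x) c(rep(1L, x), rep(0L, 2 - x))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diff <- diff + (alleles[i] != alleles[j])
  diff / choose(n, 2)
}

## Tiny two-population neutral GenotypeMatrix under Balding-Nichols drift.
neutralTwoPopGm <- function(seed, nLoci = 2000L, n = 24L, F = 0.1) {
  set.seed(seed)
  p0 <- runif(nLoci, 0.05, 0.95)
  pA <- rbeta(nLoci, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  pB <- rbeta(nLoci, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  gA <- matrix(rbinom(nLoci * n, 2, rep(pA, n)), nLoci)
  gB <- matrix(rbinom(nLoci * n, 2, rep(pB, n)), nLoci)
  makeGm(cbind(gA, gB), pos = seq_len(nLoci) * 100L,
         population = rep(c("A", "B"), each = n))
}

## Dosage row with exactly j alternate alleles among nS diploid samples.
dosageRowWithAltCount <- function(j, nS) {
  g <- integer(nS)
  full <- j %/% 2L
  if (full > 0) g[seq_len(full)] <- 2L
  if (j %% 2L == 1L) g[full + 1L] <- 1L
  g
}

## A window whose folded site counts are DRAWN from the neutral folded
## expectation c_{n,k}; returns the dosage matrix rows for S sites.
neutralWindowRows <- function(S, nS) {
  n <- 2L * nS
  ks <- seq_len(n %/% 2L)
  cnk <- (1 / ks + 1 / (n - ks)) / (1 + as.numeric(ks == n - ks))
  kDraw <- sample(ks, S, replace = TRUE, prob = cnk)
  t(vapply(kDraw, dosageRowWithAltCount, integer(nS), nS = nS))
}
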