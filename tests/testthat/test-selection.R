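test_that("Weir-Cockerham theta matches an independent transcription", {
  set.seed(71)
  for (rep in 1:50) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    gA <- rbinom(n1, 2, runif(1, 0.05, 0.95))
    gB <- rbinom(n2, 2, runif(1, 0.05, 0.95))
    gm <- makeGm(matrix(c(gA, gB), nrow = 1),
                 population = rep(c("A", "B"), c(n1, n2)))
    got <- unname(fstPerLocus(gm, seq_len(n1), n1 + seq_len(n2))$theta)
    want <- wcThetaOracle(gA, gB)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-10)
  }
  ## fixed difference -> theta = 1; identical frequencies -> theta ~ 0
  gmF <- makeGm(matrix(c(rep(0L, 20), rep(2L, 20)), nrow = 1),
                population = rep(c("A", "B"), each = 20))
  expect_equal(unname(fstPerLocus(gmF, 1:20, 21:40)$theta), 1)
  set.seed(72)
  g <- rbinom(100, 2, 0.5)
  gmE <- makeGm(matrix(g, nrow = 1), population = rep(c("A", "B"), 50))
  expect_lt(abs(fstPerLocus(gmE, seq(1, 99, 2), seq(2, 100, 2))$theta), 0.1)
  ## monomorphic locus is undefined
  gmM <- makeGm(matrix(0L, 1, 20), population = rep(c("A", "B"), each = 10))
  expect_true(is.na(fstPerLocus(gmM, 1:10, 11:20)$theta))
})

test_that("the POD threshold is deterministic given the seed", {
  gm <- neutralTwoPopGm(73, nLoci = 800L, n = 12L)
  a <- colnames(gm)[1:12]; b <- colnames(gm)[13:24]
  s1 <- podThreshold(gm, a, b, nPod = 500L, seed = 5)
  s2 <- podThreshold(gm, a, b, nPod = 500L, seed = 5)
  expect_identical(s1$threshold, s2$threshold)
  expect_identical(s1$flagged, s2$flagged)
  ## a different seed moves the threshold (same data)
  s3 <- podThreshold(gm, a, b, nPod = 500L, seed = 6)
  expect_false(identical(s1$threshold, s3$threshold))
  expect_equal(length(s1$podStats), 500L)
})

test_that("beta(1) respects its edge cases and planted signal", {
  ## empty window: beta = 0 with S = 0
  gm <- makeGm(rbind(dosageRowWithAltCount(8L, 10L),
                     dosageRowWithAltCount(6L, 10L)),
               pos = c(1000L, 50000L), population = "A")
  bs <- betaScan(gm)
  expect_equal(nrow(bs), 2L)
  expect_equal(bs$S, c(0L, 0L))
  expect_equal(bs$beta, c(0, 0))
  ## fewer than 4 alleles: refuse
  expect_error(betaScan(makeGm(matrix(1L, 2, 1), population = "A")),
               "4 alleles")
  ## cores below the MAF guard are not scored
  gmLow <- makeGm(rbind(dosageRowWithAltCount(1L, 10L),
                        dosageRowWithAltCount(8L, 10L)),
                  pos = c(1000L, 1500L), population = "A")
  bsLow <- betaScan(gmLow)
  expect_equal(nrow(bsLow), 1L)
  expect_equal(bsLow$fCore, 0.4)
  ## a window of SNPs at the core's folded frequency scores higher than a
  ## window spread over the folded spectrum
  similar <- t(vapply(rep(8L, 20), dosageRowWithAltCount, integer(10),
                      nS = 10L))
  spread <- t(vapply(rep(c(1L, 3L, 10L, 16L, 19L), 4),
                     dosageRowWithAltCount, integer(10), nS = 10L))
  gmSim <- makeGm(rbind(dosageRowWithAltCount(8L, 10L), similar),
                  pos = c(1000L, 1000L + seq_len(20) * 40L),
                  population = "A")
  gmSpr <- makeGm(rbind(dosageRowWithAltCount(8L, 10L), spread),
                  pos = c(1000L, 1000L + seq_len(20) * 40L),
                  population = "A")
  bSim <- betaScan(gmSim); bSpr <- betaScan(gmSpr)
  expect_gt(bSim$beta[bSim$pos == 1000], bSpr$beta[bSpr$pos == 1000])
  expect_gt(bSim$beta[bSim$pos == 1000], 0)
})

test_that("pseudo-beta windows are half-open upstream of the break end", {
  sv <- GRanges("chr1", IRanges(10000, width = 500))
  names(sv) <- "sv1"
  mkScores <- function(pos) data.frame(chrom = "chr1", pos = pos,
                                       beta = seq_along(pos))
  ## exactly at breakend - 1000: included; at the break end: excluded
  inWin <- pseudoBeta(sv, mkScores(c(9000, 9999)))
  expect_equal(inWin$scores$k, 2L)
  outWin <- pseudoBeta(sv, mkScores(c(8999, 10000, 10100)))
  expect_equal(nrow(outWin$scores), 0L)
  expect_equal(outWin$nExcluded, 1L)
  ## pooled mode returns the raw tagged scores
  pooled <- pseudoBeta(sv, mkScores(c(9000, 9500, 9999)), mode = "pooled")
  expect_equal(pooled$scores$beta, 1:3)
  expect_equal(pooled$scores$sv, rep("sv1", 3))
})

test_that("the trimmed mean follows the floor(0.05 k) rule", {
  x10 <- c(0:8, 100)
  expect_equal(trimmedMean10(x10), 13.6)          # k=10: no trimming
  expect_equal(trimmedMean10(rep(x10, 2)), mean(sort(rep(x10, 2))[2:19]))
  expect_equal(trimmedMean10(5), 5)               # k=1
  expect_equal(trimmedMean10(rep(3.5, 7)), 3.5)   # constants are unchanged
  x100 <- rnorm(100)
  expect_equal(trimmedMean10(x100), mean(sort(x100)[6:95]))
})

test_that("the seven-group comparison partitions and tests correctly", {
  set.seed(74)
  snpScores <- data.frame(beta = rnorm(200))
  snpOut <- rep(c(TRUE, FALSE), 100)
  svIds <- sprintf("sv%03d", 1:80)
  svScores <- data.frame(sv = svIds, pseudoBeta = rnorm(80))
  svOut <- setNames(rep(c(TRUE, FALSE), c(10, 70)), svIds)
  svTy <- setNames(rep(c("DEL", "DUP", "TRA", "INV", "INS"), 16), svIds)
  res <- sevenGroupTest(snpScores, snpOut, svScores, svOut, svTy)
  ## INS never forms a group; seven groups remain
  expect_equal(sort(res$groupSummary$group),
               sort(c("SNP_outlier", "SNP_nonoutlier", "SV_outlier",
                      "DEL_nonoutlier", "DUP_nonoutlier", "TRA_nonoutlier",
                      "INV_nonoutlier")))
  expect_equal(unname(res$kruskal$parameter), 6)
  expect_equal(nrow(res$dunn), choose(7, 2))
  ## a strongly shifted group is detected
  svScores2 <- svScores
  svScores2$pseudoBeta[svTy[svIds] == "DEL" & !svOut[svIds]] <- rnorm(14) + 5
  res2 <- sevenGroupTest(snpScores, snpOut, svScores2, svOut, svTy)
  expect_lt(res2$kruskal$p.value, 1e-6)
  delDunn <- res2$dunn[res2$dunn$group1 == "DEL_nonoutlier" |
                       res2$dunn$group2 == "DEL_nonoutlier", ]
  expect_true(any(delDunn$pAdjusted < 0.01))
  ## identical constant groups: H = 0 (all ties)
  kw0 <- sevenGroupTest(data.frame(beta = rep(1, 10)),
                        rep(c(TRUE, FALSE), 5),
                        data.frame(sv = svIds[1:4],
                                   pseudoBeta = rep(1, 4)),
                        svOut[1:4], svTy[1:4])
  expect_equal(unname(kw0$kruskal$statistic), 0)
  ## fewer than 2 groups left: refuse
  expect_error(suppressWarnings(sevenGroupTest(
    data.frame(beta = rnorm(5)), rep(FALSE, 5),
    data.frame(sv = character(0), pseudoBeta = numeric(0)),
    logical(0), character(0))), "2 groups")
})
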