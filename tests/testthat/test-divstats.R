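test_that("per-site diversity matches formula arithmetic and enumeration", {
  ## n = 4 alleles, j = 2 -> pi = 2*2*(4-2)/(4*3) = 2/3, confirmed by
  ## enumerating the 6 allele pairs of {1,1,0,0} (4 differ)
  gm <- makeGm(matrix(c(1L, 1L), nrow = 1), population = "A")
  tab <- diversityTable(gm)
  expect_equal(tab$pi, 2 / 3)
  expect_equal(tab$pi, piEnumOracle(c(1L, 1L)))
  expect_equal(tab$hO, 1)
  expect_equal(tab$hE, 0.5)
  ## monomorphic site: all three statistics zero
  tab0 <- diversityTable(makeGm(matrix(0L, 1, 4), population = "A"))
  expect_equal(c(tab0$hO, tab0$hE, tab0$pi), c(0, 0, 0))
  ## random sites: pi agrees with exhaustive pairwise enumeration
  set.seed(61)
  for (rep in 1:20) {
    g <- rbinom(6, 2, runif(1, 0.1, 0.9))
    g[sample(6, sample(0:2, 1))] <- NA
    if (sum(!is.na(g)) < 2) next
    tab <- diversityTable(makeGm(matrix(g, nrow = 1), population = "A"))
    expect_equal(tab$pi, piEnumOracle(g))
  }
})

test_that("pi equals H_E * n/(n-1) site by site", {
  set.seed(62)
  d <- matrix(rbinom(200 * 10, 2, runif(200, 0.05, 0.95)), 200)
  gm <- makeGm(d, population = "A")
  s <- SVPopGen:::.popSiteStats(dosage(gm))
  ok <- s$nAllele > 1
  expect_equal(s$pi[ok], s$hE[ok] * s$nAllele[ok] / (s$nAllele[ok] - 1))
})

test_that("private alleles are consistent and disjoint across populations", {
  ## site1: alt only in A; site2: alt in both; site3: ref absent in B
  d <- rbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L), c(0L, 1L, 2L, 2L))
  gm <- makeGm(d, population = c("A", "A", "B", "B"))
  tab <- diversityTable(gm)
  ## A: private alt at site1; private ref at site3 (B has none at site3? B
  ## genotypes 2,2 -> no ref allele in B; A has ref) -> 2 private for A
  expect_equal(tab$privateAlleles[tab$population == "A"], 2)
  expect_equal(tab$privateAlleles[tab$population == "B"], 0)
})

test_that("bottleneck depresses diversity by the drift expectation", {
  cfg <- simConfig(seed = 63, chromLengths = 2e6, nSnps = 3000L, nSvs = 10L,
    populations = data.frame(name = c("SRC", "BOT"), n = c(12L, 12L),
                             F = c(0.01, 0.3), batch = "b1"),
    invaderPops = "BOT", divergentPair = c("SRC", "BOT"),
    nBalancedLoci = 0L, nDivergentLoci = 0L)
  ts <- simulatePopulationVariants(cfg)
  tab <- diversityTable(truthSnp(ts))
  expect_lt(tab$pi[tab$population == "BOT"],
            tab$pi[tab$population == "SRC"])
})

test_that("invader-specific extraction matches its definition and the truth", {
  cfg <- simConfig(seed = 64, chromLengths = 1e6, nSnps = 50L, nSvs = 150L,
    invaderSpecificSvFrac = 0.2)
  ts <- simulatePopulationVariants(cfg)
  sv <- truthSv(ts)
  excl <- colnames(sv)[samplePopulation(sv) == "MGL"]
  invPops <- c("AU_EAST", "AU_SOUTH")
  got <- invaderSpecific(sv, invPops, excludeSamples = excl)
  ## definitional brute force on the same matrix
  keep <- setdiff(colnames(sv), excl)
  d <- dosage(sv)[, keep]
  isInv <- samplePopulation(sv)[match(keep, colnames(sv))] %in% invPops
  want <- rownames(sv)[rowSums(d[, isInv], na.rm = TRUE) > 0 &
                       rowSums(d[, !isInv], na.rm = TRUE) == 0]
  expect_equal(got, want)
  ## every labelled invader-specific SV segregating in AU_EAST/AU_SOUTH
  ## (not only in the excluded MGL samples) is recovered
  lab <- rownames(sv)[ts@invaderSpecificSv]
  labSeg <- lab[rowSums(d[lab, isInv], na.rm = TRUE) > 0]
  expect_true(all(labSeg %in% got))
  ## a single alt copy outside the invasive range disqualifies
  d2 <- rbind(c(0L, 1L, 2L, 1L), c(0L, 0L, 2L, 1L))
  gm2 <- makeGm(d2, population = c("NAT", "NAT", "INV", "INV"))
  expect_equal(invaderSpecific(gm2, "INV"), "site000002")
})

test_that("the common-variant filter is strict at MAF 0.15", {
  ## 20 alleles: 3 alt -> 0.15 exactly (excluded); 6 alt -> 0.30 (kept)
  d <- rbind(dosageRowWithAltCount(3L, 10L), dosageRowWithAltCount(6L, 10L))
  gm <- makeGm(d, population = "A")
  expect_equal(commonFilter(gm), "site000002")
  expect_equal(commonFilter(gm, ids = character(0)), character(0))
})

test_that("folded SFS classes partition SVs and histograms conserve counts", {
  si <- GenomeInfoDb::Seqinfo("chr1", 1e6)
  genes <- GRanges("chr1", IRanges(c(10000, 50000), width = 4000),
                   seqinfo = si)
  gr <- GRanges("chr1", IRanges(c(9000, 10500, 30000, 49500),
                                width = c(6000, 100, 200, 600)),
                seqinfo = si)
  mcols(gr)$type <- "DEL"
  mcols(gr)$svlen <- width(gr)
  ## alt frequency 0.9 folds to 0.1
  d <- rbind(dosageRowWithAltCount(18L, 10L),  # folded 0.1
             dosageRowWithAltCount(4L, 10L),   # 0.2
             dosageRowWithAltCount(10L, 10L),  # 0.5 -> top bin
             dosageRowWithAltCount(2L, 10L))   # 0.1
  gm <- GenotypeMatrix(d, gr, population = "A")
  sfs <- foldedSfs(gm, genes = genes)
  cls <- sfs$classOf
  ## sv1 contains gene1 entirely; sv2 break ends inside gene1; sv3 clear;
  ## sv4 ends inside gene2
  expect_equal(as.character(cls),
               c("complete_overlap", "breakend_overlap", "no_overlap",
                 "breakend_overlap"))
  expect_equal(sum(sfs$complete_overlap), 1L)
  expect_equal(sum(sfs$breakend_overlap), 2L)
  expect_equal(sum(sfs$no_overlap), 1L)
  expect_equal(unname(sfs$complete_overlap["(0.05,0.10]"]), 1L)
  expect_equal(unname(sfs$no_overlap["(0.45,0.50]"]), 1L)
})

test_that("genotype PCA separates populations and fixes signs", {
  set.seed(65)
  gm <- neutralTwoPopGm(65, nLoci = 2000L, n = 25L, F = 0.1)
  pc <- pcaGenotypes(gm)
  pop <- samplePopulation(gm)
  x <- pc$coordinates[, 1]
  ## PC1 separates the populations with a clean 1-D threshold
  thr <- (max(x[pop == "A"]) + min(x[pop == "B"])) / 2
  thr2 <- (max(x[pop == "B"]) + min(x[pop == "A"])) / 2
  purity <- max(mean((x > thr) == (pop == "B")),
                mean((x > thr2) == (pop == "A")))
  expect_equal(purity, 1)
  ## sign convention: the largest-magnitude coordinate is positive
  for (k in 1:3) {
    i <- which.max(abs(pc$coordinates[, k]))
    expect_gt(pc$coordinates[i, k], 0)
  }
  ## duplicated samples land on identical coordinates
  d <- dosage(gm)[, c(1:10, 1)]
  colnames(d) <- c(colnames(dosage(gm))[1:10], "dup")
  gm2 <- makeGm(d, pos = start(rowRanges(gm)), population = "A")
  pc2 <- pcaGenotypes(gm2)
  expect_equal(pc2$coordinates["s1", ], pc2$coordinates["dup", ],
               tolerance = 1e-8, ignore_attr = TRUE)
  ## all-zero-variance input is an error
  expect_error(pcaGenotypes(makeGm(matrix(1L, 5, 4), population = "A")),
               "zero variance")
})
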