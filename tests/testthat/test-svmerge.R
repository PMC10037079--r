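test_that("the genotype-partitioned per-sample merge retains and drops correctly", {
  ## two callers, same genotype, 400 bp apart -> one consensus call
  gr <- makeCalls(pos = c(10000L, 10400L), caller = c("a", "b"), gt = "0/1")
  m <- mergePerSample(gr)
  expect_length(m, 1L)
  expect_equal(mcols(m)$support, "a,b")
  expect_equal(mcols(m)$gt, "0/1")
  ## genotype discordance: both dropped
  gr2 <- makeCalls(pos = c(10000L, 10400L), caller = c("a", "b"),
                   gt = c("0/1", "1/1"))
  expect_length(mergePerSample(gr2), 0L)
  ## sub-minimum length excluded even at three-caller support
  gr3 <- makeCalls(pos = c(10000L, 10000L, 10000L),
                   caller = c("a", "b", "c"), svlen = 29L)
  expect_length(mergePerSample(gr3), 0L)
  ## type mismatch: no merge at min support 2
  gr4 <- makeCalls(pos = c(10000L, 10000L), caller = c("a", "b"),
                   type = c("DEL", "DUP"), strands = c("+-", "-+"))
  expect_length(mergePerSample(gr4), 0L)
  ## distance above 1 kb: no merge
  gr5 <- makeCalls(pos = c(10000L, 11100L), caller = c("a", "b"))
  expect_length(mergePerSample(gr5), 0L)
  ## TRA break ends carry no length and are exempt from the length filter
  gr6 <- makeCalls(pos = c(10000L, 10200L), caller = c("a", "b"),
                   type = "TRA", svlen = NA_integer_, strands = "++")
  expect_length(mergePerSample(gr6), 1L)
  ## missing genotypes cannot enter a genotype partition
  gr7 <- makeCalls(pos = c(10000L, 10100L), caller = c("a", "b"),
                   gt = c("./.", "./."))
  expect_length(mergePerSample(gr7), 0L)
})

test_that("break-end distance is the max over both ends", {
  ## starts 200 bp apart but ends 1.2 kb apart: svlen differs -> no merge
  gr <- makeCalls(pos = c(10000L, 10200L), caller = c("a", "b"),
                  svlen = c(500L, 1700L))
  expect_length(mergePerSample(gr), 0L)
  ## both break ends within 1 kb -> merge; representative is the low median
  gr2 <- makeCalls(pos = c(10000L, 10400L), caller = c("a", "b"),
                   svlen = c(500L, 700L))
  m <- mergePerSample(gr2)
  expect_length(m, 1L)
  expect_equal(start(m), 10000L)
  expect_equal(end(m), 10499L)  # low-median of ends 10499, 11099
})

test_that("merging is invariant to input order", {
  for (s in 1:20) {
    gr <- randMergeInstance(s)
    m1 <- mergeResultDf(mergePerSample(gr))
    set.seed(s + 1000)
    m2 <- mergeResultDf(mergePerSample(gr[sample(length(gr))]))
    expect_equal(m1, m2)
  }
})

test_that("raising maxDist never loses retained calls", {
  ## monotonicity is a property of the clustering rule; genotype agreement
  ## is off here because the cross-partition dedup convention (keep the
  ## better-supported genotype at one locus) can legitimately drop a
  ## cluster once a widened radius brings two genotype partitions into
  ## conflict
  params <- function(d) mergeParams(maxDist = d,
                                    requireGenotypeAgreement = FALSE)
  for (s in 1:15) {
    gr <- randMergeInstance(s, maxN = 8L)
    nRet <- vapply(c(200, 500, 1000, 2000, 4000), function(d) {
      m <- mergePerSample(gr, params(d))
      sum(lengths(strsplit(mcols(m)$members, ",")))
    }, numeric(1))
    expect_true(all(diff(nRet) >= 0))
  }
})

test_that("fast merge equals the brute-force oracle on random instances", {
  ## the full 1000-instance comparison runs in the acceptance suite
  for (s in 1:60) {
    gr <- randMergeInstance(s)
    expect_equal(mergeResultDf(mergePerSample(gr)),
                 mergeResultDf(bruteForceMergeOracle(gr)),
                 info = paste("instance", s))
  }
})

test_that("oracle contract: small-instance edge cases", {
  expect_length(bruteForceMergeOracle(makeCalls(integer(0),
                                                character(0))), 0L)
  one <- makeCalls(10000L, "a")
  expect_length(bruteForceMergeOracle(one), 0L)  # support 1 < 2
  expect_length(bruteForceMergeOracle(one,
    mergeParams(minSupport = 1L)), 1L)
  expect_error(bruteForceMergeOracle(makeCalls(seq.int(1, 11000, by = 1000),
                                               rep(c("a", "b"), len = 11))),
               "10 calls")
  ## A-B and B-C compatible but A-C not: best partition keeps the pair
  chain <- makeCalls(pos = c(1000L, 1900L, 2800L),
                     caller = c("a", "b", "c"))
  o <- bruteForceMergeOracle(chain)
  expect_length(o, 1L)
  expect_equal(mcols(o)$members, "c001,c002")
})

test_that("one locus surviving in two genotype partitions is resolved", {
  ## 0/1 cluster with 2 callers beats 1/1 cluster with 1 caller + 1 FP
  gr <- makeCalls(pos = c(10000L, 10120L, 10060L, 10200L),
                  caller = c("a", "b", "c", "a"),
                  gt = c("0/1", "0/1", "1/1", "1/1"))
  m <- mergePerSample(gr)
  expect_length(m, 1L)
  expect_equal(mcols(m)$gt, "0/1")
  ## equal support: the smaller-coordinate cluster wins
  gr2 <- makeCalls(pos = c(10000L, 10120L, 10060L, 10200L),
                   caller = c("a", "b", "a", "b"),
                   gt = c("1/1", "1/1", "0/1", "0/1"))
  m2 <- mergePerSample(gr2)
  expect_length(m2, 1L)
  expect_equal(mcols(m2)$gt, "1/1")  # representative pos 10000 < 10060
})

test_that("cross-sample merge types every sample with 0/0 for absences", {
  s1 <- makeCalls(10000L, caller = "consensus", gt = "0/1", sample = "s1")
  s2 <- makeCalls(10300L, caller = "consensus", gt = "1/1", sample = "s2")
  coh <- mergeAcrossSamples(list(s1 = s1, s2 = s2))
  expect_length(coh, 1L)
  expect_equal(unname(mcols(coh)$GT[1, ]), c("0/1", "1/1"))
  ## a sample-private call leaves the other sample homozygous reference
  s2b <- makeCalls(50000L, caller = "consensus", gt = "0/1", sample = "s2")
  coh2 <- mergeAcrossSamples(list(s1 = s1, s2 = s2b))
  expect_length(coh2, 2L)
  expect_equal(unname(mcols(coh2)$GT), matrix(c("0/1", "0/0", "0/0", "0/1"),
                                              2, 2))
  ## missing-genotype convention is available
  coh3 <- mergeAcrossSamples(list(s1 = s1, s2 = s2b),
                             absentGenotype = "./.")
  expect_equal(unname(mcols(coh3)$GT[1, 2]), "./.")
  ## two far-apart calls stay distinct
  s1c <- makeCalls(c(10000L, 15000L), caller = "consensus", gt = "0/1",
                   sample = "s1")
  expect_length(mergeAcrossSamples(list(s1 = s1c)), 2L)
})

test_that("cross-sample merge agrees with the oracle at min support 1", {
  params <- mergeParams(minSupport = 1L, requireGenotypeAgreement = FALSE)
  for (s in 1:25) {
    set.seed(s)
    n <- sample(2:8, 1L)
    gr <- makeCalls(pos = sample(1:3000, n, TRUE),
                    caller = "consensus",
                    gt = sample(c("0/1", "1/1"), n, TRUE),
                    sample = sample(paste0("s", 1:4), n, TRUE))
    mcols(gr)$caller <- mcols(gr)$sample  # units are samples here
    fast <- mergeAcrossSamples(split(gr, mcols(gr)$sample), params)
    oracle <- bruteForceMergeOracle(gr, params, unitField = "sample")
    expect_equal(start(fast), start(oracle))
    expect_equal(mcols(fast)$members, mcols(oracle)$members)
  }
})
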