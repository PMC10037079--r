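test_that("simulated genome honours the configuration", {
  cfg <- simConfig(seed = 1, chromLengths = c(2e6, 1e6), geneDensity = 10,
                   repeatDensity = 15)
  dir <- withr::local_tempdir()
  g <- simulateGenome(cfg, dir = dir)
  ## FASTA records of exactly the configured lengths
  seqs <- Biostrings::readDNAStringSet(g$files["fasta"])
  expect_equal(length(seqs), 2L)
  expect_equal(unname(Biostrings::width(seqs)), c(2e6, 1e6))
  ## gene count ~ Poisson(density * Mb), reproducible under the seed
  expect_gt(length(g$genes), 10)
  expect_lt(length(g$genes), 60)
  g2 <- simulateGenome(cfg)
  expect_identical(as.data.frame(g$genes), as.data.frame(g2$genes))
  expect_identical(as.data.frame(g$repeats), as.data.frame(g2$repeats))
  ## genes do not overlap; all features inside chromosome bounds
  expect_equal(sum(countOverlaps(g$genes, g$genes) > 1L), 0L)
  expect_true(all(end(g$genes) <= seqlengths(g$seqinfo)[
    as.character(seqnames(g$genes))]))
  ## annotations round-trip through GFF3/BED
  genes2 <- readGeneAnnotation(g$files["gff3"])
  expect_equal(length(genes2), length(g$genes))
  expect_equal(start(genes2), start(g$genes))
  reps2 <- readRepeatAnnotation(g$files["bed"])
  expect_equal(start(reps2), start(g$repeats))
  expect_equal(mcols(reps2)$repeat_class, mcols(g$repeats)$repeat_class)
})

test_that("zero repeat density gives an empty repeat annotation", {
  g <- simulateGenome(simConfig(seed = 2, chromLengths = 5e5,
                                repeatDensity = 0))
  expect_equal(length(g$repeats), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(populations = data.frame(
    name = "A", n = 5L, F = 1.0, batch = "b1")), "F must lie")
  expect_error(simConfig(svTypeWeights = c(DEL = 0.5, DUP = 0.5, INV = 0.5,
                                           INS = 0.2, TRA = 0.2)), "sum to 1")
  expect_error(simConfig(svLengthRange = c(20, 1000)), ">= 30")
  expect_error(simConfig(ancestralRange = c(0, 0.95)), "ancestralRange")
})

test_that("Balding-Nichols drift depresses heterozygosity monotonically", {
  ## E[2p(1-p)] after drift = (1-F) * 2 p0 (1-p0); check monotone decrease
  ## across three drift levels with a 3-MC-SE tolerance
  cfgF <- function(F, seed) simConfig(seed = seed, chromLengths = 1e6,
    nSnps = 2500L, nSvs = 10L, nBalancedLoci = 0L, nDivergentLoci = 0L,
    populations = data.frame(name = c("P", "Q"), n = c(10L, 4L),
                             F = c(F, 0.1), batch = "b1"),
    invaderPops = "Q", divergentPair = c("P", "Q"))
  hets <- ses <- numeric(3)
  Fs <- c(0.01, 0.3, 0.9)
  for (i in seq_along(Fs)) {
    ts <- simulatePopulationVariants(cfgF(Fs[i], seed = 7))
    f <- ts@snpFreq[, "P"]
    h <- 2 * f * (1 - f)
    hets[i] <- mean(h)
    ses[i] <- sd(h) / sqrt(length(h))
  }
  expect_gt(hets[1] - hets[2], -3 * sqrt(ses[1]^2 + ses[2]^2))
  expect_gt(hets[2] - hets[3], -3 * sqrt(ses[2]^2 + ses[3]^2))
  ## and the strong contrast is large
  expect_gt(hets[1], 2 * hets[3])
})

test_that("planted structure is present in the truth set", {
  cfg <- simConfig(seed = 5, chromLengths = c(2e6, 1e6), nSnps = 1500L,
                   nSvs = 200L, nBalancedLoci = 4L, nDivergentLoci = 10L,
                   invaderSpecificSvFrac = 0.1)
  ts <- simulatePopulationVariants(cfg)
  ## invader-specific count is floor(frac * nSvs), zero alt outside invaders
  expect_length(ts@invaderSpecificSv, 20L)
  nonInv <- !(samplePopulation(truthSv(ts)) %in% cfg@invaderPops)
  expect_equal(sum(dosage(truthSv(ts))[ts@invaderSpecificSv, nonInv]), 0L)
  ## every SV segregates (ascertainment)
  expect_true(all(rowSums(dosage(truthSv(ts))) > 0))
  ## balanced clusters: core + >= 10 companions within 1 kb, generative
  ## folded frequencies within 0.05 of the core's 0.4
  pos <- start(rowRanges(truthSnp(ts)))
  chr <- as.character(seqnames(rowRanges(truthSnp(ts))))
  for (i in seq_along(ts@balancedCore)) {
    core <- ts@balancedCore[i]
    comp <- ts@balancedCompanions[[i]]
    expect_gte(length(comp), 10L)
    expect_true(all(chr[comp] == chr[core]))
    expect_true(all(abs(pos[comp] - pos[core]) <= 1000))
    fComp <- ts@snpFreq[comp, 1]
    folded <- pmin(fComp, 1 - fComp)
    expect_true(all(abs(folded - 0.4) <= 0.051))
  }
  ## divergent loci have the designed frequency gap
  gap <- abs(ts@snpFreq[ts@divergentLoci, cfg@divergentPair[1]] -
             ts@snpFreq[ts@divergentLoci, cfg@divergentPair[2]])
  expect_true(all(gap >= 0.6))
})

test_that("caller emulation respects its profile and the seed", {
  cfg <- simConfig(seed = 9, chromLengths = 1e6, nSnps = 50L, nSvs = 60L,
    populations = data.frame(name = c("UK", "AU_EAST"), n = c(3L, 3L),
                             F = c(0.05, 0.1), batch = "b1"),
    invaderPops = "AU_EAST", divergentPair = c("UK", "AU_EAST"),
    nBalancedLoci = 0L, nDivergentLoci = 0L)
  ts <- simulatePopulationVariants(cfg)
  ## identity profile reproduces the truth exactly for every sample
  idProfiles <- list(identityCallerProfile("x"), identityCallerProfile("y"),
                     identityCallerProfile("z"))
  calls <- emulateCallers(ts, profiles = idProfiles)
  d <- dosage(truthSv(ts))
  gr <- rowRanges(truthSv(ts))
  for (s in colnames(d)[1:2]) {
    carrier <- which(d[, s] > 0)
    cc <- calls[[s]][["x"]]
    expect_equal(start(cc), sort(start(gr)[carrier]))
    ord <- order(as.factor(seqnames(gr[carrier])), start(gr[carrier]))
    expect_equal(mcols(cc)$gt,
                 c("0/0", "0/1", "1/1")[d[carrier, s][ord] + 1L])
    expect_true(all(mcols(cc)$filter == "PASS"))
  }
  ## a type with zero detection probability never appears
  noInv <- callerProfile("noinv", detectProb = c(DEL = 1, DUP = 1, INV = 0,
                                                 INS = 1, TRA = 1),
                         posJitter = 0L, genotypeErrorRate = 0,
                         falsePositiveRate = 0)
  calls2 <- emulateCallers(ts, profiles = list(noInv, noInv, noInv))
  types <- unlist(lapply(calls2, function(x)
    mcols(x[["noinv"]])$type))
  expect_false("INV" %in% types)
  ## same seed twice: byte-identical call sets (false positives included)
  noisy <- list(callerProfile("n1", falsePositiveRate = 10),
                callerProfile("n2"), callerProfile("n3"))
  c1 <- emulateCallers(ts, profiles = noisy)
  c2 <- emulateCallers(ts, profiles = noisy)
  expect_identical(lapply(c1, lapply, as.data.frame),
                   lapply(c2, lapply, as.data.frame))
})

test_that("batch-specific SV dropout depresses that batch's call load", {
  cfg <- simConfig(seed = 13, chromLengths = 1e6, nSnps = 20L, nSvs = 150L,
    populations = data.frame(name = c("A", "B"), n = c(6L, 6L),
                             F = c(0.05, 0.05), batch = c("b1", "b2")),
    invaderPops = "B", divergentPair = c("A", "B"),
    nBalancedLoci = 0L, nDivergentLoci = 0L, invaderSpecificSvFrac = 0,
    svDropoutBatch = "b2", svDropoutProb = 0.5)
  ts <- simulatePopulationVariants(cfg)
  calls <- emulateCallers(ts, profiles = list(
    identityCallerProfile("x"), identityCallerProfile("y"),
    identityCallerProfile("z")))
  nCalls <- vapply(calls, function(x) length(x[["x"]]), integer(1))
  carriers <- colSums(dosage(truthSv(ts)) > 0)
  frac <- nCalls / carriers
  b2 <- sampleBatch(truthSv(ts)) == "b2"
  expect_true(all(frac[!b2] == 1))
  expect_lt(mean(frac[b2]), 0.75)
})
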