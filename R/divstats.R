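## Per-population diversity statistics, private alleles, invader-specific
## variant extraction, folded site-frequency spectra by gene-overlap class,
## and PCA -- applied identically to SNP and SV genotype matrices, SV
## alleles being treated as biallelic ref/alt alleles.

.popSiteStats <- function(d) {
  ## d: dosage submatrix of one population
  nGeno <- rowSums(!is.na(d))
  nAllele <- 2L * nGeno
  j <- rowSums(d, na.rm = TRUE)           # alt allele count
  het <- rowSums(d == 1L, na.rm = TRUE)
  p <- ifelse(nAllele > 0L, j / nAllele, NA_real_)
  hO <- ifelse(nGeno > 0L, het / nGeno, NA_real_)
  hE <- 2 * p * (1 - p)
  pi <- ifelse(nAllele > 1L,
               2 * j * (nAllele - j) / (nAllele * (nAllele - 1)), NA_real_)
  list(nAllele = nAllele, j = j, p = p, hO = hO, hE = hE, pi = pi)
}

#' Per-population diversity statistics
#'
#' For every population: observed heterozygosity H_O (heterozygous /
#' non-missing genotypes), gene diversity H_E = 2p(1-p) from sample allele
#' frequencies, nucleotide diversity per site pi = 2 j (n - j) / (n (n - 1))
#' with n non-missing alleles and j alternate copies, the polymorphic-site
#' count, and private-allele counts (alleles observed in exactly one of the
#' compared populations).  Population values are means over all retained
#' sites with data; sites a population has no data for are skipped for that
#' population.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param subset optional character vector of sample ids (e.g. a
#'   single-batch subset); statistics and private alleles are computed
#'   after subsetting.
#' @return data.frame(population, nSamples, nSites, hO, hE, pi,
#'   polymorphic, privateAlleles).
#' @export
diversityTable <- function(gm, subset = NULL) {
  if (!is.null(subset)) gm <- gm[, subset]
  d <- dosage(gm)
  pops <- samplePopulation(gm)
  popNames <- unique(pops)
  stats <- lapply(popNames, function(pp)
    .popSiteStats(d[, pops == pp, drop = FALSE]))
  names(stats) <- popNames
  ## allele-presence table shared by the diversity and private-allele logic
  refPresent <- matrix(vapply(stats, function(s) s$j < s$nAllele,
                              logical(nrow(d))),
                       nrow = nrow(d), dimnames = list(NULL, popNames))
  altPresent <- matrix(vapply(stats, function(s) s$j > 0L,
                              logical(nrow(d))),
                       nrow = nrow(d), dimnames = list(NULL, popNames))
  out <- lapply(popNames, function(pp) {
    s <- stats[[pp]]
    ok <- s$nAllele > 1L
    priv <- sum(altPresent[, pp] & rowSums(altPresent) == 1L) +
      sum(refPresent[, pp] & rowSums(refPresent) == 1L)
    data.frame(population = pp, nSamples = sum(pops == pp),
               nSites = sum(ok),
               hO = mean(s$hO[ok]), hE = mean(s$hE[ok]),
               pi = mean(s$pi[ok]),
               polymorphic = sum(s$j[ok] > 0L & s$j[ok] < s$nAllele[ok]),
               privateAlleles = priv)
  })
  do.call(rbind, out)
}

#' Invader-specific variants
#'
#' Variants whose alternate allele is observed in the invasive populations
#' and in zero copies in every other population, computed after dropping
#' \code{excludeSamples} (e.g. an extreme-drift range-edge deme).
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param invaderPops population names forming the invasive range.
#' @param excludeSamples sample ids dropped before extraction.
#' @return character vector of variant names (row names of \code{gm}).
#' @export
invaderSpecific <- function(gm, invaderPops, excludeSamples = NULL) {
  if (!is.null(excludeSamples))
    gm <- gm[, setdiff(colnames(gm), excludeSamples)]
  d <- dosage(gm)
  isInv <- samplePopulation(gm) %in% invaderPops
  altInv <- rowSums(d[, isInv, drop = FALSE], na.rm = TRUE)
  altRef <- rowSums(d[, !isInv, drop = FALSE], na.rm = TRUE)
  rownames(gm)[altInv > 0L & altRef == 0L]
}

#' Common-variant filter
#'
#' Retains variants with minor allele frequency strictly above
#' \code{minMaf} (default 0.15), computed over the (optionally subset)
#' samples.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param ids candidate variant names (default: all).
#' @param minMaf strict MAF lower bound.
#' @param samples optional sample subset for the MAF computation.
#' @return character vector of retained variant names.
#' @export
commonFilter <- function(gm, ids = rownames(gm), minMaf = 0.15,
                         samples = NULL) {
  if (!is.null(samples)) gm <- gm[, samples]
  gm <- gm[intersect(ids, rownames(gm)), ]
  ids[ids %in% rownames(gm)[siteMaf(gm) > minMaf]]
}

#' Gene-overlap classes of SVs
#'
#' \code{complete_overlap}: the SV interval contains at least one whole
#' gene span; \code{breakend_overlap}: at least one break end (interval
#' boundary) lies inside a gene but no gene is fully contained;
#' \code{no_overlap}: otherwise.
#'
#' @param records SV \linkS4class{GRanges}.
#' @param genes gene \linkS4class{GRanges}.
#' @return factor parallel to \code{records}.
#' @export
geneOverlapClass <- function(records, genes) {
  ## genes wholly contained in the SV interval
  hits <- findOverlaps(genes, records, type = "within",
                       ignore.strand = TRUE)
  hasWholeGene <- logical(length(records))
  hasWholeGene[unique(S4Vectors::subjectHits(hits))] <- TRUE
  ## break ends inside a gene
  starts <- GRanges(seqnames(records), IRanges(start(records), width = 1L))
  ends <- GRanges(seqnames(records), IRanges(end(records), width = 1L))
  beInGene <- countOverlaps(starts, genes, ignore.strand = TRUE) > 0L |
    countOverlaps(ends, genes, ignore.strand = TRUE) > 0L
  cls <- ifelse(hasWholeGene, "complete_overlap",
                ifelse(beInGene, "breakend_overlap", "no_overlap"))
  factor(cls, levels = c("no_overlap", "breakend_overlap",
                         "complete_overlap"))
}

#' Folded site-frequency spectra by gene-overlap class
#'
#' Histograms of folded (minor) allele frequencies per gene-overlap class,
#' fixed bin width 0.05 over (0, 0.5]; frequencies of exactly 0.5 fall in
#' the top bin.  Monomorphic variants (folded frequency 0) carry no
#' frequency information and are excluded; each histogram sums to the
#' number of polymorphic variants in its class.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (SVs).
#' @param ids variant names to include (default: all).
#' @param genes gene \linkS4class{GRanges}.
#' @param binWidth histogram bin width.
#' @return list of named histogram vectors, one per class, plus
#'   \code{classOf} (the class factor for the selected variants).
#' @export
foldedSfs <- function(gm, ids = rownames(gm), genes, binWidth = 0.05) {
  gm <- gm[intersect(ids, rownames(gm)), ]
  maf <- siteMaf(gm)
  cls <- geneOverlapClass(rowRanges(gm), genes)
  brk <- seq(0, 0.5, by = binWidth)
  out <- lapply(levels(cls), function(cl) {
    f <- maf[cls == cl & !is.nan(maf) & maf > 0]
    h <- hist(f, breaks = brk, plot = FALSE, right = TRUE)$counts
    names(h) <- sprintf("(%.2f,%.2f]", brk[-length(brk)], brk[-1])
    h
  })
  names(out) <- levels(cls)
  out$classOf <- setNames(cls, rownames(gm))
  out
}

#' Principal component analysis of genotype dosages
#'
#' Missing dosages are mean-imputed; each site is centered by twice its
#' allele frequency and scaled by \code{sqrt(2 p (1-p))} (zero-variance
#' sites dropped), and the sample covariance of the standardized matrix is
#' eigendecomposed.  Signs are fixed so each component's largest-magnitude
#' coordinate is positive, making coordinates reproducible.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (>= 2 samples, >= 2 sites).
#' @param nComponents number of components to return.
#' @return list with \code{coordinates} (samples x components),
#'   \code{varianceExplained} and \code{values}.
#' @export
pcaGenotypes <- function(gm, nComponents = 10L) {
  d <- dosage(gm)
  if (nrow(d) < 2L || ncol(d) < 2L)
    stop("need at least 2 sites and 2 samples")
  p <- rowMeans(d, na.rm = TRUE) / 2
  v <- rowMeans(d^2, na.rm = TRUE) - (2 * p)^2
  keep <- !is.na(p) & p > 0 & p < 1 & v > 1e-12
  if (!any(keep)) stop("all sites have zero variance")
  d <- d[keep, , drop = FALSE]
  p <- p[keep]
  x <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0       # mean imputation after centering
  cv <- crossprod(x) / nrow(x)     # samples x samples
  eg <- eigen(cv, symmetric = TRUE)
  k <- min(nComponents, ncol(cv))
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  val <- pmax(eg$values[seq_len(k)], 0)
  coords <- sweep(vec, 2L, sqrt(val), "*")
  for (cc in seq_len(k)) {
    imax <- which.max(abs(coords[, cc]))
    if (coords[imax, cc] < 0) coords[, cc] <- -coords[, cc]
  }
  dimnames(coords) <- list(colnames(d), paste0("PC", seq_len(k)))
  list(coordinates = coords,
       varianceExplained = eg$values[seq_len(k)] /
         sum(pmax(eg$values, 0)),
       values = eg$values[seq_len(k)])
}
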