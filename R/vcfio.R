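#' @importFrom VariantAnnotation readVcf writeVcf VCF geno info
#' @importFrom IRanges CharacterList
NULL

.vcfHeader <- function(samples, sv = TRUE) {
  infoDf <- if (sv)
    S4Vectors::DataFrame(
      Number = c("1", "1", "1", "1"),
      Type = c("String", "Integer", "Integer", "String"),
      Description = c("Type of structural variant",
                      "End position of the variant",
                      "Length of the variant",
                      "Strand orientation of the break ends"),
      row.names = c("SVTYPE", "END", "SVLEN", "STRANDS"))
  else
    S4Vectors::DataFrame(Number = character(0), Type = character(0),
                         Description = character(0))
  new("VCFHeader", samples = samples,
      header = IRanges::DataFrameList(
        fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                          row.names = "fileformat"),
        INFO = infoDf,
        FORMAT = S4Vectors::DataFrame(Number = "1", Type = "String",
                                      Description = "Genotype",
                                      row.names = "GT")))
}

#' Write variant records to VCF v4.2
#'
#' SV records are written with a symbolic ALT (\code{<DEL>} etc.) and
#' SVTYPE/END/SVLEN/STRANDS INFO keys; SNP records get literal alleles and
#' no INFO keys.  END is emitted for spanning types (DEL/DUP/INV), SVLEN for
#' everything except TRA break ends, which carry a single coordinate and no
#' length.
#'
#' @param gr \linkS4class{GRanges} with mcols \code{type} and optionally
#'   \code{svlen}, \code{strands}.
#' @param path output path.
#' @param genotypes character matrix (sites x samples) of GT strings.
#' @param filter FILTER column (default PASS).
#' @return the path, invisibly.
#' @export
writeSVVcf <- function(gr, path, genotypes, filter = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(genotypes) == length(gr))
  if (is.null(filter)) filter <- rep("PASS", length(gr))
  type <- mcols(gr)$type
  svlen <- if ("svlen" %in% colnames(mcols(gr))) mcols(gr)$svlen
           else ifelse(type == "SNP", NA_integer_, width(gr))
  strands <- if ("strands" %in% colnames(mcols(gr))) mcols(gr)$strands
             else rep(NA_character_, length(gr))
  isSnp <- type == "SNP"
  spanning <- type %in% c("DEL", "DUP", "INV")
  rr <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L),
                seqinfo = seqinfo(gr))
  names(rr) <- if (!is.null(names(gr))) names(gr)
               else sprintf("var%06d", seq_along(gr))
  fx <- S4Vectors::DataFrame(
    REF = DNAStringSet(ifelse(isSnp, "A", "N")),
    ALT = CharacterList(as.list(ifelse(isSnp, "T",
                                       paste0("<", type, ">")))),
    QUAL = rep(NA_real_, length(gr)),
    FILTER = filter)
  infoDf <- S4Vectors::DataFrame(
    SVTYPE = ifelse(isSnp, NA_character_, type),
    END = ifelse(spanning, end(gr), NA_integer_),
    SVLEN = ifelse(isSnp | type == "TRA", NA_integer_,
                   as.integer(svlen)),
    STRANDS = ifelse(isSnp, NA_character_, strands))
  samples <- colnames(genotypes)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(genotypes)))
  rownames(genotypes) <- names(rr)
  vcf <- VCF(rowRanges = rr,
             colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                            row.names = samples),
             exptData = list(header = .vcfHeader(samples)),
             fixed = fx, info = infoDf,
             geno = SimpleList(GT = genotypes), collapsed = TRUE)
  writeVcf(vcf, path)
  invisible(path)
}

#' Read a (SV or SNP) VCF into variant records
#'
#' Biallelic records only: multi-allelic records are dropped with a warning.
#' Symbolic-ALT records missing an SVTYPE INFO key are rejected and counted.
#' Records with END before POS raise an error naming the record.  With
#' \code{passOnly = TRUE} only FILTER=PASS records are kept, matching the
#' convention of retaining PASS calls from each caller.
#'
#' @param path VCF path (plain or bgzipped).
#' @param passOnly drop records whose FILTER is not PASS.
#' @param sample,caller optional labels attached to every record (used for
#'   per-sample per-caller call sets).
#' @return \linkS4class{GRanges} with mcols \code{type, svlen, strands,
#'   filter} and either \code{gt} (single-sample) or a \code{GT} matrix
#'   column; dropped-record counts are in \code{metadata()$dropped}.
#' @export
readSVVcf <- function(path, passOnly = FALSE, sample = NULL, caller = NULL) {
  v <- suppressWarnings(readVcf(path))
  rr <- rowRanges(v)
  alt <- mcols(rr)$ALT
  altChar <- CharacterList(lapply(alt, as.character))
  nAlt <- S4Vectors::elementNROWS(altChar)
  dropped <- list(multiallelic = 0L, noSvtype = 0L, nonPass = 0L)
  keep <- rep(TRUE, length(rr))
  if (any(nAlt != 1L)) {
    dropped$multiallelic <- sum(nAlt != 1L)
    warning(dropped$multiallelic, " multi-allelic record(s) dropped")
    keep <- keep & nAlt == 1L
  }
  alt1 <- rep(NA_character_, length(rr))
  alt1[nAlt == 1L] <- unlist(altChar[nAlt == 1L])
  symbolic <- !is.na(alt1) & grepl("^<", alt1)
  svtype <- if (!is.null(info(v)$SVTYPE)) info(v)$SVTYPE
            else rep(NA_character_, length(rr))
  bad <- symbolic & is.na(svtype)
  if (any(bad & keep)) {
    dropped$noSvtype <- sum(bad & keep)
    warning(dropped$noSvtype,
            " symbolic-allele record(s) without SVTYPE rejected")
    keep <- keep & !bad
  }
  type <- ifelse(symbolic, svtype, "SNP")
  endInfo <- if (!is.null(info(v)$END)) info(v)$END
             else rep(NA_integer_, length(rr))
  badEnd <- !is.na(endInfo) & endInfo < start(rr)
  if (any(badEnd & keep))
    stop("END precedes POS for record(s): ",
         paste(names(rr)[badEnd & keep], collapse = ", "))
  filt <- mcols(rr)$FILTER
  if (passOnly) {
    dropped$nonPass <- sum(keep & filt != "PASS")
    keep <- keep & filt == "PASS"
  }
  svlen <- if (!is.null(info(v)$SVLEN)) info(v)$SVLEN
           else rep(NA_integer_, length(rr))
  if (is.list(svlen) || is(svlen, "List"))
    svlen <- vapply(svlen, function(x)
      if (length(x)) as.integer(abs(x[1])) else NA_integer_, integer(1))
  strands <- if (!is.null(info(v)$STRANDS)) as.character(info(v)$STRANDS)
             else rep(NA_character_, length(rr))
  w <- ifelse(!is.na(endInfo) & type %in% c("DEL", "DUP", "INV"),
              endInfo - start(rr) + 1L, 1L)
  out <- GRanges(seqnames(rr), IRanges(start(rr), width = w),
                 seqinfo = seqinfo(rr))
  names(out) <- names(rr)
  mcols(out)$type <- type
  mcols(out)$svlen <- as.integer(svlen)
  mcols(out)$strands <- strands
  mcols(out)$filter <- filt
  gtm <- geno(v)$GT
  if (!is.null(gtm) && ncol(gtm) == 1L) {
    mcols(out)$gt <- as.character(gtm[, 1L])
  } else if (!is.null(gtm)) {
    mcols(out)$GT <- gtm
  }
  if (!is.null(sample)) mcols(out)$sample <- sample
  if (!is.null(caller)) mcols(out)$caller <- caller
  out <- out[keep]
  metadata(out)$dropped <- dropped
  out
}

#' Read a directory of per-sample per-caller VCFs
#'
#' Expects the \code{<sample>.<caller>.vcf} layout of
#' \code{\link{writeCallerVcfs}}.
#'
#' @param dir directory to scan.
#' @param passOnly keep only PASS calls (the consensus-merge convention).
#' @return nested list \code{calls[[sample]][[caller]]}.
#' @export
readCallerVcfs <- function(dir, passOnly = TRUE) {
  files <- list.files(dir, pattern = "\\.vcf(\\.gz|\\.bgz)?$",
                      full.names = TRUE)
  out <- list()
  for (f in files) {
    parts <- strsplit(sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(f)),
                      ".", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    s <- paste(parts[-length(parts)], collapse = ".")
    cl <- parts[length(parts)]
    out[[s]][[cl]] <- readSVVcf(f, passOnly = passOnly, sample = s,
                                caller = cl)
  }
  out
}

#' Read a population map
#'
#' @param path TSV with columns sample, population, batch.
#' @return data.frame.
#' @export
readPopulationMap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "population", "batch") %in% names(df)))
  df
}

.gtToDosage <- function(gt) {
  d <- rep(NA_integer_, length(gt))
  d[gt %in% c("0/0", "0|0")] <- 0L
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gt %in% c("1/1", "1|1")] <- 2L
  d
}

#' Build a GenotypeMatrix from variant records
#'
#' @param records \linkS4class{GRanges} from \code{\link{readSVVcf}} with a
#'   \code{GT} matrix column (or single-sample \code{gt}).
#' @param populationMap data.frame(sample, population, batch); every VCF
#'   sample must be present.
#' @return a \linkS4class{GenotypeMatrix} sorted by (chrom, pos).
#' @export
buildGenotypeMatrix <- function(records, populationMap) {
  gtm <- if ("GT" %in% colnames(mcols(records))) mcols(records)$GT
         else matrix(mcols(records)$gt, ncol = 1,
                     dimnames = list(NULL, unique(mcols(records)$sample)))
  samples <- colnames(gtm)
  missingSamples <- setdiff(samples, populationMap$sample)
  if (length(missingSamples))
    stop("sample(s) absent from population map: ",
         paste(missingSamples, collapse = ", "))
  idx <- match(samples, populationMap$sample)
  dm <- matrix(.gtToDosage(as.character(gtm)), nrow = length(records),
               dimnames = list(names(records), samples))
  gr <- granges(records)
  mcols(gr)$type <- mcols(records)$type
  mcols(gr)$svlen <- mcols(records)$svlen
  if ("strands" %in% colnames(mcols(records)))
    mcols(gr)$strands <- mcols(records)$strands
  GenotypeMatrix(dm, gr, population = populationMap$population[idx],
                 batch = populationMap$batch[idx], sampleIds = samples)
}

#' Write a GenotypeMatrix as a multi-sample VCF
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGenotypeVcf <- function(gm, path) {
  d <- dosage(gm)
  gt <- matrix("./.", nrow(d), ncol(d), dimnames = dimnames(d))
  gt[!is.na(d)] <- GT_STRINGS[d[!is.na(d)] + 1L]
  writeSVVcf(rowRanges(gm), path, genotypes = gt)
}

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' @param path VCF path.
#' @param populationMap data.frame(sample, population, batch).
#' @param passOnly drop non-PASS records first.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVcf <- function(path, populationMap, passOnly = FALSE) {
  buildGenotypeMatrix(readSVVcf(path, passOnly = passOnly), populationMap)
}

#' Read gene and repeat annotations
#'
#' @param path GFF3 (genes) or BED (repeats) path.
#' @return \linkS4class{GRanges}; repeat BED names become
#'   \code{repeat_class}.
#' @export
readGeneAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr[mcols(gr)$type %in% "gene" | !("type" %in% colnames(mcols(gr)))]
}

#' @rdname readGeneAnnotation
#' @export
readRepeatAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  mcols(gr)$repeat_class <- mcols(gr)$name
  gr
}

#' Overlap variants with an annotation
#'
#' Interval arithmetic is on 1-based closed coordinates as carried by the
#' \linkS4class{GRanges}; "within 1 kb" is inclusive (at most 1000
#' intervening bases between nearest edges).  TRA break ends occupy a 1-bp
#' interval.
#'
#' @param records variant \linkS4class{GRanges}.
#' @param annotation feature \linkS4class{GRanges}.
#' @param mode \code{"any_overlap"} (features intersecting the record) or
#'   \code{"within_1kb"} (features within 1000 bp of the record, inclusive).
#' @return list (parallel to \code{records}) of integer indices into
#'   \code{annotation}.
#' @export
intersectAnnotation <- function(records,
                                annotation,
                                mode = c("any_overlap", "within_1kb")) {
  mode <- match.arg(mode)
  maxgap <- if (mode == "within_1kb") 1000L else -1L
  hits <- findOverlaps(records, annotation, maxgap = maxgap,
                       ignore.strand = TRUE)
  out <- vector("list", length(records))
  for (i in seq_along(out)) out[[i]] <- integer(0)
  sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  out[as.integer(names(sp))] <- lapply(sp, unname)
  out
}
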