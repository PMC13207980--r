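## External formats. Coordinate conventions: epiread TSV, BED and the design
## table are 0-based half-open; VCF is converted from 1-based on ingest. All
## record-level validation failures are skipped with a tally (attached as
## attr "skipped") rather than aborting the parse, except where the spec of a
## format makes recovery meaningless (missing columns, unknown samples).

#' Read a cohort design table
#'
#' Tab-separated with header columns \code{sample_id}, \code{ecotype}
#' (\code{freshwater}/\code{marine}) and \code{sex} (\code{male}/\code{female}).
#'
#' @param path file path.
#' @return data.frame with the three columns, validated.
#' @export
readDesign <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       colClasses = "character"))
  ok <- .validDesign(d)
  if (!isTRUE(ok)) stop(ok)
  d
}

#' @rdname readDesign
#' @param design a design data.frame.
#' @export
writeDesign <- function(design, path) {
  data.table::fwrite(design, path, sep = "\t")
  invisible(path)
}

#' Read and write epiread tables
#'
#' The epiread TSV is the pipeline's entry format: one sequenced fragment per
#' row, five tab-separated columns with header
#' \code{chrom, read_id, sample_id, positions, pattern}, where
#' \code{positions} is a comma-separated list of 0-based forward-strand C
#' coordinates of the CpGs the fragment covers (strictly increasing) and
#' \code{pattern} is a string over \code{M}/\code{U} of the same length.
#' This deliberately decouples the entropy statistic from aligner internals;
#' a per-CpG-call converter from aligner output can emit this format.
#'
#' Rows failing validation (non-M/U characters, length mismatch, unsorted
#' positions) are skipped and counted; the tally is reported via
#' \code{message()} and attached as \code{attr(x, "skipped")}. A
#' \code{sample_id} absent from the design is an error, as is a missing
#' column.
#'
#' @param path file path.
#' @param design cohort design (see \code{\link{readDesign}}).
#' @return an \code{\link{EpireadSet}}.
#' @examples
#' design <- data.frame(sample_id = "s1", ecotype = "marine", sex = "female")
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tread_id\tsample_id\tpositions\tpattern",
#'              "chr1\tr1\ts1\t100,105,110,118,130\tMMUMU"), f)
#' es <- readEpireads(f, design)
#' @export
readEpireads <- function(path, design) {
  ok <- .validDesign(design)
  if (!isTRUE(ok)) stop(ok)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("chrom", "read_id", "sample_id", "positions", "pattern")
  if (!all(need %in% colnames(dt)))
    stop(sprintf("epiread file must have columns: %s",
                 paste(need, collapse = ", ")))
  unknown <- setdiff(unique(dt$sample_id), design$sample_id)
  if (length(unknown))
    stop(sprintf("unknown sample_id in epiread file: %s",
                 paste(unknown, collapse = ", ")))
  pos <- strsplit(dt$positions, ",", fixed = TRUE)
  pos <- lapply(pos, function(p) suppressWarnings(as.integer(p)))
  len <- lengths(pos)
  badPattern <- !grepl("^[MU]+$", dt$pattern)
  badLength <- nchar(dt$pattern) != len |
    vapply(pos, anyNA, logical(1))
  badSorted <- vapply(pos, function(p) any(is.na(p)) ||
                        is.unsorted(p, strictly = TRUE), logical(1))
  bad <- badPattern | badLength | badSorted
  skipped <- c(pattern = sum(badPattern),
               length = sum(badLength & !badPattern),
               unsorted = sum(badSorted & !badLength & !badPattern))
  if (any(bad))
    message(sprintf("readEpireads: skipped %d malformed record(s) (pattern %d, length %d, unsorted %d)",
                    sum(bad), skipped[["pattern"]], skipped[["length"]],
                    skipped[["unsorted"]]))
  keep <- which(!bad)
  reads <- DataFrame(chrom = dt$chrom[keep], read_id = dt$read_id[keep],
                     sample_id = dt$sample_id[keep],
                     positions = IRanges::IntegerList(pos[keep]),
                     pattern = dt$pattern[keep])
  out <- EpireadSet(reads, design)
  attr(out, "skipped") <- skipped
  out
}

#' @rdname readEpireads
#' @param x an \code{EpireadSet}.
#' @export
writeEpireads <- function(x, path) {
  r <- epireads(x)
  posStr <- vapply(as.list(r$positions), paste, character(1), collapse = ",")
  dt <- data.table::data.table(chrom = r$chrom, read_id = r$read_id,
                               sample_id = r$sample_id, positions = posStr,
                               pattern = r$pattern)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Scan a FASTA for CpG sites
#'
#' Returns every 0-based position p with base(p) == C and base(p+1) == G on
#' the forward strand; the two strands of a CpG dyad collapse to this single
#' unit. Case-insensitive; ambiguity codes never match.
#'
#' @param fastaPath FASTA file path.
#' @return a \code{\link{CpGMap}}. Sequence names are truncated at the first
#'   whitespace.
#' @export
scanCpGSites <- function(fastaPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sites <- lapply(seq_along(seqs), function(i) {
    m <- Biostrings::matchPattern("CG", seqs[[i]], fixed = TRUE)
    as.integer(start(m) - 1L)
  })
  names(sites) <- names(seqs)
  CpGMap(sites)
}

#' Read a BED region set with flank expansion
#'
#' BED3+ (0-based half-open). Records with start >= end are rejected with a
#' warning and counted in \code{attr(x, "skipped")}. Column 4, when present,
#' names the regions; otherwise names are generated.
#'
#' @param bedPath BED file path.
#' @param flank bp added to each side (clipped at 0 and, when \code{seqlen}
#'   is given, at the chromosome end).
#' @param seqlen optional named integer vector of chromosome lengths.
#' @return a \code{\link{RegionSet}}.
#' @export
readRegions <- function(bedPath, flank = 0L, seqlen = integer()) {
  dt <- data.table::fread(bedPath, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns")
  start0 <- as.integer(dt[[2]])
  end0 <- as.integer(dt[[3]])
  bad <- is.na(start0) | is.na(end0) | start0 >= end0
  if (any(bad))
    warning(sprintf("readRegions: rejected %d record(s) with start >= end",
                    sum(bad)))
  nm <- if (ncol(dt) >= 4L) as.character(dt[[4]]) else
    sprintf("region_%04d", seq_len(nrow(dt)))
  g <- .granges0(as.character(dt[[1]])[!bad], start0[!bad], end0[!bad],
                 name = nm[!bad])
  out <- RegionSet(g, flank = flank, seqlen = seqlen)
  attr(out, "skipped") <- sum(bad)
  out
}

#' @rdname readRegions
#' @param x a \code{RegionSet}; the core (unflanked) intervals are written.
#' @param path output path.
#' @export
writeRegionsBed <- function(x, path) {
  g <- coreRegions(x)
  dt <- data.table::data.table(chrom = as.character(seqnames(g)),
                               start = start(g) - 1L, end = end(g),
                               name = g$name)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count matrix
#'
#' Tab-separated, header row of sample names, first column the feature id.
#'
#' @param path file path.
#' @return numeric matrix, features in rows.
#' @export
readCountMatrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "numeric"
  m
}

#' Read TSS annotation from BED6
#'
#' Strand-aware: the TSS is the interval start on \code{+}, the last base on
#' \code{-}. Column 4 is taken as the gene id.
#'
#' @param path BED6 path (strand column required).
#' @return data.frame(gene, chrom, tss0, strand), tss0 0-based.
#' @export
readTss <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 6L) stop("TSS input must be BED6 (strand column required)")
  strand <- as.character(dt[[6]])
  if (!all(strand %in% c("+", "-"))) stop("strand must be + or -")
  start0 <- as.integer(dt[[2]])
  end0 <- as.integer(dt[[3]])
  data.frame(gene = as.character(dt[[4]]), chrom = as.character(dt[[1]]),
             tss0 = ifelse(strand == "+", start0, end0 - 1L),
             strand = strand, stringsAsFactors = FALSE)
}

## ------------------------------------------------------------ C->T VCF I/O

#' Read C-to-T genotypes at CpG sites from VCF
#'
#' Retains biallelic SNVs that are C>T at a forward-strand CpG C, or G>A at
#' the paired G (reverse-strand read of the same dyad; the coordinate is
#' folded back to the forward C). Positions are converted from VCF 1-based to
#' the package's 0-based convention and restricted to the CpG universe.
#' Everything else (multi-allelic records, other substitutions, positions off
#' the CpG map) is skipped with a tally. Missing GT means the site is treated
#' as uncovered for that sample downstream.
#'
#' @param vcfPath VCF 4.x path.
#' @param cpgMap a \code{\link{CpGMap}}; only CpG positions are retained.
#' @return a genotype table: \code{list(sites, gt)} where \code{sites} is a
#'   data.frame(chrom, pos0, ref, alt) and \code{gt} a sites-by-samples
#'   character matrix of GT strings (\code{"0/1"}, \code{"0|1"}, ...). Allele
#'   0 always denotes C and allele 1 denotes T in the forward-strand CpG
#'   frame, for G>A records as well. Retention statistics are attached as
#'   \code{attr(x, "stats")}.
#' @export
readVcfCt <- function(vcfPath, cpgMap) {
  vcf <- VariantAnnotation::readVcf(vcfPath)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(seqnames(rr))
  pos1 <- start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  multi <- lengths(altL) != 1L
  alt <- rep(NA_character_, length(ref))
  alt[!multi] <- as.character(unlist(altL[!multi]))
  isCT <- !multi & ref == "C" & alt == "T"
  isGA <- !multi & ref == "G" & alt == "A"
  ## forward-strand C coordinate (0-based) of the dyad
  pos0 <- ifelse(isGA, pos1 - 2L, pos1 - 1L)
  onMap <- rep(FALSE, length(ref))
  for (chr in unique(chrom)) {
    i <- chrom == chr
    onMap[i] <- pos0[i] %in% cpgSites(cpgMap, chr)
  }
  keep <- (isCT | isGA) & onMap
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  out <- list(
    sites = data.frame(chrom = chrom[keep], pos0 = as.integer(pos0[keep]),
                       ref = "C", alt = "T", stringsAsFactors = FALSE),
    gt = gt[keep, , drop = FALSE]
  )
  attr(out, "stats") <- c(total = length(ref), retained = sum(keep),
                          multiallelic = sum(multi),
                          non_ct = sum(!multi & !(isCT | isGA)),
                          off_cpg = sum((isCT | isGA) & !onMap))
  out
}

#' @rdname readVcfCt
#' @param genotypes a genotype table as returned by \code{readVcfCt} or
#'   \code{\link{injectCtMutations}}.
#' @param path output path; a minimal VCF 4.2 with GT-only FORMAT is written.
#' @export
writeVcfCt <- function(genotypes, path) {
  sites <- genotypes$sites
  gt <- genotypes$gt
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gt)), collapse = "\t")), con)
  if (nrow(sites)) {
    body <- cbind(sites$chrom, sites$pos0 + 1L,
                  sprintf("ct_%05d", seq_len(nrow(sites))), sites$ref,
                  sites$alt, ".", "PASS", ".", "GT", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}
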