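## Central S4 containers. All coordinates stored in plain columns are 0-based
## (forward-strand C of a CpG dyad); GRanges objects used internally for
## overlap arithmetic are converted with .granges0()/.bed0() at the boundary.

ECOTYPES <- c("freshwater", "marine")
SEXES <- c("male", "female")

## ---------------------------------------------------------------- EpireadSet

#' EpireadSet: per-read CpG methylation patterns plus cohort design
#'
#' An \code{EpireadSet} holds one sequenced fragment per row: the chromosome,
#' an opaque read id, the owning sample, the ordered 0-based genomic positions
#' of the CpG sites the fragment covers, and the fragment's methylation
#' pattern as a string over \code{M} (methylated) / \code{U} (unmethylated) of
#' the same length. The cohort design maps each sample to its ecotype
#' (freshwater or marine) and sex; every read's sample must appear in the
#' design exactly once.
#'
#' Reads carrying ambiguous calls are never stored; they are dropped (and
#' counted) at parse or simulation time, because entropy estimates are
#' sensitive to imputation.
#'
#' @slot reads a \code{DataFrame} with columns \code{chrom}, \code{read_id},
#'   \code{sample_id}, \code{positions} (an \code{IntegerList}, strictly
#'   increasing within each read) and \code{pattern}.
#' @slot design a \code{data.frame} with columns \code{sample_id},
#'   \code{ecotype}, \code{sex}.
#'
#' @param reads a \code{DataFrame} or \code{data.frame} as above;
#'   \code{positions} may be a plain list of integer vectors.
#' @param design the cohort design \code{data.frame}.
#' @param x an \code{EpireadSet}.
#' @return \code{EpireadSet()} returns a validated object; \code{epireads()}
#'   the read table; \code{cohortDesign()} the design; \code{nReads()} the
#'   number of fragments.
#' @examples
#' design <- data.frame(sample_id = "s1", ecotype = "freshwater", sex = "male")
#' reads <- data.frame(chrom = "chr1", read_id = "r1", sample_id = "s1",
#'                     pattern = "MMUMU")
#' reads$positions <- list(c(100L, 105L, 110L, 118L, 130L))
#' es <- EpireadSet(reads, design)
#' nReads(es)
#' @aliases EpireadSet epireads cohortDesign nReads
#' @export EpireadSet
#' @exportClass EpireadSet
setClass("EpireadSet", slots = c(reads = "DataFrame", design = "data.frame"))

.validDesign <- function(design) {
  need <- c("sample_id", "ecotype", "sex")
  if (!all(need %in% colnames(design)))
    return(sprintf("design must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(design$sample_id))
    return("duplicated sample_id in design")
  if (!all(design$ecotype %in% ECOTYPES))
    return(sprintf("ecotype must be one of: %s", paste(ECOTYPES, collapse = ", ")))
  if (!all(design$sex %in% SEXES))
    return(sprintf("sex must be one of: %s", paste(SEXES, collapse = ", ")))
  TRUE
}

S4Vectors::setValidity2("EpireadSet", function(object) {
  r <- object@reads
  need <- c("chrom", "read_id", "sample_id", "positions", "pattern")
  if (!all(need %in% colnames(r)))
    return(sprintf("reads must have columns %s", paste(need, collapse = ", ")))
  ok <- .validDesign(object@design)
  if (!isTRUE(ok)) return(ok)
  if (nrow(r) == 0L) return(TRUE)
  if (!all(r$sample_id %in% object@design$sample_id))
    return("reads reference sample_id values absent from the design")
  len <- lengths(r$positions)
  if (!all(nchar(r$pattern) == len))
    return("pattern length must equal the number of CpG positions")
  if (!all(grepl("^[MU]+$", r$pattern)))
    return("pattern must contain only M and U")
  u <- unlist(r$positions, use.names = FALSE)
  if (length(u) > length(len)) {
    d <- diff(u)
    boundary <- cumsum(len)[-length(len)]
    within <- if (length(boundary)) d[-boundary] else d
    if (any(within <= 0L))
      return("positions must be strictly increasing within each read")
  }
  TRUE
})

#' @rdname EpireadSet-class
EpireadSet <- function(reads, design) {
  reads <- as(reads, "DataFrame")
  if (!is(reads$positions, "IntegerList"))
    reads$positions <- IRanges::IntegerList(lapply(reads$positions, as.integer))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  new("EpireadSet", reads = reads, design = design)
}

## constructor bypassing validity, for reads that are valid by construction
## (row subsets of a validated object, simulator output)
.EpireadSetUnchecked <- function(reads, design) {
  S4Vectors::new2("EpireadSet", reads = reads, design = design, check = FALSE)
}

setMethod("epireads", "EpireadSet", function(x) x@reads)
setMethod("cohortDesign", "EpireadSet", function(x) x@design)
setMethod("nReads", "EpireadSet", function(x) nrow(x@reads))

setMethod("show", "EpireadSet", function(object) {
  d <- object@design
  cat(sprintf("EpireadSet: %d reads, %d samples (%d freshwater / %d marine; %d male / %d female)\n",
              nrow(object@reads), nrow(d),
              sum(d$ecotype == "freshwater"), sum(d$ecotype == "marine"),
              sum(d$sex == "male"), sum(d$sex == "female")))
  if (nrow(object@reads) > 0L)
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(object@reads$chrom), collapse = ", ")))
})

## ------------------------------------------------------------------- CpGMap

#' CpGMap: the genome's CpG universe
#'
#' Ordered 0-based coordinates of the forward-strand C of every CpG dyad, per
#' chromosome. Both strands of a CpG collapse to this single unit (symmetric
#' CpG methylation, standard WGBS practice). The map defines the ordinal index
#' space in which sliding windows are built.
#'
#' @slot sites named list of strictly increasing integer vectors.
#' @param sites named list of integer vectors (0-based C positions).
#' @param x a \code{CpGMap}.
#' @param chrom optional chromosome name; \code{cpgSites(x, chrom)} returns
#'   that chromosome's positions, \code{cpgSites(x)} the full list.
#' @examples
#' m <- CpGMap(list(chr1 = c(1L, 3L)))
#' cpgSites(m, "chr1")
#' @aliases CpGMap cpgSites chromNames
#' @export CpGMap
#' @exportClass CpGMap
setClass("CpGMap", slots = c(sites = "list"))

setValidity("CpGMap", function(object) {
  s <- object@sites
  if (length(s) && is.null(names(s))) return("sites must be a named list")
  for (chr in names(s)) {
    p <- s[[chr]]
    if (!is.integer(p)) return(sprintf("%s: positions must be integer", chr))
    if (is.unsorted(p, strictly = TRUE))
      return(sprintf("%s: positions must be strictly increasing", chr))
  }
  TRUE
})

#' @rdname CpGMap-class
CpGMap <- function(sites) {
  new("CpGMap", sites = lapply(sites, as.integer))
}

setMethod("cpgSites", "CpGMap", function(x, chrom = NULL) {
  if (is.null(chrom)) x@sites else x@sites[[chrom]]
})
setMethod("chromNames", "CpGMap", function(x) names(x@sites))

setMethod("show", "CpGMap", function(object) {
  cat(sprintf("CpGMap: %d CpG sites on %d chromosome(s)\n",
              sum(lengths(object@sites)), length(object@sites)))
})

## ---------------------------------------------------------------- RegionSet

#' RegionSet: named genomic intervals with flank expansion
#'
#' Holds a set of core intervals (divergence islands, EcoPeaks, promoters,
#' ...) together with a fixed flank size. The core intervals are retained
#' alongside the flank-expanded ones so that core-versus-flank analyses remain
#' possible. Flank expansion is clipped at position 0 and, when sequence
#' lengths are known, at the chromosome end.
#'
#' Intervals are stored as a \code{GRanges} (1-based closed, the native
#' GRanges convention); use \code{\link{readRegions}} to ingest 0-based
#' half-open BED.
#'
#' @slot regions \code{GRanges} with an mcols column \code{name}.
#' @slot flank single non-negative integer, bp added to each side.
#' @slot seqlen named integer vector of chromosome lengths (may be empty).
#' @param regions the core \code{GRanges} (needs mcols \code{name}).
#' @param flank flank size in bp.
#' @param seqlen optional named chromosome lengths for clipping.
#' @param x a \code{RegionSet}.
#' @aliases RegionSet coreRegions flankedRegions flankSize
#' @export RegionSet
#' @exportClass RegionSet
setClass("RegionSet",
         slots = c(regions = "GRanges", flank = "integer", seqlen = "integer"))

setValidity("RegionSet", function(object) {
  if (length(object@regions) && is.null(object@regions$name))
    return("regions must carry a 'name' column")
  if (length(object@flank) != 1L || is.na(object@flank) || object@flank < 0L)
    return("flank must be a single non-negative integer")
  TRUE
})

#' @rdname RegionSet-class
RegionSet <- function(regions, flank = 0L, seqlen = integer()) {
  new("RegionSet", regions = regions, flank = as.integer(flank),
      seqlen = setNames(as.integer(seqlen), names(seqlen)))
}

setMethod("coreRegions", "RegionSet", function(x) x@regions)
setMethod("flankSize", "RegionSet", function(x) x@flank)
setMethod("flankedRegions", "RegionSet", function(x) {
  g <- x@regions
  s <- pmax(start(g) - x@flank, 1L)
  e <- end(g) + x@flank
  chr <- as.character(seqnames(g))
  if (length(x@seqlen)) {
    lim <- x@seqlen[chr]
    e <- ifelse(is.na(lim), e, pmin(e, lim))
  }
  GRanges(chr, IRanges(s, e), name = g$name)
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d region(s), flank %d bp\n",
              length(object@regions), object@flank))
})

## ----------------------------------------------------------- EntropyProfile

#' EntropyProfile: per-window entropy and its decomposition
#'
#' A \code{RangedSummarizedExperiment} subclass produced by
#' \code{\link{entropyProfile}} (or \code{\link{ctEntropyProfile}}). Rows are
#' sliding CpG windows, columns the samples contributing to the profile.
#' Assays:
#' \describe{
#'   \item{\code{N}}{reads (or haplotypes) per window and sample.}
#'   \item{\code{H}}{per-sample normalized entropy, \code{NA} below the
#'     per-sample read minimum.}
#' }
#' Row data carries \code{N_total}, \code{H_pooled}, \code{H_within},
#' \code{H_between} and a \code{qc} flag (\code{"ok"}, \code{"low_coverage"}
#' or \code{"few_samples"}). The decomposition satisfies
#' \code{H_pooled = H_within + H_between} exactly (up to floating point);
#' \code{H_between} is the mutual information between sample identity and
#' epiallele, divided by the window size b.
#'
#' @param x an \code{EntropyProfile}.
#' @aliases EntropyProfile entropyPooled entropyWithin entropyBetween
#'   windowIds qcFlags
#' @exportClass EntropyProfile
setClass("EntropyProfile", contains = "RangedSummarizedExperiment")

setValidity("EntropyProfile", function(object) {
  if (!all(c("N", "H") %in% names(assays(object))))
    return("assays N and H are required")
  need <- c("N_total", "H_pooled", "H_within", "H_between", "qc")
  if (!all(need %in% colnames(rowData(object))))
    return(sprintf("rowData must have columns %s", paste(need, collapse = ", ")))
  TRUE
})

setMethod("entropyPooled", "EntropyProfile", function(x)
  setNames(rowData(x)$H_pooled, rowData(x)$window_id))
setMethod("entropyWithin", "EntropyProfile", function(x)
  setNames(rowData(x)$H_within, rowData(x)$window_id))
setMethod("entropyBetween", "EntropyProfile", function(x)
  setNames(rowData(x)$H_between, rowData(x)$window_id))
setMethod("windowIds", "EntropyProfile", function(x) rowData(x)$window_id)
setMethod("qcFlags", "EntropyProfile", function(x)
  setNames(rowData(x)$qc, rowData(x)$window_id))

setMethod("show", "EntropyProfile", function(object) {
  qc <- rowData(object)$qc
  cat(sprintf("EntropyProfile: %d windows x %d samples (b = %s)\n",
              nrow(object), ncol(object),
              as.character(metadata(object)$b)))
  cat(sprintf("  qc: %d ok, %d low_coverage, %d few_samples\n",
              sum(qc == "ok"), sum(qc == "low_coverage"),
              sum(qc == "few_samples")))
  hb <- rowData(object)$H_between
  if (any(!is.na(hb)))
    cat(sprintf("  H_between: median %.4f (n = %d defined)\n",
                median(hb, na.rm = TRUE), sum(!is.na(hb))))
})
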