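## The C->T transition entropy control. Bisulfite sequencing cannot tell a
## genetic T at a CpG from an unmethylated (converted) C, so elevated
## methylation entropy could in principle be mutation-driven. The control
## applies the identical entropy machinery to genetic C/T alleles at the
## same window's CpG sites, with haplotypes playing the role of reads
## (N = 2 per diploid individual): genuinely epigenetic variability leaves
## the C->T entropy flat, while mutation-driven signal shows up in both.

#' Expand diploid genotypes to per-haplotype C/T window patterns
#'
#' For every window, each individual contributes two length-b allele
#' patterns over \{C, T\} at the window's CpG sites. Sites without a variant
#' record are reference C. Phased genotypes (\code{"0|1"}) are used as-is;
#' unphased heterozygotes are assigned to haplotypes uniformly at random
#' under a fixed seed (\code{phasing = "random"}, the default), or pushed to
#' the \code{"allref"}/\code{"allalt"} extremes for sensitivity bounds
#' (first haplotype gets the reference/alternate allele respectively). An
#' individual with a missing genotype at any covered variant site is
#' excluded from that window.
#'
#' @param genotypes genotype table from \code{\link{readVcfCt}} or
#'   \code{\link{injectCtMutations}}: \code{list(sites, gt)}.
#' @param windows windows from \code{\link{buildWindows}}.
#' @param phasing \code{"random"}, \code{"allref"} or \code{"allalt"}
#'   (applies to unphased heterozygotes only).
#' @param seed seed for random phasing.
#' @return \code{data.table(window_id, sample_id, hap, pattern)}, two rows
#'   per retained (window, individual); excluded pairs are counted in
#'   \code{attr(x, "excluded")}.
#' @export
genotypeToPatterns <- function(genotypes, windows,
                               phasing = c("random", "allref", "allalt"),
                               seed = 1L) {
  phasing <- match.arg(phasing)
  b <- metadata(windows)$b
  sites <- genotypes$sites
  gt <- genotypes$gt
  samples <- colnames(gt)
  if (is.null(samples)) stop("genotype matrix must have sample columns")
  nSite <- nrow(sites)
  ## parse GT strings once into two allele matrices (0 = C, 1 = T, NA = ./.)
  a1 <- a2 <- matrix(0L, nSite, length(samples),
                     dimnames = list(NULL, samples))
  if (nSite) {
    g <- as.vector(gt)
    phased <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[/|]")
    v1 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
    v2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, character(1))))
    if (phasing != "random") {
      het <- !phased & !is.na(v1) & !is.na(v2) & v1 != v2
      if (phasing == "allref") { v1[het] <- 0L; v2[het] <- 1L }
      else { v1[het] <- 1L; v2[het] <- 0L }
    } else {
      set.seed(seed)
      het <- !phased & !is.na(v1) & !is.na(v2) & v1 != v2
      flip <- het & runif(length(g)) < 0.5
      tmp <- v1[flip]; v1[flip] <- v2[flip]; v2[flip] <- tmp
    }
    a1[] <- v1
    a2[] <- v2
  }
  siteKey <- if (nSite) paste0(sites$chrom, ":", sites$pos0) else character(0)
  widAll <- mcols(windows)$window_id
  posList <- mcols(windows)$positions
  chromW <- as.character(seqnames(windows))
  chunks <- vector("list", length(windows))
  excluded <- 0L
  for (w in seq_along(windows)) {
    key <- paste0(chromW[w], ":", posList[[w]])
    si <- match(key, siteKey)
    hasVar <- !is.na(si)
    ## allele rows for this window: b x samples, reference C where no record
    m1 <- m2 <- matrix(0L, b, length(samples))
    if (any(hasVar)) {
      m1[hasVar, ] <- a1[si[hasVar], , drop = FALSE]
      m2[hasVar, ] <- a2[si[hasVar], , drop = FALSE]
    }
    bad <- colSums(is.na(m1) | is.na(m2)) > 0L
    excluded <- excluded + sum(bad)
    keep <- which(!bad)
    if (!length(keep)) next
    toPat <- function(m) apply(matrix(c("C", "T")[m[, keep, drop = FALSE] + 1L],
                                      nrow = b), 2L, paste, collapse = "")
    chunks[[w]] <- data.table::data.table(
      window_id = widAll[w],
      sample_id = rep(samples[keep], 2L),
      hap = rep(1:2, each = length(keep)),
      pattern = c(toPat(m1), toPat(m2)))
  }
  out <- data.table::rbindlist(chunks[!vapply(chunks, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    out <- data.table::data.table(window_id = character(),
                                  sample_id = character(), hap = integer(),
                                  pattern = character())
  data.table::setattr(out, "b", b)
  data.table::setattr(out, "excluded", excluded)
  out
}

#' C-to-T transition entropy profile
#'
#' Runs the identical entropy + decomposition machinery on genetic C/T
#' haplotype patterns; every \code{\link{EntropyProfile}} invariant holds
#' with "read" meaning haplotype. Coverage minima default much lower than
#' for methylation (each individual contributes exactly two haplotypes):
#' \code{perSampleMin = 2} keeps complete diploids, \code{minReads = 4}
#' requires at least two individuals.
#'
#' @param patterns haplotype pattern table from
#'   \code{\link{genotypeToPatterns}}.
#' @param design cohort design.
#' @param windows windows from \code{\link{buildWindows}}.
#' @param sex,ecotype sample filters, as in \code{\link{entropyProfile}}.
#' @param minReads,perSampleMin coverage minima in haplotype units.
#' @return an \code{\link{EntropyProfile}} (unit: haplotypes). Windows with
#'   no segregating site get H = 0 everywhere, so delta and region
#'   comparisons are reusable unchanged.
#' @export
ctEntropyProfile <- function(patterns, design, windows, sex = NULL,
                             ecotype = NULL, minReads = 4L,
                             perSampleMin = 2L) {
  ok <- .validDesign(design)
  if (!isTRUE(ok)) stop(ok)
  samples <- design$sample_id
  if (!is.null(sex)) samples <- intersect(samples,
    design$sample_id[design$sex %in% sex])
  if (!is.null(ecotype)) samples <- intersect(samples,
    design$sample_id[design$ecotype %in% ecotype])
  if (!length(samples)) stop("no samples match the sex/ecotype filters")
  b <- attr(patterns, "b")
  if (is.null(b)) b <- metadata(windows)$b
  tally <- patterns[, list(n = .N),
                    by = c("window_id", "sample_id", "pattern")]
  .profileFromTally(tally, windows, design, samples, b, minReads,
                    perSampleMin, unit = "haplotypes",
                    extraMeta = list(sex = sex, ecotype = ecotype))
}

#' Classify the source of an entropy difference (genetic vs epigenetic)
#'
#' Implements the control's decision rule: if the C->T transition entropy
#' differs significantly between ecotypes within the region set (Wilcoxon on
#' per-window between-individual components), the signal is consistent with
#' mutation-derived C->T substitutions ("genetic"); otherwise the
#' methylation entropy difference reflects genuine epigenetic variability
#' ("epigenetic").
#'
#' @param ctFresh,ctMarine C->T \code{\link{EntropyProfile}}s per ecotype.
#' @param assignment \code{\link{assignWindows}} result defining the region
#'   windows (zone \code{"core"}).
#' @param alpha significance level.
#' @return list(verdict, p_value, n_windows).
#' @export
classifyEntropySource <- function(ctFresh, ctMarine, assignment,
                                  alpha = 0.05) {
  if (!identical(windowIds(ctFresh), windowIds(ctMarine)))
    stop("profiles were computed on different window universes")
  inRegion <- assignment$zone == "core"
  a <- entropyBetween(ctFresh)[inRegion]
  b <- entropyBetween(ctMarine)[inRegion]
  if (!any(is.finite(a)) || !any(is.finite(b)))
    return(list(verdict = "epigenetic", p_value = NA_real_, n_windows = 0L))
  cmp <- compareGroups(a, b)
  list(verdict = if (is.finite(cmp$p_value) && cmp$p_value < alpha)
    "genetic" else "epigenetic",
    p_value = cmp$p_value,
    n_windows = sum(is.finite(a) & is.finite(b)))
}
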