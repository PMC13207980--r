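## Integration of promoter entropy with transcriptional variability, mean
## methylation (beta-values) and chromatin accessibility.

#' Median-of-ratios normalization
#'
#' The reference pseudo-sample is the per-gene geometric mean over samples
#' (genes with any zero count are excluded from factor estimation); each
#' sample's size factor is the median of its count-to-reference ratios, and
#' normalized counts are raw counts divided by the factor. Because the
#' reference includes every sample, multiplying one sample's column by c
#' multiplies the size-factor ratios involving it by c exactly, and changes
#' normalized values only by a common global rescaling (c to the power 1/n).
#'
#' @param counts feature-by-sample count matrix (>= 2 samples).
#' @return list(sizeFactors, normalized).
#' @examples
#' m <- cbind(a = c(10, 20), b = c(20, 40))
#' medianOfRatiosNormalize(m)$sizeFactors
#' @export
medianOfRatiosNormalize <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  useG <- rowSums(counts > 0) == ncol(counts)
  if (!any(useG))
    stop("no gene with nonzero counts in all samples; cannot estimate size factors")
  logRef <- rowMeans(log(counts[useG, , drop = FALSE]))
  sf <- apply(counts[useG, , drop = FALSE], 2L, function(col)
    exp(median(log(col) - logRef)))
  list(sizeFactors = sf,
       normalized = sweep(counts, 2L, sf, "/"))
}

#' Per-gene expression variability by ecotype
#'
#' Sample standard deviation (n - 1 denominator) of normalized counts across
#' individuals within each ecotype, and their difference
#' (freshwater - marine). Variance is exposed as an option. Genes with zero
#' counts in every sample are excluded; groups with fewer than two samples
#' yield NA.
#'
#' @param normalized normalized count matrix (see
#'   \code{\link{medianOfRatiosNormalize}}).
#' @param design data.frame(sample_id, ecotype) covering the columns.
#' @param measure \code{"sd"} (default) or \code{"variance"}.
#' @return data.frame(gene, sd_freshwater, sd_marine, dVar, mean_expr); the
#'   two spread columns are variances when \code{measure = "variance"}.
#' @export
expressionVariability <- function(normalized, design, measure = c("sd", "variance")) {
  measure <- match.arg(measure)
  samples <- colnames(normalized)
  if (is.null(samples)) stop("normalized matrix must have sample column names")
  eco <- design$ecotype[match(samples, design$sample_id)]
  if (anyNA(eco)) stop("design must cover every sample column")
  keep <- rowSums(normalized) > 0
  m <- normalized[keep, , drop = FALSE]
  spread <- function(cols) {
    if (length(cols) < 2L) return(rep(NA_real_, nrow(m)))
    v <- apply(m[, cols, drop = FALSE], 1L, sd)
    if (measure == "variance") v^2 else v
  }
  sf <- spread(which(eco == "freshwater"))
  sm <- spread(which(eco == "marine"))
  data.frame(gene = rownames(m), sd_freshwater = sf, sd_marine = sm,
             dVar = sf - sm, mean_expr = rowMeans(m),
             stringsAsFactors = FALSE)
}

#' Promoter-level entropy differences
#'
#' Promoters are the 1000 bp upstream of the TSS, strand-aware:
#' [TSS - 1000, TSS) on the + strand, (TSS, TSS + 1000] on the - strand
#' (0-based half-open), clipped at position 0. A gene's dHb is the mean
#' delta over windows whose central CpG falls inside the promoter; NA when
#' no window with a defined delta does.
#'
#' @param tss data.frame(gene, chrom, tss0, strand) from
#'   \code{\link{readTss}}.
#' @param delta a \code{\link{deltaBetween}} data.frame.
#' @param upstream promoter length in bp.
#' @return data.frame(gene, chrom, promoter_start0, promoter_end0,
#'   n_windows, dHb).
#' @export
promoterDeltaTable <- function(tss, delta, upstream = 1000L) {
  ps <- ifelse(tss$strand == "+", tss$tss0 - upstream, tss$tss0 + 1L)
  pe <- ifelse(tss$strand == "+", tss$tss0, tss$tss0 + 1L + upstream)
  ps <- pmax(ps, 0L)
  prom <- .granges0(tss$chrom, ps, pe)
  d <- delta[is.finite(delta$delta), , drop = FALSE]
  hits <- findOverlaps(.points0(d$chrom, d$central_pos0), prom)
  agg <- tapply(d$delta[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), mean)
  nw <- table(S4Vectors::subjectHits(hits))
  out <- data.frame(gene = tss$gene, chrom = tss$chrom,
                    promoter_start0 = as.integer(ps),
                    promoter_end0 = as.integer(pe),
                    n_windows = 0L, dHb = NA_real_,
                    stringsAsFactors = FALSE)
  idx <- as.integer(names(agg))
  out$dHb[idx] <- as.numeric(agg)
  out$n_windows[as.integer(names(nw))] <- as.integer(nw)
  out
}

#' Association between promoter entropy and expression variability
#'
#' Pearson correlation of promoter dHb against per-gene dVar over genes
#' with both defined, plus the exploratory candidate set: genes at or above
#' the 75th percentile (inclusive, ties kept) of BOTH axes. Thresholds are
#' rank-based, so candidate selection is invariant to monotone transforms.
#'
#' @param promoters \code{\link{promoterDeltaTable}} output.
#' @param variability \code{\link{expressionVariability}} output.
#' @param threshold quantile for candidate selection (default 0.75).
#' @return list(r, p_value, n, candidates, thresholds); \code{r} is NA with
#'   a warning when either axis is constant.
#' @export
entropyExpressionAssociation <- function(promoters, variability,
                                         threshold = 0.75) {
  m <- merge(promoters[, c("gene", "dHb")],
             variability[, c("gene", "dVar", "mean_expr")], by = "gene")
  m <- m[complete.cases(m[, c("dHb", "dVar")]), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 genes with both values defined")
  thrH <- quantile(m$dHb, threshold, names = FALSE)
  thrV <- quantile(m$dVar, threshold, names = FALSE)
  cand <- m[m$dHb >= thrH & m$dVar >= thrV, , drop = FALSE]
  if (sd(m$dHb) == 0 || sd(m$dVar) == 0) {
    warning("constant dHb or dVar; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(m),
                candidates = cand, thresholds = c(dHb = thrH, dVar = thrV)))
  }
  ct <- cor.test(m$dHb, m$dVar, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(m),
       candidates = cand, thresholds = c(dHb = thrH, dVar = thrV))
}

#' Per-site beta-values and ecotype comparison
#'
#' beta = methylated reads / total reads per CpG site, pooled within each
#' ecotype, with a per-site coverage minimum. Freshwater and marine
#' beta-values are compared genome-wide and within the supplied regions
#' (site inside a core interval) by \code{\link{compareGroups}}. Pooling
#' reads then computing beta equals the coverage-weighted mean of
#' per-sample betas, exactly.
#'
#' @param x an \code{\link{EpireadSet}}.
#' @param regions optional \code{\link{RegionSet}} for the region stratum.
#' @param minCov per-site, per-ecotype minimum coverage (default 5).
#' @param sex optional sex filter.
#' @return list(beta, comparisons): \code{beta} has one row per (site,
#'   ecotype) passing coverage; \code{comparisons} one row per stratum.
#' @export
betaValueCompare <- function(x, regions = NULL, minCov = 5L, sex = NULL) {
  design <- cohortDesign(x)
  r <- epireads(x)
  if (!is.null(sex)) {
    keep <- r$sample_id %in% design$sample_id[design$sex %in% sex]
    r <- r[keep, , drop = FALSE]
  }
  if (nrow(r) == 0L) stop("no reads after filtering")
  len <- lengths(r$positions)
  idxAll <- sequence(len)
  readAll <- rep(seq_len(nrow(r)), len)
  dt <- data.table::data.table(
    chrom = rep(r$chrom, len),
    pos0 = unlist(r$positions, use.names = FALSE),
    ecotype = design$ecotype[match(rep(r$sample_id, len),
                                   design$sample_id)],
    meth = substr(r$pattern[readAll], idxAll, idxAll) == "M")
  site <- dt[, list(meth = sum(meth), total = .N),
             by = c("chrom", "pos0", "ecotype")]
  site <- site[site$total >= minCov]
  site[, beta := meth / total]
  data.table::setorder(site, chrom, pos0, ecotype)
  bf <- site$beta[site$ecotype == "freshwater"]
  bm <- site$beta[site$ecotype == "marine"]
  rows <- list()
  if (length(bf) && length(bm))
    rows$genome <- cbind(data.frame(stratum = "genome",
                                    stringsAsFactors = FALSE),
                         compareGroups(bf, bm))
  if (!is.null(regions)) {
    core <- coreRegions(regions)
    inRegion <- !is.na(findOverlaps(.points0(site$chrom, site$pos0), core,
                                    select = "first"))
    rf <- site$beta[inRegion & site$ecotype == "freshwater"]
    rm <- site$beta[inRegion & site$ecotype == "marine"]
    if (length(rf) && length(rm))
      rows$region <- cbind(data.frame(stratum = "region",
                                      stringsAsFactors = FALSE),
                           compareGroups(rf, rm))
  }
  list(beta = as.data.frame(site),
       comparisons = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Chromatin accessibility comparison on normalized counts
#'
#' Counts-per-million normalization per sample (invariant to scaling any
#' sample's library), per-peak ecotype means, and Wilcoxon comparisons
#' genome-wide and for peaks overlapping the supplied regions. log2(x + 1)
#' is applied to report columns only, never to the tested values.
#'
#' @param counts peak-by-sample count matrix.
#' @param design data.frame(sample_id, ecotype) covering the columns.
#' @param peaks \code{GRanges} of the peaks, same order as rows.
#' @param regions optional \code{\link{RegionSet}}.
#' @return list(table, comparisons).
#' @export
accessibilityCompare <- function(counts, design, peaks = NULL,
                                 regions = NULL) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size")
  eco <- design$ecotype[match(colnames(counts), design$sample_id)]
  if (anyNA(eco)) stop("design must cover every sample column")
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  mf <- rowMeans(cpm[, eco == "freshwater", drop = FALSE])
  mm <- rowMeans(cpm[, eco == "marine", drop = FALSE])
  tab <- data.frame(peak = rownames(counts),
                    mean_freshwater = mf, mean_marine = mm,
                    log2_mean_freshwater = log2(mf + 1),
                    log2_mean_marine = log2(mm + 1),
                    stringsAsFactors = FALSE)
  rows <- list(cbind(data.frame(stratum = "genome", stringsAsFactors = FALSE),
                     compareGroups(mf, mm)))
  if (!is.null(regions) && !is.null(peaks)) {
    inRegion <- !is.na(findOverlaps(peaks, coreRegions(regions),
                                    select = "first"))
    tab$in_region <- inRegion
    if (any(inRegion))
      rows$region <- cbind(data.frame(stratum = "region",
                                      stringsAsFactors = FALSE),
                           compareGroups(mf[inRegion], mm[inRegion]))
  }
  list(table = tab,
       comparisons = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
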