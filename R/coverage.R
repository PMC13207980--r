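## Coverage matching. Sequencing depth is equalized across samples before
## entropy is computed: fragments are counted in fixed 1-kb bins, the
## group-wise (per-sex) minimum per bin becomes the target, and each sample
## is downsampled to that target. Plug-in entropy grows with read count, so
## unequal depth would masquerade as unequal diversity.

#' Count fragments per fixed genomic bin
#'
#' Each fragment is assigned to exactly one bin: the bin containing its first
#' CpG position (single assignment keeps read sets disjoint across bins,
#' which entropy tallying requires).
#'
#' @param x an \code{\link{EpireadSet}}.
#' @param binSize bin length in bp; bins tile each chromosome with step =
#'   length.
#' @return integer matrix, rows = bins (named \code{"chrom:start0"}), columns
#'   = every sample in the design (samples without reads get zero columns).
#'   Bin size is attached as \code{attr(x, "binSize")}.
#' @export
countFragmentsPerBin <- function(x, binSize = 1000L) {
  binSize <- as.integer(binSize)
  r <- epireads(x)
  samples <- cohortDesign(x)$sample_id
  if (nrow(r) == 0L) {
    m <- matrix(0L, 0L, length(samples), dimnames = list(NULL, samples))
    attr(m, "binSize") <- binSize
    return(m)
  }
  len <- lengths(r$positions)
  u <- unlist(r$positions, use.names = FALSE)
  firstPos <- u[cumsum(len) - len + 1L]
  binStart <- (firstPos %/% binSize) * binSize
  key <- paste0(r$chrom, ":", binStart)
  cnt <- data.table::data.table(bin = key, sample_id = r$sample_id)[
    , list(n = .N), by = c("bin", "sample_id")]
  bins <- sort(unique(cnt$bin))
  m <- matrix(0L, length(bins), length(samples),
              dimnames = list(bins, samples))
  m[cbind(match(cnt$bin, bins), match(cnt$sample_id, samples))] <- cnt$n
  attr(m, "binSize") <- binSize
  m
}

#' Group-minimum downsampling targets
#'
#' For every bin, the target for each sample is the minimum fragment count
#' over all samples of its group. The default grouping is sex: all male
#' samples (both ecotypes) form one pool and all female samples the other,
#' computed independently, so ecotype comparisons within a sex are made at
#' identical depth. A zero count in any group member zeroes the bin for the
#' whole group (the bin is effectively dropped).
#'
#' @param cov bin-by-sample count matrix from
#'   \code{\link{countFragmentsPerBin}}.
#' @param design cohort design covering every column of \code{cov}.
#' @param groupBy design column to group by (\code{"sex"} by default).
#' @return integer matrix of the same shape as \code{cov}: per-sample
#'   targets (equal within a group). Grouping and bin size are attached as
#'   attributes.
#' @export
groupMinimumTargets <- function(cov, design, groupBy = "sex") {
  samples <- colnames(cov)
  miss <- setdiff(samples, design$sample_id)
  if (length(miss))
    stop(sprintf("samples missing from design: %s", paste(miss, collapse = ", ")))
  grp <- design[[groupBy]][match(samples, design$sample_id)]
  targets <- cov
  for (g in unique(grp)) {
    cols <- which(grp == g)
    gmin <- if (length(cols) == 1L) cov[, cols] else
      apply(cov[, cols, drop = FALSE], 1L, min)
    targets[, cols] <- gmin
  }
  attr(targets, "binSize") <- attr(cov, "binSize")
  attr(targets, "groupBy") <- groupBy
  targets
}

#' Downsample reads to per-bin targets
#'
#' Keeps, per (sample, bin), a uniform random subset of exactly the target
#' number of fragments (sampling without replacement). Each (sample, bin)
#' cell uses its own RNG stream seeded from \code{seed} and a hash of the
#' cell's key, and candidates are ordered by read id first, so the surviving
#' set is reproducible and independent of read-file order. When the target
#' equals the available count all reads are kept regardless of seed.
#'
#' @param x an \code{\link{EpireadSet}}.
#' @param targets target matrix from \code{\link{groupMinimumTargets}}.
#' @param seed integer seed for the downsampling streams.
#' @param binSize bin length; defaults to the value recorded in
#'   \code{targets}.
#' @return a new \code{\link{EpireadSet}} whose recomputed
#'   \code{\link{countFragmentsPerBin}} equals \code{targets} exactly.
#' @export
downsampleReads <- function(x, targets, seed,
                            binSize = attr(targets, "binSize")) {
  if (is.null(binSize)) stop("binSize not given and not recorded in targets")
  r <- epireads(x)
  if (nrow(r) == 0L) return(x)
  len <- lengths(r$positions)
  u <- unlist(r$positions, use.names = FALSE)
  firstPos <- u[cumsum(len) - len + 1L]
  binKey <- paste0(r$chrom, ":", (firstPos %/% binSize) * binSize)
  rowI <- match(binKey, rownames(targets))
  colI <- match(r$sample_id, colnames(targets))
  if (anyNA(rowI) || anyNA(colI))
    stop("targets matrix does not cover every (bin, sample) with reads")
  dt <- data.table::data.table(i = seq_len(nrow(r)),
                               sample_id = r$sample_id,
                               bin = binKey, read_id = r$read_id,
                               tgt = targets[cbind(rowI, colI)])
  ## candidates ordered by read id up front, so each cell's draw is
  ## independent of read-file order
  data.table::setorder(dt, sample_id, bin, read_id)
  sel <- dt[, {
    tg <- tgt[1L]
    if (tg > .N)
      stop(sprintf("target %d exceeds %d available reads in %s / %s",
                   tg, .N, bin[1L], sample_id[1L]))
    if (tg == .N) {
      list(i = i)
    } else if (tg == 0L) {
      list(i = integer(0))
    } else {
      set.seed((seed + .strHash(paste0(sample_id[1L], "|", bin[1L]))) %%
                 2147483647L)
      list(i = i[sample.int(.N, tg)])
    }
  }, by = c("sample_id", "bin")]
  keep <- sort(sel$i)
  .EpireadSetUnchecked(r[keep, , drop = FALSE], cohortDesign(x))
}
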