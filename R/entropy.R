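## Sliding-window epiallele tallies and the entropy decomposition. This is
## the package's core statistic:
##
##   H = -(1/b) * sum_i (n_i / N) * log2(n_i / N)
##
## over the k distinct epialleles observed among the N reads fully covering a
## window of b CpGs (0 * log 0 == 0; k <= min(N, 2^b)). Pooled-group entropy
## decomposes as H_pooled = H_within + H_between where H_within is the
## coverage-weighted mean of per-sample entropies and H_between (the
## inter-individual component) equals the mutual information between sample
## identity and epiallele divided by b; concavity of entropy makes it
## non-negative.

#' Build sliding CpG windows
#'
#' Windows of \code{b} consecutive CpGs advancing by \code{step} CpGs, built
#' per chromosome from the CpG universe (a chromosome with m CpGs yields
#' max(0, m - b + 1) windows at step 1). Windows never span chromosomes.
#'
#' @param cpgMap a \code{\link{CpGMap}}.
#' @param b window size in CpGs (>= 2); 5 by default, 4 and 6 are the usual
#'   robustness variants.
#' @param step step in CpGs.
#' @return a \code{GRanges}, one row per window, with mcols \code{window_id}
#'   (\code{"chrom:ord"} where ord is the 1-based ordinal of the first CpG),
#'   \code{ord}, \code{central_pos0} (0-based position of the central CpG,
#'   site ceiling(b/2), used for region assignment) and \code{positions}
#'   (IntegerList of the b 0-based CpG coordinates). The CpG universe, b and
#'   step travel along in \code{metadata()}.
#' @examples
#' m <- CpGMap(list(chr1 = as.integer(c(10, 20, 30, 40, 50, 60, 70))))
#' length(buildWindows(m, b = 5))  # 3
#' @export
buildWindows <- function(cpgMap, b = 5L, step = 1L) {
  b <- as.integer(b)
  step <- as.integer(step)
  if (b < 2L) stop("b must be >= 2")
  if (step < 1L) stop("step must be >= 1")
  sites <- cpgSites(cpgMap)
  pieces <- lapply(names(sites), function(chr) {
    p <- sites[[chr]]
    m <- length(p)
    if (m < b) return(NULL)
    ords <- seq.int(1L, m - b + 1L, by = step)
    list(chrom = rep(chr, length(ords)), ord = ords,
         first = p[ords], last = p[ords + b - 1L],
         central = p[ords + as.integer(ceiling(b / 2)) - 1L],
         pos = lapply(ords, function(o) p[o:(o + b - 1L)]))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    gr <- GRanges()
    metadata(gr) <- list(b = b, step = step, sites = sites)
    return(gr)
  }
  chrom <- unlist(lapply(pieces, `[[`, "chrom"))
  ords <- unlist(lapply(pieces, `[[`, "ord"))
  gr <- .granges0(chrom, unlist(lapply(pieces, `[[`, "first")),
                  unlist(lapply(pieces, `[[`, "last")) + 1L)
  mcols(gr)$window_id <- paste0(chrom, ":", ords)
  mcols(gr)$ord <- ords
  mcols(gr)$central_pos0 <- unlist(lapply(pieces, `[[`, "central"))
  mcols(gr)$positions <- IRanges::IntegerList(
    do.call(c, lapply(pieces, `[[`, "pos")))
  metadata(gr) <- list(b = b, step = step, sites = sites)
  gr
}

#' Tally epialleles per window and sample
#'
#' A read contributes to a window iff it covers all b CpGs of that window
#' with unambiguous calls; its epiallele is the b-character substring of its
#' pattern over those sites. A long read contributes to every sliding window
#' it fully covers; partial overlaps are silently excluded (counted in the
#' \code{qc} attribute). Read positions not present in the CpG universe break
#' a read into separately tallied runs.
#'
#' @param x an \code{\link{EpireadSet}}.
#' @param windows windows from \code{\link{buildWindows}}.
#' @return a \code{data.table} with columns \code{window_id},
#'   \code{sample_id}, \code{pattern}, \code{n}, sorted canonically (so equal
#'   tallies hash equal regardless of read order). Attributes: \code{b} and
#'   \code{qc} (number of reads contributing to no window).
#' @export
tallyEpialleles <- function(x, windows) {
  b <- metadata(windows)$b
  sites <- metadata(windows)$sites
  if (is.null(b) || is.null(sites))
    stop("windows must come from buildWindows()")
  r <- epireads(x)
  empty <- data.table::data.table(window_id = character(),
                                  sample_id = character(),
                                  pattern = character(), n = integer())
  if (nrow(r) == 0L) {
    data.table::setattr(empty, "b", b)
    data.table::setattr(empty, "qc", c(readsExcluded = 0L))
    return(empty)
  }
  ## concatenated site vector with per-chromosome offsets; a read position
  ## maps to global ordinal gOrd, and chromosome-local ordinal ord
  chrOff <- c(0L, cumsum(lengths(sites)))[seq_along(sites)]
  names(chrOff) <- names(sites)
  siteVec <- unlist(sites, use.names = FALSE)
  nSite <- length(siteVec)
  len <- lengths(r$positions)
  ends <- cumsum(len)
  firstPos <- unlist(r$positions, use.names = FALSE)[ends - len + 1L]
  readChrOff <- chrOff[r$chrom]
  ## fast path: reads whose positions are exactly a contiguous block of the
  ## CpG universe. Locate the first position, then check the whole read
  ## against the site vector in one vectorized comparison.
  ordFirstLocal <- rep(NA_integer_, nrow(r))
  for (chr in unique(r$chrom)) {
    i <- which(r$chrom == chr & !is.na(readChrOff[r$chrom]))
    if (length(i))
      ordFirstLocal[i] <- match(firstPos[i], sites[[chr]])
  }
  gFirst <- readChrOff + ordFirstLocal
  chromLen <- lengths(sites)[r$chrom]
  inBounds <- !is.na(ordFirstLocal) & (ordFirstLocal + len - 1L) <= chromLen
  uread <- rep(seq_len(nrow(r)), len)
  uidx <- sequence(len)
  upos <- unlist(r$positions, use.names = FALSE)
  expectIdx <- gFirst[uread] + uidx - 1L
  okPos <- inBounds[uread] & expectIdx >= 1L & expectIdx <= nSite
  okPos[okPos] <- siteVec[expectIdx[okPos]] == upos[okPos]
  nOk <- rowsum(as.integer(okPos), uread, reorder = TRUE)[, 1L]
  contiguous <- inBounds & nOk == len
  pieces <- list()
  ## contiguous reads: windows startOrd = ord1 .. ord1 + len - b
  ci <- which(contiguous & len >= b)
  if (length(ci)) {
    nw <- len[ci] - b + 1L
    off <- sequence(nw) - 1L
    readV <- rep(ci, nw)
    pieces$fast <- data.table::data.table(
      read = readV,
      chrom = rep(r$chrom[ci], nw),
      startOrd = rep(ordFirstLocal[ci], nw) + off,
      startIdx = off + 1L)
  }
  ## general path (gapped or partially unmapped reads): split into maximal
  ## runs of consecutive CpG ordinals that are also consecutive within the
  ## read, so the pattern substring is well defined
  gi <- which(!contiguous)
  if (length(gi)) {
    sel <- uread %in% gi
    u <- data.table::data.table(read = uread[sel], idx = uidx[sel],
                                chrom = r$chrom[uread[sel]],
                                pos = upos[sel])
    mapDT <- data.table::data.table(
      chrom = rep(names(sites), lengths(sites)),
      pos = siteVec,
      ord = unlist(lapply(sites, seq_along), use.names = FALSE))
    u <- mapDT[u, on = c("chrom", "pos")]
    u <- u[!is.na(ord)]
    if (nrow(u)) {
      brk <- c(TRUE, !(diff(u$read) == 0L & diff(u$ord) == 1L &
                         diff(u$idx) == 1L))
      u[, run := cumsum(brk)]
      runs <- u[, list(read = read[1L], chrom = chrom[1L],
                       startIdx = idx[1L], startOrd = ord[1L], len = .N),
                by = run]
      runs <- runs[len >= b]
      if (nrow(runs)) {
        nw <- runs$len - b + 1L
        off <- sequence(nw) - 1L
        pieces$slow <- data.table::data.table(
          read = rep(runs$read, nw),
          chrom = rep(runs$chrom, nw),
          startOrd = rep(runs$startOrd, nw) + off,
          startIdx = rep(runs$startIdx, nw) + off)
      }
    }
  }
  contributing <- integer(0)
  tally <- empty
  if (length(pieces)) {
    contrib <- data.table::rbindlist(pieces)
    winId <- paste0(contrib$chrom, ":", contrib$startOrd)
    keep <- winId %in% mcols(windows)$window_id
    if (any(keep)) {
      readV <- contrib$read[keep]
      startIdxV <- contrib$startIdx[keep]
      pat <- substr(r$pattern[readV], startIdxV, startIdxV + b - 1L)
      contributing <- unique(readV)
      tally <- data.table::data.table(
        window_id = winId[keep], sample_id = r$sample_id[readV],
        pattern = pat)[, list(n = .N),
                       by = c("window_id", "sample_id", "pattern")]
      data.table::setorder(tally, window_id, sample_id, pattern)
    }
  }
  data.table::setattr(tally, "b", b)
  data.table::setattr(tally, "qc",
                      c(readsExcluded = nrow(r) - length(contributing)))
  tally
}

#' Normalized window entropy from epiallele counts
#'
#' \code{H = -(1/b) sum_i (n_i/N) log2(n_i/N)} with the 0 log 0 == 0
#' convention. Undefined (\code{NA}) below the pooled coverage minimum; the
#' default of 32 reads matches the size of the 5-CpG pattern space, so a
#' window can in principle realize every epiallele.
#'
#' @param counts integer vector of epiallele counts (zeros allowed).
#' @param b window size in CpGs.
#' @param minReads minimum total reads for H to be defined.
#' @return H in [0, min(log2 N, b)/b], or NA.
#' @examples
#' windowEntropy(c(MMMMM = 16, UUUUU = 16), b = 5)         # 0.2
#' windowEntropy(rep(1, 32), b = 5, minReads = 32)         # 1
#' @export
windowEntropy <- function(counts, b = 5L, minReads = 32L) {
  N <- sum(counts)
  if (N < minReads || N == 0L) return(NA_real_)
  .H(counts, b)
}

#' Entropy decomposition for one window
#'
#' Splits pooled-group entropy into within- and between-sample components:
#' \code{H_pooled} is the entropy of the summed counts over qualifying
#' samples, \code{H_within = sum_s (N_s/N) H_s}, and
#' \code{H_between = H_pooled - H_within}, i.e. the mutual information
#' between sample label and epiallele divided by b. Samples below
#' \code{perSampleMin} reads are excluded from the decomposition (a per-
#' sample plug-in entropy over 2-3 reads is degenerate); with fewer than two
#' qualifying samples the between component is undefined.
#'
#' @param tallies named list, sample -> named epiallele count vector.
#' @param b window size in CpGs.
#' @param minReads minimum pooled reads (over qualifying samples).
#' @param perSampleMin minimum reads for a sample to enter the decomposition.
#' @return list with \code{H_pooled}, \code{H_within}, \code{H_between},
#'   \code{H_sample}, \code{N_sample}, \code{N_total}, \code{qc}.
#' @examples
#' decomposeEntropy(list(a = c(MMMMM = 16), b = c(UUUUU = 16)),
#'                  b = 5, minReads = 32, perSampleMin = 8)
#' @export
decomposeEntropy <- function(tallies, b = 5L, minReads = 32L,
                             perSampleMin = 8L) {
  Ns <- vapply(tallies, sum, numeric(1))
  out <- list(H_pooled = NA_real_, H_within = NA_real_, H_between = NA_real_,
              H_sample = setNames(rep(NA_real_, length(Ns)), names(Ns)),
              N_sample = Ns, N_total = 0, qc = "ok")
  ok <- Ns >= perSampleMin
  pooledN <- sum(Ns[ok])
  out$N_total <- pooledN
  if (pooledN < minReads) {
    out$qc <- "low_coverage"
    return(out)
  }
  pooled <- tapply(
    unlist(lapply(tallies[ok], as.numeric), use.names = FALSE),
    unlist(lapply(tallies[ok], names), use.names = FALSE), sum)
  out$H_pooled <- .H(pooled, b)
  out$H_sample[ok] <- vapply(tallies[ok], .H, numeric(1), b = b)
  if (sum(ok) < 2L) {
    out$qc <- "few_samples"
    return(out)
  }
  out$H_within <- sum(Ns[ok] / pooledN * out$H_sample[ok])
  out$H_between <- out$H_pooled - out$H_within
  out
}

## Shared engine: tally (long data.table) -> EntropyProfile. Used for both
## methylation epireads and C->T haplotype patterns.
.profileFromTally <- function(tally, windows, design, samples, b,
                              minReads, perSampleMin, unit = "reads",
                              extraMeta = list()) {
  wid <- mcols(windows)$window_id
  nW <- length(wid)
  nS <- length(samples)
  Nmat <- matrix(0, nW, nS, dimnames = list(wid, samples))
  Hmat <- matrix(NA_real_, nW, nS, dimnames = list(wid, samples))
  t <- tally[tally$sample_id %in% samples]
  if (nrow(t)) {
    NsAll <- t[, list(N_s = sum(n)), by = c("window_id", "sample_id")]
    Nmat[cbind(match(NsAll$window_id, wid), match(NsAll$sample_id, samples))] <-
      NsAll$N_s
    NsOK <- NsAll[NsAll$N_s >= perSampleMin, c("window_id", "sample_id")]
    t2 <- t[NsOK, on = c("window_id", "sample_id")]
  } else {
    t2 <- t
  }
  Hp <- Hw <- Hb <- rep(NA_real_, nW)
  Ntot <- rep(0, nW)
  qc <- rep("low_coverage", nW)
  if (nrow(t2)) {
    Hs <- t2[, list(H_s = .H(n, b), N_s = sum(n)),
             by = c("window_id", "sample_id")]
    Hmat[cbind(match(Hs$window_id, wid), match(Hs$sample_id, samples))] <-
      Hs$H_s
    pool <- t2[, list(n = sum(n)), by = c("window_id", "pattern")]
    poolW <- pool[, list(H_pooled = .H(n, b), N_total = sum(n)),
                  by = "window_id"]
    within <- Hs[, list(H_within = sum(N_s / sum(N_s) * H_s), S = .N),
                 by = "window_id"]
    res <- merge(poolW, within, by = "window_id")
    i <- match(res$window_id, wid)
    Ntot[i] <- res$N_total
    covOK <- res$N_total >= minReads
    Hp[i[covOK]] <- res$H_pooled[covOK]
    qc[i[covOK]] <- ifelse(res$S[covOK] >= 2L, "ok", "few_samples")
    decOK <- covOK & res$S >= 2L
    Hw[i[decOK]] <- res$H_within[decOK]
    Hb[i[decOK]] <- res$H_pooled[decOK] - res$H_within[decOK]
  }
  rd <- mcols(windows)[, c("window_id", "ord", "central_pos0")]
  rd$N_total <- Ntot
  rd$H_pooled <- Hp
  rd$H_within <- Hw
  rd$H_between <- Hb
  rd$qc <- qc
  rr <- granges(windows)
  mcols(rr) <- rd
  cd <- design[match(samples, design$sample_id), , drop = FALSE]
  rownames(cd) <- samples
  se <- SummarizedExperiment(assays = list(N = Nmat, H = Hmat),
                             rowRanges = rr, colData = as(cd, "DataFrame"))
  metadata(se) <- c(list(b = b, minReads = minReads,
                         perSampleMin = perSampleMin, unit = unit),
                    extraMeta)
  new("EntropyProfile", se)
}

#' Per-window entropy profile for a sample group
#'
#' Tallies epialleles (unless a precomputed tally is supplied) and runs the
#' entropy decomposition for every window, restricted to the samples matching
#' the \code{sex}/\code{ecotype} filters. Sexes are processed independently
#' throughout the package, mirroring the sex-stratified coverage matching.
#'
#' @param x an \code{\link{EpireadSet}} (coverage-matched; see
#'   \code{\link{downsampleReads}}).
#' @param windows windows from \code{\link{buildWindows}}.
#' @param sex,ecotype optional filters selecting the sample group.
#' @param minReads pooled coverage minimum for a window (default 32 = 2^5).
#' @param perSampleMin per-sample minimum to enter the decomposition.
#' @param tally optional precomputed \code{\link{tallyEpialleles}} result
#'   (it is filtered to the selected samples internally, so one tally can
#'   serve several group profiles).
#' @return an \code{\link{EntropyProfile}}.
#' @export
entropyProfile <- function(x, windows, sex = NULL, ecotype = NULL,
                           minReads = 32L, perSampleMin = 8L, tally = NULL) {
  design <- cohortDesign(x)
  samples <- design$sample_id
  if (!is.null(sex)) samples <- intersect(samples,
    design$sample_id[design$sex %in% sex])
  if (!is.null(ecotype)) samples <- intersect(samples,
    design$sample_id[design$ecotype %in% ecotype])
  if (!length(samples)) stop("no samples match the sex/ecotype filters")
  if (is.null(tally)) tally <- tallyEpialleles(x, windows)
  b <- attr(tally, "b")
  .profileFromTally(tally, windows, design, samples, b, minReads,
                    perSampleMin, unit = "reads",
                    extraMeta = list(sex = sex, ecotype = ecotype))
}

#' Per-window between-sample entropy difference (freshwater minus marine)
#'
#' @param profileFresh,profileMarine \code{\link{EntropyProfile}} objects for
#'   the two ecotypes, computed on the same window universe and the same sex
#'   (mismatched windows are an error).
#' @return data.frame(window_id, chrom, start0, central_pos0,
#'   H_between_freshwater, H_between_marine, delta); \code{delta} is NA
#'   wherever either between-component is undefined.
#' @export
deltaBetween <- function(profileFresh, profileMarine) {
  wf <- windowIds(profileFresh)
  wm <- windowIds(profileMarine)
  if (!identical(wf, wm))
    stop("profiles were computed on different window universes")
  sf <- metadata(profileFresh)$sex
  sm <- metadata(profileMarine)$sex
  if (!identical(sf, sm))
    warning("profiles carry different sex filters; deltas compare across sexes")
  rr <- rowRanges(profileFresh)
  hf <- rowData(profileFresh)$H_between
  hm <- rowData(profileMarine)$H_between
  data.frame(window_id = wf,
             chrom = as.character(seqnames(rr)),
             start0 = start(rr) - 1L,
             central_pos0 = mcols(rr)$central_pos0,
             H_between_freshwater = hf,
             H_between_marine = hm,
             delta = hf - hm,
             stringsAsFactors = FALSE)
}
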