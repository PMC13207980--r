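## Region-level comparisons: assign windows to region sets (divergence
## islands, EcoPeaks, promoters, ...), compare entropy between ecotypes with
## the Wilcoxon rank-sum test, and decompose the freshwater bias over
## quantiles of |delta H_between|.

#' Assign windows to regions by their central CpG
#'
#' A window belongs to a region iff its central CpG (site ceiling(b/2)) lies
#' inside the interval -- an unambiguous rule that treats core and flank
#' symmetrically. Windows centered in the flank-expanded interval but not in
#' the core get zone \code{"flank"}; all others are \code{"background"}.
#' Regions that overlap after flanking trigger a warning and the first (in
#' file order) wins.
#'
#' @param x windows (\code{GRanges} from \code{\link{buildWindows}}), an
#'   \code{\link{EntropyProfile}}, or a \code{\link{deltaBetween}}
#'   data.frame -- anything carrying \code{window_id}, \code{chrom} and
#'   \code{central_pos0}.
#' @param regions a \code{\link{RegionSet}}.
#' @return data.frame(window_id, region, zone) with zone in
#'   \code{c("core", "flank", "background")}; \code{region} is NA for
#'   background windows.
#' @export
assignWindows <- function(x, regions) {
  if (is(x, "EntropyProfile")) {
    df <- data.frame(window_id = windowIds(x),
                     chrom = as.character(seqnames(rowRanges(x))),
                     central_pos0 = rowData(x)$central_pos0,
                     stringsAsFactors = FALSE)
  } else if (is(x, "GRanges")) {
    df <- data.frame(window_id = mcols(x)$window_id,
                     chrom = as.character(seqnames(x)),
                     central_pos0 = mcols(x)$central_pos0,
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)[, c("window_id", "chrom", "central_pos0")]
  }
  core <- coreRegions(regions)
  flanked <- flankedRegions(regions)
  if (length(flanked) > 1L &&
      length(reduce(flanked, min.gapwidth = 0L)) < length(flanked))
    warning("regions overlap after flanking; first region in file order wins")
  centers <- .points0(df$chrom, df$central_pos0)
  hitCore <- findOverlaps(centers, core, select = "first")
  hitFlank <- findOverlaps(centers, flanked, select = "first")
  zone <- ifelse(!is.na(hitCore), "core",
                 ifelse(!is.na(hitFlank), "flank", "background"))
  regionName <- rep(NA_character_, nrow(df))
  regionName[!is.na(hitCore)] <- core$name[hitCore[!is.na(hitCore)]]
  fl <- is.na(hitCore) & !is.na(hitFlank)
  regionName[fl] <- flanked$name[hitFlank[fl]]
  data.frame(window_id = df$window_id, region = regionName, zone = zone,
             stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact enumeration of all rank configurations (tie-aware, via midranks)
#' when n_a + n_b <= 20; the tie-corrected normal approximation with
#' continuity correction otherwise. NAs are dropped; at least one finite
#' value per side is required. When every value is identical the p-value
#' is 1.
#'
#' @param a,b numeric vectors.
#' @return one-row data.frame: \code{statistic} (the Mann-Whitney U of
#'   \code{a}), \code{p_value}, \code{n_a}, \code{n_b}, \code{median_a},
#'   \code{median_b}, \code{method}.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
compareGroups <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (!length(a) || !length(b))
    stop("each group needs at least one finite value")
  na <- length(a); nb <- length(b); n <- na + nb
  rk <- rank(c(a, b))
  W <- sum(rk[seq_len(na)])
  U <- W - na * (na + 1) / 2
  mu <- na * (n + 1) / 2
  if (n <= 20L) {
    combos <- combn(n, na)
    Ws <- colSums(matrix(rk[combos], nrow = na))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation"
  }
  data.frame(statistic = U, p_value = p, n_a = na, n_b = nb,
             median_a = median(a), median_b = median(b),
             method = method, stringsAsFactors = FALSE)
}

#' Quantile decomposition of the freshwater entropy bias
#'
#' Partitions windows into quantiles of |delta| with edges computed over ALL
#' windows with a defined delta (genome-wide, not region-restricted), then
#' reports, per quantile, both readings of the divergence-island statistic:
#' the fraction of DI windows in the quantile with delta > 0, and each
#' quantile's share of all freshwater-preferring (delta > 0) DI windows.
#' Ties at quantile edges go to the lower quantile.
#'
#' @param delta a \code{\link{deltaBetween}} data.frame.
#' @param assignment a \code{\link{assignWindows}} data.frame; rows with
#'   zone \code{"core"} define the DI windows.
#' @param nQuantiles number of quantiles (10 deciles by default; Q10 = top).
#' @param zone which assignment zones count as "in region".
#' @return data.frame with one row per quantile: \code{quantile}, edge
#'   \code{lo}/\code{hi}, \code{n_windows}, \code{n_region},
#'   \code{frac_fw_bias} (NA where the quantile holds no region window) and
#'   \code{share_fw_bias} (shares sum to 1 when any positive-delta region
#'   window exists).
#' @export
quantileBias <- function(delta, assignment, nQuantiles = 10L,
                         zone = "core") {
  d <- merge(delta, assignment, by = "window_id")
  d <- d[is.finite(d$delta), , drop = FALSE]
  if (nrow(d) < nQuantiles)
    stop("fewer windows with defined delta than quantiles")
  absd <- abs(d$delta)
  edges <- quantile(absd, probs = seq(0, 1, length.out = nQuantiles + 1L),
                    names = FALSE, type = 7)
  q <- findInterval(absd, edges[-c(1L, nQuantiles + 1L)],
                    left.open = TRUE) + 1L
  inRegion <- d$zone %in% zone
  posRegion <- inRegion & d$delta > 0
  totPos <- sum(posRegion)
  out <- data.frame(
    quantile = paste0("Q", seq_len(nQuantiles)),
    lo = edges[seq_len(nQuantiles)],
    hi = edges[-1L],
    n_windows = as.integer(tabulate(q, nQuantiles)),
    n_region = as.integer(tabulate(q[inRegion], nQuantiles)),
    stringsAsFactors = FALSE)
  posByQ <- tabulate(q[posRegion], nQuantiles)
  out$frac_fw_bias <- ifelse(out$n_region > 0, posByQ / out$n_region, NA_real_)
  out$share_fw_bias <- if (totPos > 0) posByQ / totPos else NA_real_
  out
}

#' Ecotype comparison tables over multiple region sets
#'
#' Applies identical machinery to every supplied region set: per set (and
#' for the background complement) the windows' between-sample entropies are
#' compared freshwater versus marine with \code{\link{compareGroups}}.
#'
#' @param profileFresh,profileMarine \code{\link{EntropyProfile}}s for the
#'   two ecotypes on the same window universe (same sex).
#' @param regionSets named list of \code{\link{RegionSet}} objects (DIs,
#'   EcoPeak flavors, TempoPeaks, ...).
#' @param zone assignment zones treated as inside the region set.
#' @return long data.frame, one row per (region set, stratum in
#'   \{region, background\}), with compareGroups columns. Empty strata are
#'   skipped with a warning.
#' @export
regionEntropyTable <- function(profileFresh, profileMarine, regionSets,
                               zone = "core") {
  if (!identical(windowIds(profileFresh), windowIds(profileMarine)))
    stop("profiles were computed on different window universes")
  if (is.null(names(regionSets)) || any(names(regionSets) == ""))
    stop("regionSets must be a named list")
  hf <- entropyBetween(profileFresh)
  hm <- entropyBetween(profileMarine)
  rows <- list()
  for (nm in names(regionSets)) {
    rs <- regionSets[[nm]]
    if (length(coreRegions(rs)) == 0L) {
      warning(sprintf("region set '%s' is empty; skipped", nm))
      next
    }
    asg <- assignWindows(profileFresh, rs)
    for (stratum in c("region", "background")) {
      inSet <- if (stratum == "region") asg$zone %in% zone else
        asg$zone == "background"
      af <- hf[inSet]; am <- hm[inSet]
      if (!any(is.finite(af)) || !any(is.finite(am))) {
        warning(sprintf("region set '%s' (%s): no defined entropies; skipped",
                        nm, stratum))
        next
      }
      cmp <- compareGroups(af, am)
      rows[[paste(nm, stratum)]] <- cbind(
        data.frame(region_set = nm, stratum = stratum,
                   n_windows = sum(inSet), stringsAsFactors = FALSE), cmp)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
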