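## Synthetic cohorts with the statistical structure the analysis assumes.
##
## Generative model, per window of b CpGs:
##   base distribution over the 2^b epialleles  ~ Dirichlet(alphaWithin)
##   individual distribution p_s               ~ Dirichlet(base / tau_s)
##   reads per individual per 1-kb bin         ~ NegBin(coverageMean, size)
##   epialleles of the reads                   ~ Multinomial(p_s)
## where tau_s = tauBetween, multiplied by diEffect for freshwater
## individuals in divergence-island windows. alphaWithin tunes
## within-individual epiallele diversity (small alpha -> sparse, low-entropy
## distributions); tauBetween tunes between-individual divergence (tau -> 0
## collapses every individual onto the base distribution, so H_between -> 0
## as coverage grows). Everything is determined by the seed.

#' Simulation configuration
#'
#' Defaults encode the reference study design: 16 freshwater and 16 marine
#' fish (7 males + 9 females per ecotype), 5-CpG windows, negative-binomial
#' coverage with mean 32 fragments per 1-kb bin, 10% of windows inside
#' divergence islands, and a 4-fold tau multiplier for freshwater DI windows.
#'
#' @param nMalePerEcotype,nFemalePerEcotype individuals per (ecotype, sex)
#'   cell.
#' @param nWindows number of simulated 5-CpG windows (one per 1-kb bin).
#' @param b CpGs per window.
#' @param cpgSpacing bp between consecutive CpGs within a window.
#' @param binSize coverage bin length in bp.
#' @param coverageMean,coverageDispersion negative-binomial mean and size for
#'   per-bin fragment counts.
#' @param alphaWithin symmetric Dirichlet concentration of the window base
#'   distribution (within-individual diversity dial).
#' @param tauBetween between-individual divergence; each individual's
#'   epiallele distribution is Dirichlet(base / tauBetween).
#' @param diFraction fraction of windows inside divergence islands.
#' @param diEffect multiplier on tauBetween for freshwater DI windows.
#' @param methylationVariation if \code{FALSE}, every read is fully
#'   methylated (point-mass base, no individual variation) -- the
#'   pure-genetic background for the C-to-T control.
#' @param straddlingReads also emit reads that straddle adjacent windows, to
#'   exercise partial-overlap exclusion.
#' @param chrom chromosome name for the simulated genome.
#' @param seed integer; fully determines the cohort.
#' @return validated config list of class \code{simConfig}.
#' @export
simConfig <- function(nMalePerEcotype = 7L, nFemalePerEcotype = 9L,
                      nWindows = 500L, b = 5L, cpgSpacing = 25L,
                      binSize = 1000L, coverageMean = 32,
                      coverageDispersion = 16, alphaWithin = 0.2,
                      tauBetween = 0.1, diFraction = 0.1, diEffect = 4,
                      methylationVariation = TRUE, straddlingReads = FALSE,
                      chrom = "chrS", seed = 1L) {
  cfg <- list(nMalePerEcotype = as.integer(nMalePerEcotype),
              nFemalePerEcotype = as.integer(nFemalePerEcotype),
              nWindows = as.integer(nWindows), b = as.integer(b),
              cpgSpacing = as.integer(cpgSpacing),
              binSize = as.integer(binSize), coverageMean = coverageMean,
              coverageDispersion = coverageDispersion,
              alphaWithin = alphaWithin, tauBetween = tauBetween,
              diFraction = diFraction, diEffect = diEffect,
              methylationVariation = isTRUE(methylationVariation),
              straddlingReads = isTRUE(straddlingReads),
              chrom = chrom, seed = as.integer(seed))
  if (cfg$diFraction < 0 || cfg$diFraction > 1)
    stop("diFraction must be in [0, 1]")
  if (cfg$alphaWithin <= 0 || cfg$tauBetween <= 0 || cfg$diEffect <= 0)
    stop("alphaWithin, tauBetween and diEffect must be > 0")
  if (cfg$coverageMean <= 0 || cfg$coverageDispersion <= 0)
    stop("coverage parameters must be > 0")
  if (cfg$b < 2L) stop("b must be >= 2")
  if ((cfg$b - 1L) * cfg$cpgSpacing + 100L > cfg$binSize)
    stop("window does not fit inside one bin; reduce cpgSpacing or b")
  class(cfg) <- "simConfig"
  cfg
}

.simDesign <- function(cfg) {
  rows <- list()
  for (eco in ECOTYPES) {
    tag <- if (eco == "freshwater") "fw" else "mar"
    if (cfg$nMalePerEcotype > 0L)
      rows[[paste0(tag, "m")]] <- data.frame(
        sample_id = sprintf("%s_m_%02d", tag, seq_len(cfg$nMalePerEcotype)),
        ecotype = eco, sex = "male", stringsAsFactors = FALSE)
    if (cfg$nFemalePerEcotype > 0L)
      rows[[paste0(tag, "f")]] <- data.frame(
        sample_id = sprintf("%s_f_%02d", tag, seq_len(cfg$nFemalePerEcotype)),
        ecotype = eco, sex = "female", stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate an epiread cohort with ground truth
#'
#' Draws a full cohort under the Dirichlet-multinomial hierarchy described in
#' the package overview: per-window base epiallele distributions, per-
#' individual distributions concentrated around them, negative-binomial
#' coverage per 1-kb bin, and multinomial reads. Freshwater individuals in
#' divergence-island windows receive \code{tauBetween * diEffect}. Reads are
#' window-aligned (each covers exactly the b CpGs of its window) unless
#' \code{straddlingReads} adds fragments spanning adjacent windows.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list of class \code{epiCohort}:
#'   \describe{
#'     \item{epireads}{an \code{\link{EpireadSet}} (always passes format
#'       validation).}
#'     \item{cpgMap}{the simulated CpG universe.}
#'     \item{windows}{ready-built \code{\link{buildWindows}} result.}
#'     \item{diRegions}{\code{\link{RegionSet}} of DI intervals (flank 0).}
#'     \item{truth}{ground truth: \code{windows} (per-window data.frame with
#'       DI flags and realized tau), \code{pInd} (per-window individual-by-
#'       epiallele probability matrices), \code{baseProbs}, \code{readCounts}
#'       (window-by-sample realized coverage), \code{patterns}.}
#'     \item{design, config}{as supplied.}
#'   }
#' @examples
#' cohort <- simulateCohort(simConfig(nWindows = 20L, nFemalePerEcotype = 0L))
#' cohort$epireads
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "simConfig")) stop("config must come from simConfig()")
  cfg <- config
  set.seed(cfg$seed)
  design <- .simDesign(cfg)
  nS <- nrow(design)
  K <- 2L^cfg$b
  patterns <- .allPatterns(cfg$b)
  offsets <- (seq_len(cfg$b) - 1L) * cfg$cpgSpacing
  winFirst0 <- (seq_len(cfg$nWindows) - 1L) * cfg$binSize + 100L
  sitesAll <- as.integer(rep(winFirst0, each = cfg$b) +
                           rep(offsets, cfg$nWindows))
  cpgMap <- CpGMap(setNames(list(sitesAll), cfg$chrom))
  nDi <- round(cfg$diFraction * cfg$nWindows)
  diW <- if (nDi > 0L) sort(sample.int(cfg$nWindows, nDi)) else integer(0)
  isDi <- seq_len(cfg$nWindows) %in% diW
  isFresh <- design$ecotype == "freshwater"
  allM <- numeric(K); allM[1L] <- 1  # pattern "MM...M" is first

  baseProbs <- matrix(0, cfg$nWindows, K)
  pInd <- vector("list", cfg$nWindows)
  readCounts <- matrix(0L, cfg$nWindows, nS,
                       dimnames = list(NULL, design$sample_id))
  chunks <- vector("list", cfg$nWindows)
  for (w in seq_len(cfg$nWindows)) {
    base <- if (cfg$methylationVariation)
      .rdirichlet1(rep(cfg$alphaWithin, K)) else allM
    baseProbs[w, ] <- base
    P <- matrix(0, nS, K, dimnames = list(design$sample_id, patterns))
    cnt <- matrix(0L, nS, K)
    for (s in seq_len(nS)) {
      tau <- cfg$tauBetween *
        if (isDi[w] && isFresh[s]) cfg$diEffect else 1
      p <- if (cfg$methylationVariation) .rdirichlet1(base / tau) else base
      P[s, ] <- p
      nCov <- rnbinom(1L, mu = cfg$coverageMean,
                      size = cfg$coverageDispersion)
      readCounts[w, s] <- nCov
      if (nCov > 0L) cnt[s, ] <- rmultinom(1L, nCov, p)
    }
    pInd[[w]] <- P
    nz <- which(cnt > 0L, arr.ind = TRUE)
    if (nrow(nz))
      chunks[[w]] <- data.table::data.table(
        w = w, s = nz[, 1L], k = nz[, 2L], n = cnt[nz])
  }
  long <- data.table::rbindlist(chunks[!vapply(chunks, is.null, logical(1))])
  reads <- NULL
  if (!is.null(long) && nrow(long)) {
    data.table::setorder(long, w, s, k)
    rw <- rep(long$w, long$n)
    rs <- rep(long$s, long$n)
    rk <- rep(long$k, long$n)
    idDT <- data.table::data.table(w = rw, s = rs)
    idDT[, idx := seq_len(.N), by = c("w", "s")]
    nR <- length(rw)
    posFlat <- rep(winFirst0[rw], each = cfg$b) + rep(offsets, nR)
    reads <- DataFrame(
      chrom = rep(cfg$chrom, nR),
      read_id = paste0(design$sample_id[rs], "_w", rw, "_r", idDT$idx),
      sample_id = design$sample_id[rs],
      positions = IRanges::relist(
        as.integer(posFlat),
        IRanges::PartitioningByEnd(seq.int(cfg$b, cfg$b * nR, by = cfg$b))),
      pattern = patterns[rk])
  }
  if (cfg$straddlingReads && cfg$nWindows > 1L) {
    half <- cfg$b %/% 2L
    sw <- rep(seq_len(cfg$nWindows - 1L),
              rpois(cfg$nWindows - 1L, 2))
    if (length(sw)) {
      ssamp <- sample.int(nS, length(sw), replace = TRUE)
      spat <- vapply(seq_along(sw), function(i)
        paste(sample(c("M", "U"), cfg$b, replace = TRUE), collapse = ""),
        character(1))
      tailPos <- lapply(sw, function(w)
        as.integer(c(winFirst0[w] + offsets[(cfg$b - half + 1L):cfg$b],
                     winFirst0[w + 1L] + offsets[seq_len(cfg$b - half)])))
      straddle <- DataFrame(
        chrom = rep(cfg$chrom, length(sw)),
        read_id = sprintf("straddle_w%04d_i%04d", sw, seq_along(sw)),
        sample_id = design$sample_id[ssamp],
        positions = IRanges::IntegerList(tailPos),
        pattern = spat)
      reads <- if (is.null(reads)) straddle else rbind(reads, straddle)
    }
  }
  if (is.null(reads))
    reads <- DataFrame(chrom = character(), read_id = character(),
                       sample_id = character(),
                       positions = IRanges::IntegerList(),
                       pattern = character())
  epi <- .EpireadSetUnchecked(reads, design)
  windows <- buildWindows(cpgMap, b = cfg$b, step = 1L)
  diGr <- .granges0(rep(cfg$chrom, length(diW)),
                    (diW - 1L) * cfg$binSize,
                    diW * cfg$binSize,
                    name = sprintf("DI_%04d", seq_along(diW)))
  truthWin <- data.frame(
    window_id = paste0(cfg$chrom, ":", (seq_len(cfg$nWindows) - 1L) * cfg$b + 1L),
    chrom = cfg$chrom,
    start0 = winFirst0,
    central_pos0 = winFirst0 + offsets[as.integer(ceiling(cfg$b / 2))],
    is_di = isDi,
    tau_freshwater = cfg$tauBetween * ifelse(isDi, cfg$diEffect, 1),
    tau_marine = cfg$tauBetween,
    stringsAsFactors = FALSE)
  out <- list(epireads = epi, cpgMap = cpgMap, windows = windows,
              diRegions = RegionSet(diGr, flank = 0L),
              truth = list(windows = truthWin, pInd = pInd,
                           baseProbs = baseProbs, readCounts = readCounts,
                           patterns = patterns),
              design = design, config = cfg)
  class(out) <- "epiCohort"
  out
}

#' @export
print.epiCohort <- function(x, ...) {
  cat(sprintf("epiCohort: %d windows (%d in DIs), %d samples, %d reads, seed %d\n",
              x$config$nWindows, sum(x$truth$windows$is_di),
              nrow(x$design), nReads(x$epireads), x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the epiread TSV, the design TSV, the DI BED and the per-window truth
#' table, all plain text.
#'
#' @param cohort an \code{epiCohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEpireads(cohort$epireads, file.path(dir, "epireads.tsv"))
  writeDesign(cohort$design, file.path(dir, "design.tsv"))
  writeRegionsBed(cohort$diRegions, file.path(dir, "di.bed"))
  data.table::fwrite(cohort$truth$windows, file.path(dir, "truth_windows.tsv"),
                     sep = "\t")
  invisible(dir)
}

## --------------------------------------------------------- C->T injection

#' Inject C-to-T mutations into a simulated cohort
#'
#' Models the genetic confounder the C-to-T entropy control is designed to
#' expose: a thymine allele at a CpG site is read by bisulfite sequencing
#' exactly like an unmethylated (converted) cytosine. In \code{"genetic"}
#' mode, each CpG site is selected with probability \code{rate}; selected
#' sites receive population C/T polymorphism, with high heterozygosity in
#' freshwater at divergence-island sites (allele frequency ~
#' Beta(\code{fwHet})) and low-frequency variation elsewhere and in marine
#' fish (~ Beta(\code{bgHet})) -- the counterfactual in which the freshwater
#' DI entropy elevation is mutation-driven. Each read is assigned to one of
#' its individual's two haplotypes; wherever that haplotype carries T the
#' read's call is flipped to \code{U}. In \code{"epigenetic"} mode no
#' variants are emitted and reads are untouched.
#'
#' @param cohort an \code{epiCohort} from \code{\link{simulateCohort}}.
#' @param rate per-CpG-site selection probability in [0, 1].
#' @param mode \code{"genetic"} or \code{"epigenetic"}.
#' @param fwHet,bgHet Beta shape pairs for freshwater-DI and background
#'   allele frequencies.
#' @param seed RNG seed (defaults to the cohort seed + 1).
#' @return list with \code{epireads} (modified \code{\link{EpireadSet}}),
#'   \code{genotypes} (phased genotype table, same shape as
#'   \code{\link{readVcfCt}} output), \code{truthSites} (data.frame of
#'   injected sites with their per-ecotype allele frequencies) and
#'   \code{hapAlleles} (site-by-haplotype 0/1 matrix).
#' @export
injectCtMutations <- function(cohort, rate, mode = c("epigenetic", "genetic"),
                              fwHet = c(2, 2), bgHet = c(0.5, 9.5),
                              seed = cohort$config$seed + 1L) {
  mode <- match.arg(mode)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  design <- cohort$design
  nS <- nrow(design)
  emptySites <- data.frame(chrom = character(), pos0 = integer(),
                           ref = character(), alt = character(),
                           stringsAsFactors = FALSE)
  emptyGt <- matrix(character(), 0L, nS,
                    dimnames = list(NULL, design$sample_id))
  if (mode == "epigenetic" || rate == 0) {
    return(list(epireads = cohort$epireads,
                genotypes = list(sites = emptySites, gt = emptyGt),
                truthSites = cbind(emptySites,
                                   data.frame(window_id = character(),
                                              freq_freshwater = numeric(),
                                              freq_marine = numeric())),
                hapAlleles = matrix(0L, 0L, 2L * nS)))
  }
  set.seed(seed)
  cfg <- cohort$config
  tw <- cohort$truth$windows
  siteDf <- data.frame(
    chrom = rep(tw$chrom, each = cfg$b),
    pos0 = unlist(cpgSites(cohort$cpgMap), use.names = FALSE),
    window_id = rep(tw$window_id, each = cfg$b),
    is_di = rep(tw$is_di, each = cfg$b),
    stringsAsFactors = FALSE)
  sel <- which(runif(nrow(siteDf)) < rate)
  nSel <- length(sel)
  sites <- siteDf[sel, , drop = FALSE]
  freqFw <- ifelse(sites$is_di, rbeta(nSel, fwHet[1], fwHet[2]),
                   rbeta(nSel, bgHet[1], bgHet[2]))
  freqMar <- rbeta(nSel, bgHet[1], bgHet[2])
  ## haplotype alleles: columns interleaved (sample1 hap1, sample1 hap2, ...)
  hap <- matrix(0L, nSel, 2L * nS)
  colnames(hap) <- paste0(rep(design$sample_id, each = 2L), "|h",
                          rep(1:2, nS))
  for (s in seq_len(nS)) {
    f <- if (design$ecotype[s] == "freshwater") freqFw else freqMar
    hap[, 2L * s - 1L] <- rbinom(nSel, 1L, f)
    hap[, 2L * s] <- rbinom(nSel, 1L, f)
  }
  gt <- matrix(paste0(hap[, seq(1L, 2L * nS, by = 2L), drop = FALSE], "|",
                      hap[, seq(2L, 2L * nS, by = 2L), drop = FALSE]),
               nSel, nS, dimnames = list(NULL, design$sample_id))
  ## flip read calls on T haplotypes
  r <- epireads(cohort$epireads)
  pat <- r$pattern
  if (nrow(r) && nSel) {
    readHap <- sample.int(2L, nrow(r), replace = TRUE)
    sIdx <- match(r$sample_id, design$sample_id)
    len <- lengths(r$positions)
    u <- data.table::data.table(
      read = rep(seq_len(nrow(r)), len), idx = sequence(len),
      chrom = rep(r$chrom, len), pos = unlist(r$positions, use.names = FALSE))
    siteKey <- paste0(sites$chrom, ":", sites$pos0)
    u[, siteIdx := match(paste0(chrom, ":", pos), siteKey)]
    hits <- u[!is.na(siteIdx)]
    if (nrow(hits)) {
      allele <- hap[cbind(hits$siteIdx,
                          2L * (sIdx[hits$read] - 1L) + readHap[hits$read])]
      hits <- hits[allele == 1L]
      for (v in unique(hits$idx)) {
        hr <- hits$read[hits$idx == v]
        substr(pat[hr], v, v) <- "U"
      }
    }
  }
  r$pattern <- pat
  list(epireads = .EpireadSetUnchecked(r, design),
       genotypes = list(sites = data.frame(chrom = sites$chrom,
                                           pos0 = sites$pos0,
                                           ref = "C", alt = "T",
                                           stringsAsFactors = FALSE),
                        gt = gt),
       truthSites = data.frame(chrom = sites$chrom, pos0 = sites$pos0,
                               ref = "C", alt = "T",
                               window_id = sites$window_id,
                               freq_freshwater = freqFw,
                               freq_marine = freqMar,
                               stringsAsFactors = FALSE),
       hapAlleles = hap)
}

## ------------------------------------------------------------- expression

#' Simulate a gene expression count matrix with group-specific variance
#'
#' Counts are negative binomial around log-normal base means, scaled by
#' log-normal library sizes (so normalization is non-trivial). Genes listed
#' in \code{varGenes} get their dispersion multiplied by \code{varEffect} in
#' freshwater samples only, creating a between-individual variance excess
#' without a mean shift.
#'
#' @param nGenes number of genes.
#' @param design optional data.frame(sample_id, ecotype); defaults to
#'   \code{nPerEcotype} bulk replicates per ecotype.
#' @param nPerEcotype replicates per ecotype for the default design.
#' @param varGenes integer indices or gene ids receiving inflated freshwater
#'   dispersion.
#' @param varEffect dispersion multiplier for \code{varGenes}.
#' @param meanLog,meanSdLog log-normal parameters of gene base means.
#' @param dispersion baseline NB dispersion (1/size).
#' @param librarySdLog sd(log) of sample library-size factors.
#' @param seed optional seed.
#' @return list: \code{counts} (gene-by-sample integer matrix),
#'   \code{design}, \code{truth} (per-gene base mean, dispersion, inflation
#'   flag).
#' @export
simulateExpression <- function(nGenes = 2000L, design = NULL,
                               nPerEcotype = 4L, varGenes = integer(),
                               varEffect = 16, meanLog = log(100),
                               meanSdLog = 1, dispersion = 0.05,
                               librarySdLog = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design))
    design <- data.frame(
      sample_id = c(sprintf("rna_fw_%d", seq_len(nPerEcotype)),
                    sprintf("rna_mar_%d", seq_len(nPerEcotype))),
      ecotype = rep(ECOTYPES, each = nPerEcotype),
      stringsAsFactors = FALSE)
  genes <- sprintf("g%05d", seq_len(nGenes))
  if (is.character(varGenes)) varGenes <- match(varGenes, genes)
  inflated <- seq_len(nGenes) %in% varGenes
  baseMean <- rlnorm(nGenes, meanLog, meanSdLog)
  lib <- rlnorm(nrow(design), 0, librarySdLog)
  counts <- matrix(0L, nGenes, nrow(design),
                   dimnames = list(genes, design$sample_id))
  for (s in seq_len(nrow(design))) {
    disp <- ifelse(inflated & design$ecotype[s] == "freshwater",
                   dispersion * varEffect, dispersion)
    counts[, s] <- rnbinom(nGenes, mu = baseMean * lib[s], size = 1 / disp)
  }
  list(counts = counts, design = design,
       truth = data.frame(gene = genes, baseMean = baseMean,
                          dispersion = dispersion,
                          varInflated = inflated,
                          stringsAsFactors = FALSE))
}

## -------------------------------------------- exact expectation oracles

#' Exact expectation of the plug-in entropy estimator
#'
#' For counts n ~ Multinomial(N, p), the expectation of the plug-in
#' normalized entropy decomposes over categories into binomial marginals:
#' E[H] = -(1/b) sum_i sum_n Binom(n; N, p_i) (n/N) log2(n/N). Exact and
#' cheap; used to tabulate truth expectations and to quantify the
#' finite-coverage bias of the estimator.
#'
#' @param p probability vector over epialleles.
#' @param N number of reads.
#' @param b window size in CpGs.
#' @return E[H] (a number in [0, 1] for N >= 2^b).
#' @export
expectedPluginEntropy <- function(p, N, b) {
  if (N < 1L) return(NA_real_)
  n <- seq_len(N)
  f <- (n / N) * log2(n / N)  # f(N) = 0, consistent with 0 log 0 at n = 0
  acc <- 0
  for (pi in p[p > 0]) acc <- acc + sum(dbinom(n, N, pi) * f)
  -acc / b
}

## pmf convolution: distribution of a sum of independent counts
.convAdd <- function(v, w) {
  out <- numeric(length(v) + length(w) - 1L)
  for (j in seq_along(w))
    out[j:(j + length(v) - 1L)] <- out[j:(j + length(v) - 1L)] + v * w[j]
  out
}

#' Exact expected entropy decomposition under fixed sampling distributions
#'
#' Given each individual's epiallele distribution (rows of \code{P}) and
#' fixed read counts \code{Ns}, computes the exact expectations of the
#' plug-in pooled, within and between entropy components. Pooled category
#' counts are sums of independent binomials, handled by convolution.
#'
#' @param P individuals-by-epialleles probability matrix.
#' @param Ns integer vector of reads per individual.
#' @param b window size in CpGs.
#' @return list(H_pooled, H_within, H_between) of expectations.
#' @export
expectedDecomposition <- function(P, Ns, b) {
  S <- nrow(P)
  stopifnot(length(Ns) == S)
  N <- sum(Ns)
  eHs <- vapply(seq_len(S), function(s)
    expectedPluginEntropy(P[s, ], Ns[s], b), numeric(1))
  eWithin <- sum(Ns / N * eHs)
  acc <- 0
  m <- seq_len(N)
  f <- (m / N) * log2(m / N)
  for (i in seq_len(ncol(P))) {
    pmf <- 1
    for (s in seq_len(S)) pmf <- .convAdd(pmf, dbinom(0:Ns[s], Ns[s], P[s, i]))
    acc <- acc + sum(pmf[-1L] * f)  # drop m = 0 term
  }
  ePooled <- -acc / b
  list(H_pooled = ePooled, H_within = eWithin,
       H_between = ePooled - eWithin)
}
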