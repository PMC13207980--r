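## Independent oracles and small fixture builders used across the suite.
## Each oracle takes a different computational route from the implementation
## it checks.

## entropy via the algebraically rearranged form
## H = (1/b) (log2 N - (1/N) sum n_i log2 n_i)
oracleEntropyAlt <- function(counts, b) {
  n <- counts[counts > 0]
  N <- sum(n)
  (log2(N) - sum(n * log2(n)) / N) / b
}

## mutual information between sample label and epiallele, from the joint
## distribution directly (not pooled-minus-within)
oracleMI <- function(cnt, b) {
  N <- sum(cnt)
  ps <- rowSums(cnt) / N
  pp <- colSums(cnt) / N
  pj <- cnt / N
  mi <- 0
  for (s in seq_len(nrow(cnt)))
    for (k in seq_len(ncol(cnt)))
      if (pj[s, k] > 0)
        mi <- mi + pj[s, k] * log2(pj[s, k] / (ps[s] * pp[k]))
  unname(mi / b)
}

## two-sided rank-sum p by enumeration in U-statistic form (ties at 1/2)
oracleRankSumP <- function(a, b) {
  n <- length(a) + length(b)
  vals <- c(a, b)
  Ustat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u0 <- Ustat(a, b)
  mu <- length(a) * length(b) / 2
  idx <- utils::combn(n, length(a))
  us <- apply(idx, 2L, function(i) Ustat(vals[i], vals[-i]))
  mean(abs(us - mu) >= abs(u0 - mu) - 1e-9)
}

## a random per-sample tally for one window: counts over the 2^b patterns
randomTallies <- function(nSamples, b = 5L, maxReads = 64L) {
  pats <- epientropy:::.allPatterns(b)
  lapply(seq_len(nSamples), function(s) {
    N <- sample.int(maxReads, 1L)
    k <- sample.int(min(2L^b, N), 1L)
    chosen <- sample(pats, k)
    cnt <- as.integer(rmultinom(1L, N, rep(1 / k, k)))
    setNames(cnt, chosen)[cnt > 0]
  })
}

## tallies (named list) -> samples x patterns count matrix
talliesToMatrix <- function(tallies) {
  pats <- sort(unique(unlist(lapply(tallies, names))))
  m <- matrix(0, length(tallies), length(pats),
              dimnames = list(names(tallies), pats))
  for (s in seq_along(tallies)) m[s, names(tallies[[s]])] <- tallies[[s]]
  m
}

## minimal two-sample design + handmade EpireadSet
tinyDesign <- function() {
  data.frame(sample_id = c("s1", "s2"),
             ecotype = c("freshwater", "marine"),
             sex = c("male", "male"), stringsAsFactors = FALSE)
}

tinyEpireads <- function(positions, patterns, samples = NULL,
                         chrom = "chr1", design = tinyDesign()) {
  n <- length(patterns)
  if (is.null(samples)) samples <- rep(design$sample_id[1L], n)
  reads <- S4Vectors::DataFrame(
    chrom = rep(chrom, n),
    read_id = sprintf("r%03d", seq_len(n)),
    sample_id = samples,
    positions = IRanges::IntegerList(positions),
    pattern = patterns)
  EpireadSet(reads, design)
}
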