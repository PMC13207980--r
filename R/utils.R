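## Internal helpers shared across modules.

## 0-based half-open [start0, end0) -> 1-based closed GRanges
.granges0 <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}

## point positions (0-based) -> width-1 GRanges
.points0 <- function(chrom, pos0) {
  GRanges(chrom, IRanges(pos0 + 1L, width = 1L))
}

## Deterministic string hash (polynomial rolling hash mod 2^31 - 1), used to
## derive an independent RNG stream per (sample, bin) so downsampling does not
## depend on read-file order.
.strHash <- function(s) {
  m <- 2147483647
  vapply(s, function(x) {
    h <- 0
    for (v in utf8ToInt(x)) h <- (h * 131 + v) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

## All length-b patterns over an alphabet, in a fixed lexicographic order.
.allPatterns <- function(b, alphabet = c("M", "U")) {
  g <- expand.grid(rep(list(alphabet), b), stringsAsFactors = FALSE)
  ## column 1 varies fastest in expand.grid; rebuild so position 1 is the
  ## most significant symbol for a predictable ordering
  do.call(paste0, rev(g))
}

## One Dirichlet draw; degenerate all-zero gamma underflow falls back to a
## point mass on the largest concentration.
.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  s <- sum(g)
  if (!is.finite(s) || s <= 0) {
    p <- numeric(length(alpha))
    p[which.max(alpha)] <- 1
    return(p)
  }
  g / s
}

## Plug-in normalized entropy from raw counts; 0 log 0 == 0 by construction.
.H <- function(n, b) {
  n <- n[n > 0]
  if (!length(n)) return(NA_real_)
  p <- n / sum(n)
  -sum(p * log2(p)) / b
}
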