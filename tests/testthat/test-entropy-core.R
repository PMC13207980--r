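test_that("window construction yields m - b + 1 windows per chromosome", {
  m7 <- CpGMap(list(chr1 = as.integer(10 * (1:7))))
  expect_length(buildWindows(m7, b = 5L), 3L)
  m4 <- CpGMap(list(chr1 = as.integer(10 * (1:4))))
  expect_length(buildWindows(m4, b = 5L), 0L)
  ## b = 4 and b = 6 variants: m - 3 and m - 5 windows
  m10 <- CpGMap(list(chr1 = as.integer(10 * (1:10))))
  expect_length(buildWindows(m10, b = 4L), 7L)
  expect_length(buildWindows(m10, b = 6L), 5L)
  expect_error(buildWindows(m10, b = 1L), "b must be")
  ## windows never span chromosomes
  m2 <- CpGMap(list(chr1 = as.integer(10 * (1:6)),
                    chr2 = as.integer(10 * (1:5))))
  w <- buildWindows(m2, b = 5L)
  expect_length(w, 3L)
  expect_equal(as.character(GenomicRanges::seqnames(w)),
               c("chr1", "chr1", "chr2"))
})

test_that("tallying requires full window coverage and allows multi-window reads", {
  map <- CpGMap(list(chr1 = as.integer(c(10, 20, 30, 40, 50, 60))))
  w <- buildWindows(map, b = 5L)
  ## exact cover of window 1
  es <- tinyEpireads(list(as.integer(c(10, 20, 30, 40, 50))), "MMUMU")
  t1 <- tallyEpialleles(es, w)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$pattern, "MMUMU")
  expect_equal(t1$n, 1L)
  ## 4 of 5 sites -> contributes nothing, counted in qc
  es4 <- tinyEpireads(list(as.integer(c(10, 20, 30, 40))), "MMUM")
  t4 <- tallyEpialleles(es4, w)
  expect_equal(nrow(t4), 0L)
  expect_equal(unname(attr(t4, "qc")["readsExcluded"]), 1L)
  ## a 6-CpG read covers both sliding windows with shifted substrings
  es6 <- tinyEpireads(list(as.integer(c(10, 20, 30, 40, 50, 60))), "MMUMUM")
  t6 <- tallyEpialleles(es6, w)
  expect_equal(sort(t6$window_id), c("chr1:1", "chr1:2"))
  expect_setequal(t6$pattern, c("MMUMU", "MUMUM"))
  ## a gapped read (skips a mapped CpG) cannot cover a 5-window here
  esg <- tinyEpireads(list(as.integer(c(10, 20, 40, 50, 60))), "MMMUM")
  expect_equal(nrow(tallyEpialleles(esg, w)), 0L)
  ## 32 reads realizing each pattern once -> k = 32
  pats <- epientropy:::.allPatterns(5L)
  es32 <- tinyEpireads(rep(list(as.integer(c(10, 20, 30, 40, 50))), 32), pats)
  t32 <- tallyEpialleles(es32, w)
  k <- length(unique(t32[t32$window_id == "chr1:1"]$pattern))
  expect_equal(k, 32L)
})

test_that("window entropy matches closed forms and the coverage rule", {
  expect_equal(windowEntropy(c(MMMMM = 32), b = 5), 0)
  expect_equal(windowEntropy(setNames(rep(1, 32), epientropy:::.allPatterns(5L)),
                             b = 5), 1)
  expect_equal(windowEntropy(c(MMMMM = 16, UUUUU = 16), b = 5), 0.2)
  ## frozen from the independent rearranged-form oracle
  h <- windowEntropy(c(MMMMM = 10, UUUUU = 10, MUMUM = 12), b = 5)
  expect_equal(h, 0.31588678, tolerance = 1e-7)
  expect_equal(h, oracleEntropyAlt(c(10, 10, 12), 5), tolerance = 1e-13)
  ## below the minimum the value is undefined, never NaN
  expect_true(is.na(windowEntropy(c(MMMMM = 10), b = 5, minReads = 32)))
  expect_true(is.na(windowEntropy(integer(0), b = 5)))
})

test_that("entropy respects its bounds with equality cases", {
  set.seed(42)
  for (i in 1:200) {
    b <- sample(4:6, 1)
    tl <- randomTallies(1L, b = b, maxReads = 200L)[[1]]
    H <- windowEntropy(tl, b = b, minReads = 1L)
    N <- sum(tl)
    expect_gte(H, 0)
    expect_lte(H, min(log2(N), b) / b + 1e-12)
  }
})

test_that("decomposition satisfies the identity and equals mutual information", {
  ## two identical distributions: no between component
  d <- decomposeEntropy(list(a = c(MMMMM = 8, UUUUU = 8),
                             b = c(MMMMM = 8, UUUUU = 8)),
                        b = 5, minReads = 32, perSampleMin = 8)
  expect_equal(d$H_between, 0)
  expect_equal(d$H_pooled, 0.2)
  ## the all-M vs all-U illustration: entropy is purely between samples
  d2 <- decomposeEntropy(list(a = c(MMMMM = 16), b = c(UUUUU = 16)),
                         b = 5, minReads = 32, perSampleMin = 8)
  expect_equal(d2$H_pooled, 0.2)
  expect_equal(d2$H_within, 0)
  expect_equal(d2$H_between, 0.2)
  ## random tallies: pooled = within + between, H_between = I(label; pattern)/b
  set.seed(7)
  for (i in 1:300) {
    tl <- randomTallies(sample(2:5, 1), b = 5L)
    names(tl) <- paste0("s", seq_along(tl))
    d <- decomposeEntropy(tl, b = 5, minReads = 1L, perSampleMin = 1L)
    expect_lt(abs(d$H_pooled - d$H_within - d$H_between), 1e-12)
    expect_gte(d$H_between, -1e-12)
    expect_equal(d$H_between, oracleMI(talliesToMatrix(tl), 5L),
                 tolerance = 1e-10)
  }
  ## sub-threshold samples are excluded; lone qualifiers give no between term
  d3 <- decomposeEntropy(list(a = c(MMMMM = 40), b = c(UUUUU = 2)),
                         b = 5, minReads = 32, perSampleMin = 8)
  expect_equal(d3$qc, "few_samples")
  expect_true(is.na(d3$H_between))
  expect_equal(d3$N_total, 40)
})

test_that("profiles are invariant to read and sample order", {
  cohort <- simulateCohort(simConfig(nWindows = 30L, nMalePerEcotype = 3L,
                                     nFemalePerEcotype = 0L, seed = 13L))
  r <- epireads(cohort$epireads)
  set.seed(1)
  perm <- sample(nrow(r))
  shuffled <- EpireadSet(r[perm, , drop = FALSE],
                         cohort$design[sample(nrow(cohort$design)), ])
  t1 <- tallyEpialleles(cohort$epireads, cohort$windows)
  t2 <- tallyEpialleles(shuffled, cohort$windows)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  p1 <- entropyProfile(cohort$epireads, cohort$windows, sex = "male",
                       ecotype = "freshwater", minReads = 8, perSampleMin = 2)
  p2 <- entropyProfile(shuffled, cohort$windows, sex = "male",
                       ecotype = "freshwater", minReads = 8, perSampleMin = 2)
  expect_identical(SummarizedExperiment::rowData(p1),
                   SummarizedExperiment::rowData(p2))
})

test_that("delta is zero on identical inputs and antisymmetric under label swap", {
  cohort <- simulateCohort(simConfig(nWindows = 40L, nMalePerEcotype = 4L,
                                     nFemalePerEcotype = 0L, seed = 17L))
  tally <- tallyEpialleles(cohort$epireads, cohort$windows)
  pf <- entropyProfile(cohort$epireads, cohort$windows, sex = "male",
                       ecotype = "freshwater", tally = tally)
  pm <- entropyProfile(cohort$epireads, cohort$windows, sex = "male",
                       ecotype = "marine", tally = tally)
  expect_equal(deltaBetween(pf, pf)$delta[is.finite(entropyBetween(pf))],
               rep(0, sum(is.finite(entropyBetween(pf)))))
  d1 <- deltaBetween(pf, pm)$delta
  d2 <- deltaBetween(pm, pf)$delta
  expect_equal(d1, -d2)
  ## mismatched universes are refused
  w2 <- buildWindows(cohort$cpgMap, b = 4L)
  p4 <- entropyProfile(cohort$epireads, w2, sex = "male",
                       ecotype = "freshwater")
  expect_error(deltaBetween(pf, p4), "window universes")
})

test_that("DI elevation keeps its sign across window sizes 4, 5 and 6", {
  signs <- vapply(c(4L, 5L, 6L), function(b) {
    cohort <- simulateCohort(simConfig(nWindows = 150L, nFemalePerEcotype = 0L,
                                       b = b, seed = 29L))
    res <- runEntropyPipeline(cohort, sex = "male", minReads = 2L^b,
                              seed = 29L)
    asg <- res$assignment
    mean(res$delta$delta[asg$zone == "core"], na.rm = TRUE) -
      mean(res$delta$delta[asg$zone == "background"], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(signs > 0))
})
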