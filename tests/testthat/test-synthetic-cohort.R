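test_that("configuration is validated", {
  expect_error(simConfig(diFraction = 1.5), "diFraction")
  expect_error(simConfig(alphaWithin = 0), "must be > 0")
  expect_error(simConfig(tauBetween = -1), "must be > 0")
  expect_error(simConfig(b = 1L), "b must be")
  expect_s3_class(simConfig(), "simConfig")
})

test_that("identical configs give byte-identical cohorts", {
  cfg <- simConfig(nWindows = 40L, nMalePerEcotype = 3L,
                   nFemalePerEcotype = 2L, seed = 7L,
                   straddlingReads = TRUE)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeEpireads(c1$epireads, f1)
  writeEpireads(c2$epireads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(c1$truth$windows, c2$truth$windows)
  expect_identical(c1$truth$pInd, c2$truth$pInd)
  ## a different seed gives different reads
  c3 <- simulateCohort(simConfig(nWindows = 40L, nMalePerEcotype = 3L,
                                 nFemalePerEcotype = 2L, seed = 8L,
                                 straddlingReads = TRUE))
  f3 <- tempfile(); writeEpireads(c3$epireads, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("emitted epireads always pass format validation", {
  for (seed in c(3L, 4L)) {
    cohort <- simulateCohort(simConfig(nWindows = 30L, nMalePerEcotype = 2L,
                                       nFemalePerEcotype = 2L, seed = seed,
                                       straddlingReads = TRUE))
    expect_true(validObject(cohort$epireads, test = FALSE))
    ## and through the parser as well
    f <- tempfile()
    writeEpireads(cohort$epireads, f)
    expect_no_message(readEpireads(f, cohort$design))
  }
})

test_that("tau controls the decomposition in its limits", {
  ## tau -> 0: individuals share the group distribution; H_between stays at
  ## the level of pure estimator bias
  lo <- simulateCohort(simConfig(nWindows = 60L, nMalePerEcotype = 4L,
                                 nFemalePerEcotype = 0L, tauBetween = 1e-6,
                                 diFraction = 0, coverageMean = 64,
                                 seed = 51L))
  pLo <- entropyProfile(lo$epireads, lo$windows, sex = "male",
                        minReads = 32L, perSampleMin = 8L)
  hbLo <- entropyBetween(pLo)
  expect_lt(mean(hbLo, na.rm = TRUE), 0.05)
  ## alpha -> 0 with tau large: individuals near-monomorphic but mutually
  ## different; H_within ~ 0, H_between > 0
  hi <- simulateCohort(simConfig(nWindows = 60L, nMalePerEcotype = 4L,
                                 nFemalePerEcotype = 0L, alphaWithin = 0.01,
                                 tauBetween = 50, diFraction = 0,
                                 coverageMean = 64, seed = 52L))
  pHi <- entropyProfile(hi$epireads, hi$windows, sex = "male",
                        minReads = 32L, perSampleMin = 8L)
  hwHi <- entropyWithin(pHi)
  hbHi <- entropyBetween(pHi)
  expect_lt(mean(hwHi, na.rm = TRUE), 0.1)
  expect_gt(mean(hbHi, na.rm = TRUE), mean(hwHi, na.rm = TRUE))
})

test_that("realized H_between agrees with the exact conditional expectation", {
  ## small-coverage check of model consistency: mean realized minus expected
  ## within 3 Monte-Carlo standard errors over >= 500 windows
  cohort <- simulateCohort(simConfig(nWindows = 500L, nMalePerEcotype = 4L,
                                     nFemalePerEcotype = 0L, coverageMean = 8,
                                     coverageDispersion = 100,
                                     diFraction = 0, seed = 61L))
  fw <- cohort$design$sample_id[cohort$design$ecotype == "freshwater"]
  prof <- entropyProfile(cohort$epireads, cohort$windows,
                         ecotype = "freshwater", minReads = 2L,
                         perSampleMin = 1L)
  hb <- SummarizedExperiment::rowData(prof)$H_between
  wid <- windowIds(prof)
  tw <- cohort$truth$windows
  diffs <- c()
  for (w in seq_len(nrow(tw))) {
    i <- match(tw$window_id[w], wid)
    Ns <- cohort$truth$readCounts[w, fw]
    use <- Ns > 0
    if (sum(use) < 2L || !is.finite(hb[i])) next
    P <- cohort$truth$pInd[[w]][fw, , drop = FALSE][use, , drop = FALSE]
    e <- expectedDecomposition(P, Ns[use], b = 5L)
    diffs <- c(diffs, hb[i] - e$H_between)
  }
  expect_gte(length(diffs), 450L)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("C>T injection respects rate, truth list and homozygous extremes", {
  cohort <- simulateCohort(simConfig(nWindows = 20L, nMalePerEcotype = 2L,
                                     nFemalePerEcotype = 0L, seed = 71L))
  ## rate 0: empty VCF, untouched reads
  inj0 <- injectCtMutations(cohort, rate = 0, mode = "genetic")
  expect_equal(nrow(inj0$genotypes$sites), 0L)
  expect_identical(epireads(inj0$epireads)$pattern,
                   epireads(cohort$epireads)$pattern)
  ## epigenetic mode: same, by construction
  injE <- injectCtMutations(cohort, rate = 0.5, mode = "epigenetic")
  expect_equal(nrow(injE$genotypes$sites), 0L)
  ## record count equals the truth list
  inj <- injectCtMutations(cohort, rate = 0.1, mode = "genetic")
  expect_equal(nrow(inj$genotypes$sites), nrow(inj$truthSites))
  expect_error(injectCtMutations(cohort, rate = 1.5), "rate")
  ## all haplotypes T at every site -> every read reads unmethylated-like
  injT <- injectCtMutations(cohort, rate = 1, mode = "genetic",
                            fwHet = c(1e9, 1e-9), bgHet = c(1e9, 1e-9))
  expect_true(all(injT$hapAlleles == 1L))
  expect_true(all(epireads(injT$epireads)$pattern ==
                    strrep("U", cohort$config$b)))
})

test_that("expression simulation recovers inflated freshwater variance", {
  ## null: no inflation, dVar centered at zero
  null <- simulateExpression(nGenes = 2000L, varEffect = 1, seed = 81L)
  vn <- expressionVariability(
    medianOfRatiosNormalize(null$counts)$normalized, null$design)
  expect_lt(abs(mean(vn$dVar / (vn$mean_expr + 1), na.rm = TRUE)), 0.05)
  ## dispersion x16 in freshwater: inflated genes land in the top quartile
  ## of dVar with probability > 0.9 (Monte Carlo, 200 replicates). The
  ## variability is ranked on log2(normalized + 1), which frees the spread
  ## measure from the gene's absolute expression scale; on the raw scale
  ## high-mean genes drown the ranking (see the methods vignette).
  hit <- 0L; tot <- 0L
  for (rep in 1:200) {
    sim <- simulateExpression(nGenes = 100L, varGenes = 1:5, varEffect = 16,
                              seed = 100L + rep)
    norm <- medianOfRatiosNormalize(sim$counts)$normalized
    v <- expressionVariability(log2(norm + 1), sim$design)
    thr <- quantile(v$dVar, 0.75, names = FALSE)
    hit <- hit + sum(v$dVar[match(sprintf("g%05d", 1:5), v$gene)] >= thr)
    tot <- tot + 5L
  }
  expect_gt(hit / tot, 0.9)
  ## seeded reproducibility
  s1 <- simulateExpression(nGenes = 50L, seed = 9L)
  s2 <- simulateExpression(nGenes = 50L, seed = 9L)
  expect_identical(s1$counts, s2$counts)
})

test_that("cohorts write to plain-text files", {
  cohort <- simulateCohort(simConfig(nWindows = 10L, nMalePerEcotype = 2L,
                                     nFemalePerEcotype = 0L, seed = 91L))
  d <- file.path(tempdir(), "cohort_out")
  writeCohort(cohort, d)
  expect_true(all(file.exists(file.path(
    d, c("epireads.tsv", "design.tsv", "di.bed", "truth_windows.tsv")))))
  es <- readEpireads(file.path(d, "epireads.tsv"),
                     readDesign(file.path(d, "design.tsv")))
  expect_equal(nReads(es), nReads(cohort$epireads))
})
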