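test_that("median-of-ratios normalization behaves like its definition", {
  ## sample B = 2 x sample A: factors proportional to (1, 2), equal columns
  a <- c(10, 50, 200, 7)
  m <- cbind(A = a, B = 2 * a)
  mr <- medianOfRatiosNormalize(m)
  expect_equal(unname(mr$sizeFactors["B"] / mr$sizeFactors["A"]), 2)
  expect_equal(unname(mr$normalized[, "A"]), unname(mr$normalized[, "B"]))
  ## single-gene matrix: (1, 2) up to the geometric-mean convention
  m1 <- matrix(c(10, 20), 1, 2, dimnames = list("g", c("a", "b")))
  sf1 <- medianOfRatiosNormalize(m1)$sizeFactors
  expect_equal(unname(sf1["b"] / sf1["a"]), 2)
  expect_equal(unname(prod(sf1)), 1, tolerance = 1e-12)
  ## scaling one column by c scales factor ratios by c exactly; normalized
  ## columns change only by a common global constant (the reference shifts
  ## by c^(1/n) because it includes the scaled sample)
  set.seed(3)
  r <- matrix(rnbinom(300, mu = 50, size = 5) + 1, 50, 6)
  colnames(r) <- paste0("s", 1:6)
  base <- medianOfRatiosNormalize(r)
  r2 <- r; r2[, 3] <- r2[, 3] * 7
  scaled <- medianOfRatiosNormalize(r2)
  expect_equal(scaled$sizeFactors[3] / scaled$sizeFactors[1],
               7 * base$sizeFactors[3] / base$sizeFactors[1])
  expect_equal(scaled$normalized[, 3] / 7^(1 / 6), base$normalized[, 3])
  expect_equal(scaled$normalized[, 1] / 7^(1 / 6), base$normalized[, 1])
  ## matches the reference implementation of the same definition
  expect_equal(base$sizeFactors,
               DESeq2::estimateSizeFactorsForMatrix(r), tolerance = 1e-12)
  ## all-zero-containing genes cannot anchor the reference
  z <- matrix(c(0, 5, 3, 0), 2, 2)
  expect_error(medianOfRatiosNormalize(z), "nonzero")
})

test_that("expression variability uses the n-1 sample SD per ecotype", {
  design <- data.frame(sample_id = c("f1", "f2", "m1", "m2"),
                       ecotype = c("freshwater", "freshwater",
                                   "marine", "marine"))
  norm <- rbind(gA = c(1, 3, 2, 2),   # freshwater {1,3}: SD = sqrt(2)
                gB = c(5, 5, 1, 9),
                gC = c(0, 0, 0, 0))   # excluded (all zero)
  colnames(norm) <- design$sample_id
  v <- expressionVariability(norm, design)
  expect_equal(v$sd_freshwater[v$gene == "gA"], sqrt(2))
  expect_equal(v$sd_marine[v$gene == "gA"], 0)
  expect_equal(v$dVar[v$gene == "gA"], sqrt(2))
  expect_false("gC" %in% v$gene)
  ## variance option squares the spread
  v2 <- expressionVariability(norm, design, measure = "variance")
  expect_equal(v2$dVar[v2$gene == "gA"], 2)
  ## fewer than two per group -> NA
  v3 <- expressionVariability(norm[, 1:3], design[1:3, ])
  expect_true(all(is.na(v3$sd_marine)))
})

test_that("promoters are strand-aware 1-kb windows upstream of the TSS", {
  delta <- data.frame(window_id = c("c:1", "c:2", "c:3", "c:4"),
                      chrom = "chr1",
                      start0 = c(500, 1500, 2500, 3500),
                      central_pos0 = c(550, 1550, 2550, 3550),
                      delta = c(0.1, 0.2, 0.4, NA))
  tss <- data.frame(gene = c("plus", "minus", "edge", "none"),
                    chrom = "chr1",
                    tss0 = c(1600L, 500L, 700L, 9000L),
                    strand = c("+", "-", "+", "+"))
  pt <- promoterDeltaTable(tss, delta)
  ## + strand: [600, 1600) captures only the central at 1550
  expect_equal(pt$dHb[pt$gene == "plus"], 0.2)
  ## - strand: downstream interval [501, 1501) captures only 550
  expect_equal(pt$dHb[pt$gene == "minus"], 0.1)
  ## clipped at zero without error; [0, 700) captures 550
  expect_equal(pt$promoter_start0[pt$gene == "edge"], 0L)
  expect_equal(pt$dHb[pt$gene == "edge"], 0.1)
  ## NA when no defined-delta window falls inside
  expect_true(is.na(pt$dHb[pt$gene == "none"]))
  expect_equal(pt$n_windows[pt$gene == "none"], 0L)
})

test_that("entropy-expression association computes r and quartile candidates", {
  ## perfectly coupled axes: r = 1
  prom <- data.frame(gene = sprintf("g%02d", 1:8), dHb = (1:8) / 10)
  var <- data.frame(gene = sprintf("g%02d", 1:8), dVar = (1:8) / 10,
                    mean_expr = 1:8)
  a <- entropyExpressionAssociation(prom, var)
  expect_equal(a$r, 1)
  ## constructed so exactly genes 7 and 8 clear both 75th percentiles
  var2 <- var; var2$dVar <- c(8, 7, 6, 5, 4, 3, 9, 10) / 10
  a2 <- entropyExpressionAssociation(prom, var2)
  expect_setequal(a2$candidates$gene, c("g07", "g08"))
  ## candidate choice is invariant to monotone transforms of either axis
  prom3 <- prom; prom3$dHb <- exp(prom$dHb)
  a3 <- entropyExpressionAssociation(prom3, var2)
  expect_setequal(a3$candidates$gene, a2$candidates$gene)
  ## degenerate axis flagged
  promC <- prom; promC$dHb <- 1
  expect_warning(ac <- entropyExpressionAssociation(promC, var), "constant")
  expect_true(is.na(ac$r))
  expect_error(entropyExpressionAssociation(prom[1:2, ], var), "at least 3")
})

test_that("beta-values pool reads within ecotype and respect coverage", {
  design <- data.frame(sample_id = c("f1", "f2", "m1"),
                       ecotype = c("freshwater", "freshwater", "marine"),
                       sex = "male", stringsAsFactors = FALSE)
  pos <- list(as.integer(c(10, 20)), as.integer(c(10, 20)),
              as.integer(c(10, 20)), as.integer(c(10, 20)),
              as.integer(c(10, 20)))
  es <- tinyEpireads(pos, c("MM", "MU", "UM", "MM", "UU"),
                     samples = c("f1", "f1", "f2", "m1", "m1"),
                     design = design)
  bv <- betaValueCompare(es, minCov = 3L)
  b <- bv$beta
  ## freshwater site 10: M, M, U of 3 reads -> 2/3
  expect_equal(b$beta[b$pos0 == 10 & b$ecotype == "freshwater"], 2 / 3)
  ## marine has only 2 reads: below minCov, absent
  expect_false(any(b$ecotype == "marine"))
  expect_true(all(b$beta >= 0 & b$beta <= 1))
  ## pooled beta equals the coverage-weighted mean of per-sample betas
  bf1 <- 1    # f1 at site 10: M,M over 2 reads
  bf2 <- 0    # f2 at site 10: U over 1 read
  expect_equal(b$beta[b$pos0 == 10 & b$ecotype == "freshwater"],
               (2 * bf1 + 1 * bf2) / 3)
  ## all-methylated and 3-of-10 closed forms
  es2 <- tinyEpireads(rep(list(10L), 10),
                      c(rep("M", 3), rep("U", 7)),
                      samples = rep("f1", 10), design = design)
  b2 <- betaValueCompare(es2, minCov = 5L)$beta
  expect_equal(b2$beta, 0.3)
})

test_that("accessibility comparisons are CPM-invariant and null on equality", {
  counts <- matrix(c(5, 9, 13,
                     5, 9, 13,
                     5, 9, 13,
                     5, 9, 13), nrow = 3,
                   dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  design <- data.frame(sample_id = paste0("s", 1:4),
                       ecotype = rep(c("freshwater", "marine"), each = 2))
  acc <- accessibilityCompare(counts, design)
  expect_true(all(acc$comparisons$p_value == 1))
  expect_equal(acc$table$mean_freshwater, acc$table$mean_marine)
  ## scaling one sample's library by 10 changes nothing after CPM
  c2 <- counts; c2[, 2] <- c2[, 2] * 10
  acc2 <- accessibilityCompare(c2, design)
  expect_equal(acc2$table$mean_freshwater, acc$table$mean_freshwater)
  expect_error(accessibilityCompare(cbind(counts, z = 0),
                                    rbind(design,
                                          data.frame(sample_id = "z",
                                                     ecotype = "marine"))),
               "zero library")
})

test_that("null simulated effects give near-zero entropy-expression correlation", {
  rs <- vapply(1:10, function(s) {
    sim <- simulateExpression(nGenes = 3000L, varEffect = 1, seed = 500L + s)
    v <- expressionVariability(
      medianOfRatiosNormalize(sim$counts)$normalized, sim$design)
    set.seed(600L + s)
    prom <- data.frame(gene = v$gene, dHb = rnorm(nrow(v), 0, 0.05))
    entropyExpressionAssociation(prom, v)$r
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.06)
  expect_lt(abs(mean(rs)), 0.02)
})
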