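test_that("genotypes are valid dosages with Hardy-Weinberg means", {
  sc <- TriangleScenario(nSamples = 5000, nSnps = 40, nGenes = 5,
                         mafRange = c(0.5, 0.5), nCausalGenes = 1, seed = 21)
  set.seed(sc@seed)
  g <- simulateGenotypes(sc)
  expect_true(all(g@.Data %in% c(0, 1, 2)))
  # mean dosage 2 * maf = 1 at maf 0.5
  expect_true(all(abs(colMeans(g@.Data) - 1) < 0.05))
})

test_that("LD blocks produce within-block but not across-block correlation", {
  sc <- TriangleScenario(nSamples = 5000, nSnps = 100, nGenes = 5,
                         ldBlockSize = 10, ldR = 0.8, nCausalGenes = 1,
                         seed = 22)
  set.seed(sc@seed)
  g <- simulateGenotypes(sc)
  cc <- cor(g@.Data)
  block <- (seq_len(100) - 1) %/% 10
  adj <- vapply(2:100, function(j)
    if (block[j] == block[j - 1]) cc[j - 1, j] else NA_real_, 0)
  across <- abs(cc[upper.tri(cc)][outer(block, block, "!=")[upper.tri(cc)]])
  expect_gte(median(adj, na.rm = TRUE), 0.6)
  expect_lte(median(across), 0.1)
})

test_that("without planted eQTLs all pair p-values are uniform", {
  sc <- TriangleScenario(nSamples = 200, nSnps = 50, nGenes = 40,
                         eqtlFraction = 0, nCausalGenes = 1, nFactors = 4,
                         ldBlockSize = 1, seed = 23)
  set.seed(sc@seed)
  g <- simulateGenotypes(sc)
  ex <- simulateExpression(g, sc)
  expect_equal(nrow(ex$trueEqtlPairs), 0)
  r <- cor(g@.Data, ex$expression@.Data)
  tt <- r * sqrt((200 - 2) / (1 - r^2))
  pv <- 2 * pt(-abs(tt), 198)
  ks <- suppressWarnings(ks.test(as.vector(pv), "punif"))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(length(pv)))
})

test_that("planted eQTL slopes are recovered by regression", {
  sc <- TriangleScenario(nSamples = 2000, nSnps = 60, nGenes = 60,
                         eqtlFraction = 0.5, eqtlEffect = 1, nCausalGenes = 1,
                         ldBlockSize = 1, seed = 24)
  set.seed(sc@seed)
  g <- simulateGenotypes(sc)
  ex <- simulateExpression(g, sc)
  pairs <- ex$trueEqtlPairs
  ok <- 0
  for (i in seq_len(nrow(pairs))) {
    fit <- summary(lm(ex$expression@.Data[, pairs$gene_id[i]] ~
                        g@.Data[, pairs$snp_id[i]]))$coefficients
    if (abs(fit[2, 1] - 1) <= 3 * fit[2, 2]) ok <- ok + 1
  }
  expect_gte(ok / nrow(pairs), 0.95)
})

test_that("factor loadings control gene-gene correlation", {
  sc <- TriangleScenario(nSamples = 5000, nSnps = 10, nGenes = 2,
                         nFactors = 1, eqtlFraction = 0, nCausalGenes = 1,
                         ldBlockSize = 1, seed = 25)
  set.seed(sc@seed)
  g <- simulateGenotypes(sc)
  L <- matrix(0.9, nrow = 2, ncol = 1)
  ex <- simulateExpression(g, sc, loadings = L)
  r <- cor(ex$expression@.Data[, 1], ex$expression@.Data[, 2])
  expect_lt(abs(r - 0.81), 0.05)
})

test_that("phenotype variance decomposition matches the requested R2", {
  sc <- TriangleScenario(nSamples = 2000, nSnps = 50, nGenes = 40,
                         nCausalGenes = 5, phenotypeR2 = 0.5, seed = 26)
  set.seed(sc@seed)
  g <- simulateGenotypes(sc)
  ex <- simulateExpression(g, sc)
  ph <- simulatePhenotype(ex$expression, sc)
  fit <- summary(lm(phenotype(ph$phenotype) ~
                      ex$expression@.Data[, ph$causalGenes]))
  expect_lt(abs(fit$r.squared - 0.5), 0.05)
})

test_that("the pure-null phenotype is independent of expression", {
  sc <- TriangleScenario(nSamples = 2000, nSnps = 20, nGenes = 50,
                         phenotypeR2 = 0, seed = 27)
  d <- simulateTriangleData(sc)
  expect_identical(d$truth$causalGenes, character(0))
  expect_identical(d$truth$signalSnps, character(0))
  r <- abs(cor(phenotype(d$phenotype), d$expression@.Data))
  # Bonferroni 1% envelope for the max of nGenes null correlations
  envelope <- qnorm(1 - 0.01 / (2 * 50)) / sqrt(2000)
  expect_lt(max(r), envelope * 1.5)
})

test_that("generation is reproducible and truth labels are consistent", {
  sc <- TriangleScenario(nSamples = 80, nSnps = 60, nGenes = 30, seed = 28)
  d1 <- simulateTriangleData(sc)
  d2 <- simulateTriangleData(sc)
  expect_identical(d1$dosages@.Data, d2$dosages@.Data)
  expect_identical(phenotype(d1$phenotype), phenotype(d2$phenotype))

  tr <- d1$truth
  derived <- sort(unique(
    tr$trueEqtlPairs$snp_id[tr$trueEqtlPairs$gene_id %in% tr$causalGenes]))
  expect_identical(tr$signalSnps, derived)
  expect_true(all(tr$signalSnps %in% tr$linkedSnps))
  # every generated object satisfies its class invariants en route
  expect_true(validObject(d1$dosages))
  expect_true(validObject(d1$expression))
  expect_true(validObject(d1$phenotype))
})

test_that("a generated study round-trips through the on-disk formats", {
  sc <- TriangleScenario(nSamples = 20, nSnps = 12, nGenes = 6,
                         nCausalGenes = 2, seed = 29)
  d <- simulateTriangleData(sc)
  dir <- withr::local_tempdir()
  writeTriangleData(d, dir, eqtlMap = computeEqtlMap(d$dosages, d$expression,
                                                     0.5))
  suppressMessages({
    back <- loadTriangleData(file.path(dir, "genotype.tsv"),
                             file.path(dir, "expression.tsv"),
                             file.path(dir, "phenotype.tsv"),
                             file.path(dir, "eqtl_map.tsv"), mafMin = 0)
  })
  expect_equal(back$dosages@.Data, d$dosages@.Data)
  expect_equal(back$expression@.Data, d$expression@.Data)
  expect_equal(phenotype(back$phenotype), phenotype(d$phenotype))
})
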