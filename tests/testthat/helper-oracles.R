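# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately use naive one-at-a-time computation (lm() loops,
# double-loop counting) so they share no code path with the package.

# Brute-force direct-count eFDR/q computation.
bruteEfdrOracle <- function(obsP, simP, lambda = 0.5, conservative = FALSE) {
  m <- length(obsP)
  M0 <- length(simP)
  if (conservative) {
    pi0 <- 1
  } else {
    den <- 0
    for (s in simP) if (s > lambda) den <- den + 1
    num <- 0
    for (o in obsP) if (o > lambda) num <- num + 1
    pi0 <- if (den == 0 || num == 0) 1 else min((num / m) / (den / M0), 1)
  }
  ord <- order(obsP)
  ps <- obsP[ord]
  efdr <- numeric(m)
  for (i in seq_len(m)) {
    t <- ps[i]
    ns <- 0
    for (s in simP) if (s <= t) ns <- ns + 1
    no <- 0
    for (o in ps) if (o <= t) no <- no + 1
    efdr[i] <- if (M0 > 0 && ns == 0) 0 else min((ns / M0) / (no / m) * pi0, 1)
  }
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(efdr[i:m])
  list(p = ps, efdr = efdr, q = q, pi0 = pi0)
}

# One-feature-at-a-time OLS via lm(); the reference for massRegression.
lmOracle <- function(X, y, covariates = NULL) {
  out <- data.frame(beta = numeric(ncol(X)), pvalue = numeric(ncol(X)))
  for (j in seq_len(ncol(X))) {
    fit <- if (is.null(covariates)) lm(y ~ X[, j])
           else lm(y ~ X[, j] + covariates)
    sm <- summary(fit)$coefficients
    out$beta[j] <- sm[2, 1]
    out$pvalue[j] <- sm[2, 4]
  }
  out
}

# Straight-line reimplementation of the triangle filter: explicit loops over
# genes and SNPs, lm() per association (fixtures without covariates).
naiveTriangleOracle <- function(expr, pheno, dosages, eqtlMap, th) {
  y <- phenotype(pheno)
  genes <- character(0)
  for (g in colnames(expr)) {
    p <- summary(lm(y ~ expr@.Data[, g]))$coefficients[2, 4]
    if (p < th@pGenePhenotype) genes <- c(genes, g)
  }
  rec <- eqtlRecords(eqtlMap)
  snps <- character(0)
  prov <- list()
  for (s in unique(rec$snp_id)) {
    sup <- character(0)
    for (i in which(rec$snp_id == s))
      if (rec$pvalue[i] < th@pSnpGene && rec$gene_id[i] %in% genes)
        sup <- c(sup, rec$gene_id[i])
    sup <- sort(unique(sup))
    if (length(sup) >= th@minGeneCount && s %in% colnames(dosages)) {
      snps <- c(snps, s)
      prov[[s]] <- sup
    }
  }
  pv <- numeric(0)
  for (s in snps) {
    p <- summary(lm(y ~ dosages@.Data[, s]))$coefficients[2, 4]
    if (p < th@pSnpPhenotype) pv[s] <- p
  }
  list(genes = genes, snpsEqtl = snps, pv = pv, prov = prov[names(pv)])
}

# Small aligned fixture with a toy random eQTL map (independent of
# computeEqtlMap) for triangle/permutation tests.
makeToyFixture <- function(n = 30, nSnps = 40, nGenes = 8, seed = 71,
                           withCovariate = FALSE) {
  sc <- TriangleScenario(nSamples = n, nSnps = nSnps, nGenes = nGenes,
                         ldBlockSize = 5, nFactors = 3, eqtlFraction = 0.5,
                         nCausalGenes = 2, phenotypeR2 = 0.3, seed = seed)
  d <- simulateTriangleData(sc)
  set.seed(seed + 1)
  rec <- expand.grid(snp_id = colnames(d$dosages),
                     gene_id = colnames(d$expression),
                     stringsAsFactors = FALSE)
  rec <- rec[sample(nrow(rec), nSnps * 3), ]
  rec$pvalue <- 10^runif(nrow(rec), -8, 0)
  d$eqtlMap <- EqtlMap(rec)
  if (withCovariate) {
    y <- phenotype(d$phenotype)
    cv <- matrix(rnorm(length(y)), ncol = 1,
                 dimnames = list(names(y), "age"))
    d$phenotype <- PhenotypeVector(y, cv)
  }
  d
}
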