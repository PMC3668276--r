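#' Run the full prioritization + empirical FDR pipeline
#'
#' Orchestrates the end-to-end analysis: build (or accept) the eQTL map once,
#' run the observed triangle filter, build the permutation null pool with the
#' identical filter, and estimate empirical FDR q-values (plus the naive
#' uniform-null comparator) for the prioritized SNPs. Every random draw flows
#' from `seed`; re-running with the same inputs reproduces the FdrTable
#' exactly.
#'
#' @param data list with `dosages`, `expression`, `phenotype` and optionally
#'   `eqtlMap` -- either from [loadTriangleData()] or
#'   [simulateTriangleData()].
#' @param thresholds a [TriangleThresholds-class].
#' @param nPermutations permutation replicates for the null pool.
#' @param seed integer master seed.
#' @param lambda pi0 tail cutoff.
#' @param conservative logical; fix pi0 = 1.
#' @param outputDir optional directory; when given, the FdrTable, the null
#'   pool and QQ coordinates (observed SNPs and pooled null) are written
#'   there.
#' @return list with `observed` ([TriangleResult-class]), `nullPool`
#'   ([NullPool-class]), `fdr` ([FdrTable-class]) and `eqtlMap`.
#' @examples
#' d <- simulateTriangleData(TriangleScenario(nSamples = 60, nSnps = 100,
#'                                            nGenes = 30, seed = 11))
#' res <- runTrianglePipeline(d, nPermutations = 25, seed = 5)
#' res$fdr
#' @export
runTrianglePipeline <- function(data, thresholds = TriangleThresholds(),
                                nPermutations = 1000, seed = 1,
                                lambda = 0.5, conservative = FALSE,
                                outputDir = NULL) {
  eqtlMap <- data$eqtlMap
  if (is.null(eqtlMap))
    eqtlMap <- computeEqtlMap(data$dosages, data$expression,
                              thresholds@pSnpGene)
  observed <- runTriangle(data$expression, data$phenotype, data$dosages,
                          eqtlMap, thresholds)
  message(sprintf("observed triangle: %s",
                  paste(names(stageCounts(observed)), stageCounts(observed),
                        sep = "=", collapse = ", ")))
  pool <- buildNullPool(data$expression, data$phenotype, data$dosages,
                        eqtlMap, thresholds, n = nPermutations, seed = seed)
  message(sprintf("null pool: M0 = %d from %d permutations", nullSize(pool),
                  pool@n))
  meta <- list(n_permutations = nPermutations, seed = seed,
               p_gene_phenotype = thresholds@pGenePhenotype,
               p_snp_gene = thresholds@pSnpGene,
               p_snp_phenotype = thresholds@pSnpPhenotype,
               min_gene_count = thresholds@minGeneCount)
  fdr <- efdrQvalues(observed, pool, lambda = lambda,
                     conservative = conservative, metadata = meta)
  message(sprintf("eFDR: m = %d, M0 = %d, pi0 = %.4g", fdr@m, fdr@M0,
                  fdr@pi0))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeFdrTable(fdr, file.path(outputDir, "fdr_table.tsv"))
    writeNullPool(pool, file.path(outputDir, "null_pool.tsv"))
    if (length(snpPvalues(observed)))
      write.table(.fullPrecision(qqCoordinates(snpPvalues(observed))),
                  file.path(outputDir, "qq_observed.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (nullSize(pool))
      write.table(.fullPrecision(qqCoordinates(pooledPvalues(pool))),
                  file.path(outputDir, "qq_null.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  list(observed = observed, nullPool = pool, fdr = fdr, eqtlMap = eqtlMap)
}
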