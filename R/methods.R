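#' @rdname accessors
setMethod("sampleIds", "DosageMatrix", function(x) rownames(x))
#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) rownames(x))
#' @rdname accessors
setMethod("sampleIds", "PhenotypeVector", function(x) names(x@y))
#' @rdname accessors
setMethod("snpIds", "DosageMatrix", function(x) colnames(x))
#' @rdname accessors
setMethod("snpIds", "EqtlMap", function(x) unique(x@records$snp_id))
#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) colnames(x))
#' @rdname accessors
setMethod("geneIds", "EqtlMap", function(x) unique(x@records$gene_id))
#' @rdname accessors
setMethod("phenotype", "PhenotypeVector", function(x) x@y)
#' @rdname accessors
setMethod("covariates", "PhenotypeVector", function(x) x@covariates)
#' @rdname accessors
setMethod("eqtlRecords", "EqtlMap", function(x) x@records)
#' @rdname accessors
setMethod("snpPvalues", "TriangleResult", function(x) x@snpPvalues)
#' @rdname accessors
setMethod("selectedGenes", "TriangleResult", function(x) x@selectedGenes)
#' @rdname accessors
setMethod("provenance", "TriangleResult", function(x) x@provenance)
#' @rdname accessors
setMethod("stageCounts", "TriangleResult", function(x) x@stageCounts)
#' @rdname accessors
setMethod("pooledPvalues", "NullPool", function(x) x@pooledPvalues)
#' @rdname accessors
setMethod("perReplicateCounts", "NullPool", function(x) x@perReplicateCounts)
#' @rdname accessors
setMethod("nullSize", "NullPool", function(x) length(x@pooledPvalues))
#' @rdname accessors
setMethod("fdrTable", "FdrTable", function(x) x@table)
#' @rdname accessors
setMethod("pi0", "FdrTable", function(x) x@pi0)

setMethod("show", "DosageMatrix", function(object) {
  cat(sprintf("DosageMatrix: %d samples x %d SNPs\n", nrow(object), ncol(object)))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d samples x %d genes\n",
              nrow(object), ncol(object)))
})

setMethod("show", "PhenotypeVector", function(object) {
  cat(sprintf("PhenotypeVector: %d samples, %d covariate(s)\n",
              length(object@y), ncol(object@covariates)))
})

setMethod("show", "EqtlMap", function(object) {
  rec <- object@records
  cat(sprintf("EqtlMap: %d records (%d SNPs, %d genes)\n", nrow(rec),
              length(unique(rec$snp_id)), length(unique(rec$gene_id))))
})

setMethod("show", "TriangleThresholds", function(object) {
  cat("TriangleThresholds:\n",
      sprintf("  p(gene-phenotype) < %g\n", object@pGenePhenotype),
      sprintf("  p(SNP-gene)       < %g\n", object@pSnpGene),
      sprintf("  p(SNP-phenotype)  < %g\n", object@pSnpPhenotype),
      sprintf("  min supporting genes: %d; MAF floor: %g\n",
              object@minGeneCount, object@mafMin), sep = "")
})

setMethod("show", "TriangleResult", function(object) {
  cat(sprintf("TriangleResult: %d selected genes, %d prioritized SNPs\n",
              length(object@selectedGenes), length(object@snpPvalues)))
  if (length(object@stageCounts))
    cat("  stage counts:",
        paste(names(object@stageCounts), object@stageCounts,
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "NullPool", function(object) {
  cat(sprintf("NullPool: M0 = %d p-values from n = %d permutations (seed %d)\n",
              length(object@pooledPvalues), object@n, object@seed))
})

setMethod("show", "FdrTable", function(object) {
  cat(sprintf(
    "FdrTable: %d SNPs (m = %d, M0 = %d), lambda = %g, pi0 = %.4g%s\n",
    nrow(object@table), object@m, object@M0, object@lambda, object@pi0,
    if (object@conservative) " [conservative]" else ""))
  if (nrow(object@table)) print(head(object@table, 5))
})

setMethod("show", "TriangleScenario", function(object) {
  cat(sprintf(
    "TriangleScenario: %d samples, %d SNPs, %d genes%s (seed %d)\n",
    object@nSamples, object@nSnps, object@nGenes,
    if (object@phenotypeR2 == 0) " [pure null]"
    else sprintf(", phenotype R2 = %g via %d causal genes",
                 object@phenotypeR2, object@nCausalGenes),
    object@seed))
})
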