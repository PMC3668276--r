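#' @import methods
#' @importFrom stats pt cor rnorm rbinom runif sd var setNames
#' @importFrom utils read.delim write.table head
NULL

.checkUniqueNames <- function(nm, what) {
  if (is.null(nm)) return(sprintf("%s must be named", what))
  if (anyDuplicated(nm)) return(sprintf("duplicated %s", what))
  if (any(is.na(nm) | nm == "")) return(sprintf("empty or NA %s", what))
  NULL
}

#' DosageMatrix: samples-by-SNPs genotype dosages
#'
#' A numeric matrix (rows = samples, columns = SNPs) of allele dosages in
#' [0, 2]: the genotype arm of the triangle. Missing entries must be resolved
#' (e.g., mean-imputed) before construction; monomorphic SNPs are rejected by
#' [readDosageMatrix()] at load time but tolerated here so that permutation
#' machinery can operate on arbitrary subsets.
#'
#' @slot .Data numeric matrix, samples x SNPs, dosages in [0, 2].
#' @export
setClass("DosageMatrix", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (!is.numeric(v)) return("dosages must be numeric")
  if (anyNA(v)) return("dosages contain NA; apply an imputation policy first")
  if (length(v) && (min(v) < 0 || max(v) > 2)) return("dosages must lie in [0, 2]")
  msg <- c(.checkUniqueNames(rownames(v), "sample ids (rownames)"),
           .checkUniqueNames(colnames(v), "SNP ids (colnames)"))
  if (length(msg)) msg else TRUE
})

#' ExpressionMatrix: samples-by-genes expression values
#'
#' A numeric matrix (rows = samples, columns = genes) of quantitative gene
#' expression: the molecular-trait arm of the triangle.
#'
#' @slot .Data numeric matrix, samples x genes, finite values.
#' @export
setClass("ExpressionMatrix", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (!is.numeric(v)) return("expression values must be numeric")
  if (length(v) && !all(is.finite(v))) return("expression values must be finite")
  msg <- c(.checkUniqueNames(rownames(v), "sample ids (rownames)"),
           .checkUniqueNames(colnames(v), "gene ids (colnames)"))
  if (length(msg)) msg else TRUE
})

#' PhenotypeVector: quantitative trait with optional covariates
#'
#' The phenotype (e.g., log IC50) per sample, with optional covariates whose
#' rows are index-locked to the trait: any permutation moves them together.
#' This is the only object the permutation null ever touches.
#'
#' @slot y named numeric vector of trait values.
#' @slot covariates numeric matrix (samples x c) or a 0-column matrix when no
#'   covariates are present; rownames match names(y).
#' @export
setClass("PhenotypeVector",
  representation(y = "numeric", covariates = "matrix"),
  validity = function(object) {
    msg <- .checkUniqueNames(names(object@y), "sample ids (names of y)")
    if (!is.null(msg)) return(msg)
    if (anyNA(object@y)) return("phenotype values contain NA")
    cv <- object@covariates
    if (ncol(cv) > 0) {
      if (nrow(cv) != length(object@y)) return("covariate rows must match y length")
      if (!is.numeric(cv)) return("covariates must be numeric")
      if (anyNA(cv)) return("covariates contain NA")
      if (is.null(colnames(cv))) return("covariate columns must be labelled")
    }
    TRUE
  })

#' EqtlMap: SNP-gene association records
#'
#' The fixed "genetic machinery" of the analysis: (snp_id, gene_id, pvalue)
#' records, typically a SCAN-style database export or the output of
#' [computeEqtlMap()]. Queried per selected gene; never recomputed during
#' permutation.
#'
#' @slot records data.frame with columns `snp_id`, `gene_id`, `pvalue`;
#'   no duplicated (snp, gene) pairs; pvalue in (0, 1].
#' @export
setClass("EqtlMap", representation(records = "data.frame"),
  validity = function(object) {
    rec <- object@records
    need <- c("snp_id", "gene_id", "pvalue")
    if (!all(need %in% names(rec))) return("records need snp_id, gene_id, pvalue")
    if (nrow(rec)) {
      if (anyDuplicated(rec[c("snp_id", "gene_id")])) return("duplicated (snp, gene) pairs")
      if (any(rec$pvalue <= 0 | rec$pvalue > 1)) return("pvalue must lie in (0, 1]")
    }
    TRUE
  })

#' TriangleThresholds: the filter cutoffs of the triangle method
#'
#' All three p-value thresholds are applied with strict `<`; ties at a cutoff
#' are excluded. `minGeneCount > 1` activates the hub-eQTL variant in which a
#' SNP must be an eQTL for several phenotype-associated genes.
#'
#' @slot pGenePhenotype gene--phenotype p-value cutoff (default 0.05).
#' @slot pSnpGene SNP--gene (eQTL) p-value cutoff (default 1e-4).
#' @slot pSnpPhenotype final-arm SNP--phenotype cutoff (default 1: no final
#'   filtering, applied identically to observed and permuted runs).
#' @slot minGeneCount minimum number of supporting selected genes per SNP.
#' @slot mafMin minor-allele-frequency floor applied at genotype load time.
#' @export
setClass("TriangleThresholds",
  representation(pGenePhenotype = "numeric", pSnpGene = "numeric",
                 pSnpPhenotype = "numeric", minGeneCount = "integer",
                 mafMin = "numeric"),
  prototype(pGenePhenotype = 0.05, pSnpGene = 1e-4, pSnpPhenotype = 1,
            minGeneCount = 1L, mafMin = 0.05),
  validity = function(object) {
    p <- c(object@pGenePhenotype, object@pSnpGene, object@pSnpPhenotype)
    if (length(p) != 3 || any(p < 0 | p > 1)) return("p cutoffs must lie in [0, 1]")
    if (object@minGeneCount < 1L) return("minGeneCount must be >= 1")
    if (object@mafMin < 0 || object@mafMin >= 0.5) return("mafMin must lie in [0, 0.5)")
    TRUE
  })

#' TriangleResult: prioritized SNPs and their observed p-values
#'
#' @slot selectedGenes character vector of phenotype-associated genes
#'   (stage 1 survivors).
#' @slot snpPvalues named numeric vector: phenotype-association p-value per
#'   prioritized SNP (the observed p's the eFDR is computed on).
#' @slot provenance named list: for each SNP, the selected genes it supports
#'   as an eQTL.
#' @slot stageCounts named integer vector of survivors per filter stage.
#' @export
setClass("TriangleResult",
  representation(selectedGenes = "character", snpPvalues = "numeric",
                 provenance = "list", stageCounts = "integer"),
  validity = function(object) {
    p <- object@snpPvalues
    if (length(p)) {
      if (is.null(names(p)) || anyDuplicated(names(p))) return("snpPvalues must have unique names")
      if (any(p <= 0 | p > 1)) return("snpPvalues must lie in (0, 1]")
      if (!setequal(names(p), names(object@provenance)))
        return("provenance must cover exactly the prioritized SNPs")
      genes <- unique(unlist(object@provenance, use.names = FALSE))
      if (!all(genes %in% object@selectedGenes))
        return("supporting genes must be selected genes")
    }
    TRUE
  })

#' NullPool: the empirical null distribution of p-values
#'
#' Pooled SNP--phenotype p-values from n permuted-phenotype runs of the
#' identical triangle filter, with per-replicate counts m_0s and their total
#' M0.
#'
#' @slot pooledPvalues numeric vector of pooled null p-values (length M0).
#' @slot perReplicateCounts integer vector m_0s, one per permutation replicate.
#' @slot n number of permutation replicates.
#' @slot seed master seed the replicate substreams were derived from.
#' @export
setClass("NullPool",
  representation(pooledPvalues = "numeric", perReplicateCounts = "integer",
                 n = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@perReplicateCounts) != object@n)
      return("need one replicate count per permutation")
    if (sum(object@perReplicateCounts) != length(object@pooledPvalues))
      return("M0 must equal the sum of per-replicate counts")
    p <- object@pooledPvalues
    if (length(p) && any(p <= 0 | p > 1)) return("pooled p-values must lie in (0, 1]")
    TRUE
  })

#' FdrTable: per-SNP empirical FDR and q-values
#'
#' @slot table data.frame with columns `snp_id`, `genes` (comma-joined
#'   supporting genes), `p_obs`, `naive_q`, `efdr`, `q_efdr`, sorted by
#'   `p_obs`.
#' @slot lambda tail cutoff used for pi0 estimation.
#' @slot pi0 the pi0 estimate actually used (1 in conservative mode).
#' @slot m number of observed (prioritized) SNPs.
#' @slot M0 size of the permutation null pool.
#' @slot conservative logical; TRUE when pi0 was fixed at 1.
#' @slot metadata list of run provenance (thresholds, n permutations, seed).
#' @export
setClass("FdrTable",
  representation(table = "data.frame", lambda = "numeric", pi0 = "numeric",
                 m = "integer", M0 = "integer", conservative = "logical",
                 metadata = "list"),
  validity = function(object) {
    tb <- object@table
    need <- c("snp_id", "genes", "p_obs", "naive_q", "efdr", "q_efdr")
    if (!all(need %in% names(tb))) return("missing FdrTable columns")
    if (nrow(tb)) {
      if (is.unsorted(tb$p_obs)) return("rows must be sorted by p_obs")
      if (is.unsorted(tb$q_efdr)) return("q_efdr must be nondecreasing in p_obs")
      qs <- c(tb$naive_q, tb$efdr, tb$q_efdr)
      if (any(qs < 0 | qs > 1)) return("FDR quantities must lie in [0, 1]")
    }
    if (object@pi0 <= 0 || object@pi0 > 1) return("pi0 must lie in (0, 1]")
    TRUE
  })

#' TriangleScenario: parameters of the synthetic-data generator
#'
#' Describes a synthetic genotype/expression/phenotype study: LD-block
#' genotypes, factor-correlated expression with planted eQTL effects, and a
#' phenotype mediated by causal gene expression. `phenotypeR2 = 0` defines the
#' pure-null scenario (phenotype independent of everything).
#'
#' @slot nSamples,nSnps,nGenes dimensions of the simulated study.
#' @slot mafRange length-2 interval in (0, 0.5] the per-SNP MAF is drawn from.
#' @slot ldBlockSize SNPs per LD block.
#' @slot ldR within-block haplotype-copy probability (target adjacent-SNP
#'   dosage correlation), in [0, 1).
#' @slot nFactors latent factors generating gene-gene correlation.
#' @slot eqtlFraction fraction of genes with a planted eQTL.
#' @slot eqtlEffect planted eQTL slope (expression units per dosage unit).
#' @slot nCausalGenes number of genes mediating the phenotype.
#' @slot phenotypeR2 fraction of phenotype variance explained by the causal
#'   genes, in [0, 1).
#' @slot seed integer seed for reproducible generation.
#' @export
setClass("TriangleScenario",
  representation(nSamples = "integer", nSnps = "integer", nGenes = "integer",
                 mafRange = "numeric", ldBlockSize = "integer", ldR = "numeric",
                 nFactors = "integer", eqtlFraction = "numeric",
                 eqtlEffect = "numeric", nCausalGenes = "integer",
                 phenotypeR2 = "numeric", seed = "integer"),
  prototype(nSamples = 200L, nSnps = 3000L, nGenes = 300L,
            mafRange = c(0.1, 0.5), ldBlockSize = 10L, ldR = 0.8,
            nFactors = 10L, eqtlFraction = 0.3, eqtlEffect = 1,
            nCausalGenes = 10L, phenotypeR2 = 0.4, seed = 1L),
  validity = function(object) {
    if (any(c(object@nSamples, object@nSnps, object@nGenes,
              object@ldBlockSize, object@nFactors) < 1L))
      return("counts must be >= 1")
    mr <- object@mafRange
    if (length(mr) != 2 || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5)
      return("mafRange must be an interval within (0, 0.5]")
    if (object@ldR < 0 || object@ldR >= 1) return("ldR must lie in [0, 1)")
    if (object@eqtlFraction < 0 || object@eqtlFraction > 1)
      return("eqtlFraction must lie in [0, 1]")
    if (object@phenotypeR2 < 0 || object@phenotypeR2 >= 1)
      return("phenotypeR2 must lie in [0, 1)")
    if (object@nCausalGenes > object@nGenes)
      return("nCausalGenes must not exceed nGenes")
    TRUE
  })
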