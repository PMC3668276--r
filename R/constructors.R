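#' Construct a DosageMatrix
#'
#' @param values numeric matrix, samples in rows, SNPs in columns, with
#'   complete dimnames; entries are allele dosages in [0, 2].
#' @return A [DosageMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 1, 0), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), c("rs1", "rs2")))
#' DosageMatrix(m)
#' @export
DosageMatrix <- function(values) {
  new("DosageMatrix", as.matrix(values))
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, samples in rows, genes in columns, with
#'   complete dimnames.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values) {
  new("ExpressionMatrix", as.matrix(values))
}

#' Construct a PhenotypeVector
#'
#' @param y named numeric vector of trait values (names are sample ids).
#' @param covariates optional numeric matrix (samples x c) with labelled
#'   columns, rows aligned to `y`.
#' @return A [PhenotypeVector-class] object.
#' @export
PhenotypeVector <- function(y, covariates = NULL) {
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = length(y), ncol = 0,
                         dimnames = list(names(y), NULL))
  covariates <- as.matrix(covariates)
  if (is.null(rownames(covariates)) && nrow(covariates) == length(y))
    rownames(covariates) <- names(y)
  new("PhenotypeVector", y = y, covariates = covariates)
}

#' Construct an EqtlMap
#'
#' @param records data.frame with character columns `snp_id`, `gene_id` and a
#'   numeric `pvalue` column in (0, 1].
#' @return An [EqtlMap-class] object.
#' @export
EqtlMap <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$snp_id <- as.character(records$snp_id)
  records$gene_id <- as.character(records$gene_id)
  rownames(records) <- NULL
  new("EqtlMap", records = records)
}

#' Construct the triangle filter thresholds
#'
#' Defaults follow the method's standard application: genes kept at
#' p < 0.05 against the phenotype, SNPs kept as eQTLs at p < 1e-4, and no
#' final-arm SNP--phenotype filtering (cutoff 1), applied identically to
#' observed and permuted runs.
#'
#' @param pGenePhenotype gene--phenotype p-value cutoff.
#' @param pSnpGene SNP--gene (eQTL) p-value cutoff.
#' @param pSnpPhenotype final-arm SNP--phenotype p-value cutoff.
#' @param minGeneCount minimum supporting selected genes per SNP (> 1
#'   activates the hub-eQTL variant).
#' @param mafMin MAF floor applied when genotypes are loaded from disk.
#' @return A [TriangleThresholds-class] object.
#' @export
TriangleThresholds <- function(pGenePhenotype = 0.05, pSnpGene = 1e-4,
                               pSnpPhenotype = 1, minGeneCount = 1,
                               mafMin = 0.05) {
  new("TriangleThresholds", pGenePhenotype = pGenePhenotype,
      pSnpGene = pSnpGene, pSnpPhenotype = pSnpPhenotype,
      minGeneCount = as.integer(minGeneCount), mafMin = mafMin)
}

#' Describe a synthetic study scenario
#'
#' The default is a desk-scale study (200 samples, 3000 SNPs, 300 genes)
#' preserving the structural features the method depends on: LD among
#' genotypes, gene-gene correlation through latent factors, planted eQTL
#' effects, and a phenotype mediated by causal gene expression. Set
#' `phenotypeR2 = 0` for the pure-null scenario.
#'
#' @param nSamples,nSnps,nGenes study dimensions.
#' @param mafRange interval in (0, 0.5] the per-SNP MAF is drawn from.
#' @param ldBlockSize SNPs per LD block.
#' @param ldR within-block haplotype-copy probability in [0, 1).
#' @param nFactors latent factors inducing gene-gene correlation.
#' @param eqtlFraction fraction of genes given a planted eQTL.
#' @param eqtlEffect planted eQTL slope per dosage unit.
#' @param nCausalGenes genes mediating the phenotype.
#' @param phenotypeR2 phenotype variance fraction from causal genes.
#' @param seed integer seed.
#' @return A [TriangleScenario-class] object.
#' @export
TriangleScenario <- function(nSamples = 200, nSnps = 3000, nGenes = 300,
                             mafRange = c(0.1, 0.5), ldBlockSize = 10,
                             ldR = 0.8, nFactors = 10, eqtlFraction = 0.3,
                             eqtlEffect = 1, nCausalGenes = 10,
                             phenotypeR2 = 0.4, seed = 1) {
  new("TriangleScenario", nSamples = as.integer(nSamples),
      nSnps = as.integer(nSnps), nGenes = as.integer(nGenes),
      mafRange = mafRange, ldBlockSize = as.integer(ldBlockSize), ldR = ldR,
      nFactors = as.integer(nFactors), eqtlFraction = eqtlFraction,
      eqtlEffect = eqtlEffect, nCausalGenes = as.integer(nCausalGenes),
      phenotypeR2 = phenotypeR2, seed = as.integer(seed))
}
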