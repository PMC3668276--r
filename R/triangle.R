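#' Stage 1: select phenotype-associated gene expression traits
#'
#' @param geneAssoc data.frame from [massRegression()] (columns `feature_id`,
#'   `pvalue`) of gene expression against the phenotype.
#' @param pGenePhenotype p-value cutoff; genes with p strictly below it are
#'   kept (ties at the cutoff excluded).
#' @return Character vector of selected gene ids (possibly empty).
#' @export
selectGenes <- function(geneAssoc, pGenePhenotype) {
  geneAssoc$feature_id[geneAssoc$pvalue < pGenePhenotype]
}

#' Stage 2: select SNPs that are eQTLs of the selected genes
#'
#' Keeps SNPs with eQTL-map records below `pSnpGene` to at least
#' `minGeneCount` of the selected genes. `minGeneCount > 1` is the hub-eQTL
#' (master regulator) variant. Each SNP appears once regardless of how many
#' genes support it; the supporting genes are returned as provenance.
#'
#' @param eqtlMap an [EqtlMap-class].
#' @param genes character vector of selected gene ids.
#' @param pSnpGene p-value cutoff (strict `<`).
#' @param minGeneCount minimum number of supporting selected genes.
#' @return A list with `snps` (character vector) and `provenance` (named list
#'   of supporting gene ids per SNP).
#' @export
selectSnps <- function(eqtlMap, genes, pSnpGene, minGeneCount = 1) {
  rec <- eqtlRecords(eqtlMap)
  keep <- rec$pvalue < pSnpGene & rec$gene_id %in% genes
  rec <- rec[keep, , drop = FALSE]
  if (!nrow(rec)) return(list(snps = character(0), provenance = list()))
  prov <- split(rec$gene_id, rec$snp_id)
  prov <- prov[lengths(prov) >= minGeneCount]
  prov <- lapply(prov, function(g) sort(unique(g)))
  snps <- sort(names(prov))
  list(snps = snps, provenance = prov[snps])
}

#' Run the integrative triangle filter
#'
#' Composes the three arms: (1) genes associated with the phenotype at
#' p < pGenePhenotype; (2) SNPs that are eQTLs (p < pSnpGene in the fixed
#' eQTL map) of at least `minGeneCount` selected genes; (3) the surviving
#' SNPs tested for association with the phenotype, retaining those with
#' p < pSnpPhenotype together with their observed p-values. Covariates, when
#' present in `pheno`, are adjusted for in arms 1 and 3.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param pheno a [PhenotypeVector-class], samples aligned with `expr` and
#'   `dosages`.
#' @param dosages a [DosageMatrix-class].
#' @param eqtlMap an [EqtlMap-class]; treated as fixed genetic machinery.
#' @param thresholds a [TriangleThresholds-class].
#' @return A [TriangleResult-class] with the prioritized SNPs, their
#'   phenotype-association p-values, per-SNP supporting genes, and stage-wise
#'   survivor counts. An empty cascade yields an empty result, not an error.
#' @examples
#' sc <- TriangleScenario(nSamples = 60, nSnps = 80, nGenes = 30,
#'                        nCausalGenes = 3, seed = 7)
#' d <- simulateTriangleData(sc)
#' em <- computeEqtlMap(d$dosages, d$expression, 1e-3)
#' runTriangle(d$expression, d$phenotype, d$dosages, em,
#'             TriangleThresholds(pSnpGene = 1e-3))
#' @export
runTriangle <- function(expr, pheno, dosages, eqtlMap, thresholds) {
  if (!identical(rownames(expr), sampleIds(pheno)) ||
      !identical(rownames(dosages), sampleIds(pheno)))
    stop("expression, genotype and phenotype samples are not aligned")
  cv <- covariates(pheno)
  if (ncol(cv) == 0L) cv <- NULL

  geneAssoc <- massRegression(expr@.Data, phenotype(pheno), cv)
  genes <- selectGenes(geneAssoc, thresholds@pGenePhenotype)

  sel <- selectSnps(eqtlMap, genes, thresholds@pSnpGene,
                    thresholds@minGeneCount)
  snps <- intersect(sel$snps, colnames(dosages))

  pv <- numeric(0)
  if (length(snps)) {
    snpAssoc <- massRegression(dosages@.Data[, snps, drop = FALSE],
                               phenotype(pheno), cv)
    pv <- setNames(snpAssoc$pvalue, snpAssoc$feature_id)
    pv <- pv[pv < thresholds@pSnpPhenotype]
    pv <- pv[order(names(pv))]
  }

  counts <- c(genes_selected = length(genes),
              snps_eqtl = length(snps),
              snps_final = length(pv))
  new("TriangleResult", selectedGenes = as.character(genes),
      snpPvalues = pv, provenance = sel$provenance[names(pv)],
      stageCounts = setNames(as.integer(counts), names(counts)))
}
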