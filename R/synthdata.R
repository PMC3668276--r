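#' Simulate LD-block genotype dosages
#'
#' Generates hard-call dosages in \{0, 1, 2\} under Hardy--Weinberg
#' proportions with a haplotype-copying LD scheme: each SNP's target minor
#' allele frequency is drawn from `mafRange`; within an LD block, each of a
#' sample's two haplotype alleles at SNP j copies the sample's allele at
#' SNP j-1 with probability `ldR` and is otherwise drawn fresh at the target
#' MAF. Adjacent SNPs within a block therefore have dosage correlation close
#' to `ldR` (exactly `ldR` when MAFs match); blocks are independent.
#' Monomorphic draws are redrawn so every SNP is polymorphic.
#'
#' @param scenario a [TriangleScenario-class]. Uses `nSamples`, `nSnps`,
#'   `mafRange`, `ldBlockSize`, `ldR`; the caller controls the RNG state.
#' @return A [DosageMatrix-class] (samples `S1..`, SNPs `snp1..`).
#' @export
simulateGenotypes <- function(scenario) {
  n <- scenario@nSamples
  p <- scenario@nSnps
  bs <- scenario@ldBlockSize
  maf <- runif(p, scenario@mafRange[1], scenario@mafRange[2])
  hap1 <- matrix(0L, n, p)
  hap2 <- matrix(0L, n, p)
  blockStart <- ((seq_len(p) - 1L) %% bs) == 0L
  for (j in seq_len(p)) {
    fresh1 <- rbinom(n, 1L, maf[j])
    fresh2 <- rbinom(n, 1L, maf[j])
    if (blockStart[j] || scenario@ldR == 0) {
      hap1[, j] <- fresh1
      hap2[, j] <- fresh2
    } else {
      copy1 <- rbinom(n, 1L, scenario@ldR) == 1L
      copy2 <- rbinom(n, 1L, scenario@ldR) == 1L
      hap1[, j] <- ifelse(copy1, hap1[, j - 1L], fresh1)
      hap2[, j] <- ifelse(copy2, hap2[, j - 1L], fresh2)
    }
  }
  d <- hap1 + hap2
  # redraw monomorphic SNPs (possible at small n): regression needs variance
  for (j in which(apply(d, 2L, function(x) length(unique(x))) == 1L)) {
    repeat {
      d[, j] <- rbinom(n, 1L, maf[j]) + rbinom(n, 1L, maf[j])
      if (length(unique(d[, j])) > 1L) break
    }
  }
  dimnames(d) <- list(paste0("S", seq_len(n)), paste0("snp", seq_len(p)))
  DosageMatrix(d)
}

#' Simulate factor-correlated expression with planted eQTLs
#'
#' Expression of gene g is
#' `beta * dosage[, snp(g)] * I(g planted) + loadings_g %*% factors + noise`,
#' where shared latent factors induce the gene-gene correlation structure the
#' permutation scheme must preserve. By default each gene loads on one random
#' factor with loading drawn uniformly in [0.3, 0.7] and unit total
#' background variance (noise sd `sqrt(1 - loading^2)`). A fraction
#' `eqtlFraction` of genes receives a planted eQTL on a distinct random SNP
#' with slope `eqtlEffect`.
#'
#' @param dosages a [DosageMatrix-class].
#' @param scenario a [TriangleScenario-class].
#' @param loadings optional nGenes x nFactors loading matrix overriding the
#'   default one-factor-per-gene loadings (rows may exceed unit norm; noise
#'   sd is then floored at 0.05).
#' @return list with `expression` (an [ExpressionMatrix-class]) and
#'   `trueEqtlPairs` (data.frame `snp_id`, `gene_id` of planted effects).
#' @export
simulateExpression <- function(dosages, scenario, loadings = NULL) {
  n <- nrow(dosages)
  ng <- scenario@nGenes
  k <- scenario@nFactors
  if (is.null(loadings)) {
    loadings <- matrix(0, ng, k)
    fac <- sample.int(k, ng, replace = TRUE)
    lam <- runif(ng, 0.3, 0.7)
    loadings[cbind(seq_len(ng), fac)] <- lam
  }
  noiseSd <- sqrt(pmax(1 - rowSums(loadings^2), 0.05^2))
  f <- matrix(rnorm(n * k), n, k)
  e <- f %*% t(loadings) + sweep(matrix(rnorm(n * ng), n, ng), 2L, noiseSd, `*`)

  nEqtl <- round(scenario@eqtlFraction * ng)
  pairs <- data.frame(snp_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  if (nEqtl > 0L) {
    genes <- sample.int(ng, nEqtl)
    snps <- sample.int(ncol(dosages), min(nEqtl, ncol(dosages)))
    genes <- genes[seq_along(snps)]
    for (i in seq_along(genes)) {
      dos <- dosages@.Data[, snps[i]]
      e[, genes[i]] <- e[, genes[i]] + scenario@eqtlEffect * (dos - mean(dos))
    }
    pairs <- data.frame(snp_id = colnames(dosages)[snps],
                        gene_id = paste0("gene", genes),
                        stringsAsFactors = FALSE)
  }
  dimnames(e) <- list(rownames(dosages), paste0("gene", seq_len(ng)))
  list(expression = ExpressionMatrix(e), trueEqtlPairs = pairs)
}

#' Simulate an expression-mediated phenotype
#'
#' `y = sum_g gamma_g * expression_g + noise` over `nCausalGenes` randomly
#' chosen causal genes, with equal-magnitude random-sign effects
#' (`gamma_g = +/-1`) so every causal gene contributes comparably, and the
#' noise scaled against the realized signal so the causal genes explain
#' `phenotypeR2` of the phenotype variance. `phenotypeR2 = 0` yields a
#' standard-normal phenotype independent of everything (the pure-null
#' scenario).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param scenario a [TriangleScenario-class].
#' @return list with `phenotype` (a [PhenotypeVector-class]) and
#'   `causalGenes` (character vector; empty in the pure-null scenario).
#' @export
simulatePhenotype <- function(expr, scenario) {
  n <- nrow(expr)
  if (scenario@phenotypeR2 == 0 || scenario@nCausalGenes == 0L) {
    y <- setNames(rnorm(n), rownames(expr))
    return(list(phenotype = PhenotypeVector(y), causalGenes = character(0)))
  }
  causal <- sort(sample(colnames(expr), scenario@nCausalGenes))
  gamma <- sample(c(-1, 1), length(causal), replace = TRUE)
  signal <- as.vector(expr@.Data[, causal, drop = FALSE] %*% gamma)
  r2 <- scenario@phenotypeR2
  noiseSd <- sd(signal) * sqrt((1 - r2) / r2)
  y <- setNames(signal + rnorm(n, sd = noiseSd), rownames(expr))
  list(phenotype = PhenotypeVector(y), causalGenes = causal)
}

#' Generate a complete synthetic study with truth labels
#'
#' Runs the three generators under `scenario@seed` and assembles the truth
#' labels: the planted (snp, gene) pairs, the causal genes, and the signal
#' SNPs (eQTLs of causal genes -- the SNPs the triangle method should
#' recover). Because genotype reaches the phenotype only through planted
#' eQTLs of causal genes, the SNPs with truly nonzero phenotype association
#' are the signal SNPs and their LD block-mates; the latter are reported as
#' `linkedSnps` (a superset of `signalSnps`) so that realized false
#' discovery proportions can be computed against genuinely null SNPs rather
#' than against tagging variants.
#'
#' @param scenario a [TriangleScenario-class].
#' @return list with `dosages`, `expression`, `phenotype`, and `truth` (a
#'   list with `trueEqtlPairs`, `causalGenes`, `signalSnps`, `linkedSnps`).
#' @examples
#' d <- simulateTriangleData(TriangleScenario(nSamples = 50, nSnps = 40,
#'                                            nGenes = 20, seed = 3))
#' d$truth$signalSnps
#' @export
simulateTriangleData <- function(scenario) {
  set.seed(scenario@seed)
  dosages <- simulateGenotypes(scenario)
  ex <- simulateExpression(dosages, scenario)
  ph <- simulatePhenotype(ex$expression, scenario)
  pairs <- ex$trueEqtlPairs
  signal <- sort(unique(pairs$snp_id[pairs$gene_id %in% ph$causalGenes]))
  allSnps <- colnames(dosages)
  block <- (seq_along(allSnps) - 1L) %/% scenario@ldBlockSize
  linked <- sort(allSnps[block %in% block[match(signal, allSnps)]])
  list(dosages = dosages, expression = ex$expression,
       phenotype = ph$phenotype,
       truth = list(trueEqtlPairs = pairs, causalGenes = ph$causalGenes,
                    signalSnps = signal, linkedSnps = linked))
}

#' Write a synthetic study (and truth labels) to disk
#'
#' Writes the four method inputs in the package's tab-delimited dialects
#' plus a `truth.tsv` labelling planted eQTL pairs and causal genes.
#'
#' @param data list as returned by [simulateTriangleData()].
#' @param dir output directory (created if needed).
#' @param eqtlMap optional [EqtlMap-class] to write alongside.
#' @return The directory path, invisibly.
#' @export
writeTriangleData <- function(data, dir, eqtlMap = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDosageMatrix(data$dosages, file.path(dir, "genotype.tsv"))
  writeExpressionMatrix(data$expression, file.path(dir, "expression.tsv"))
  writePhenotype(data$phenotype, file.path(dir, "phenotype.tsv"))
  if (!is.null(eqtlMap))
    writeEqtlMap(eqtlMap, file.path(dir, "eqtl_map.tsv"))
  tr <- data$truth
  lab <- function(kind, id1, id2 = character(length(id1)))
    data.frame(kind = rep(kind, length(id1)), id1 = id1, id2 = id2,
               stringsAsFactors = FALSE)
  truth <- rbind(lab("eqtl_pair", tr$trueEqtlPairs$snp_id,
                     tr$trueEqtlPairs$gene_id),
                 lab("causal_gene", tr$causalGenes),
                 lab("signal_snp", tr$signalSnps),
                 lab("linked_snp", tr$linkedSnps))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
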