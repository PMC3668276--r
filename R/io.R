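.stopMalformed <- function(path, what) {
  stop(sprintf("malformed input in '%s': %s", path, what))
}

.numericCells <- function(df, path) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) {
      v[v %in% c("NA", "", ".")] <- NA
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        .stopMalformed(path, sprintf("non-numeric cell at row %d, column %d ('%s')",
                                     bad[1], j + 1L, v[bad[1]]))
      df[[j]] <- vn
    }
  }
  df
}

#' Read a genotype dosage matrix
#'
#' Accepts either the tab-delimited dialect (first column `snp_id`, remaining
#' columns sample ids, cells dosages; `NA`, `.` or empty cells are missing)
#' or a VCF, from which the dosage is the ALT-allele count of the GT field
#' (phased or unphased; `./.` is missing). Missing entries are resolved by
#' the imputation policy; SNPs that are monomorphic or below the MAF floor
#' are dropped.
#'
#' @param path file path (`.vcf` or `.vcf.gz` triggers VCF parsing, which
#'   requires the vcfR package).
#' @param impute missing-genotype policy: `"mean"` replaces a missing cell by
#'   the SNP's mean non-missing dosage; `"drop"` drops any sample with a
#'   missing call.
#' @param mafMin minor-allele-frequency floor; SNPs with MAF < mafMin (or
#'   zero variance) are excluded.
#' @return A [DosageMatrix-class] (samples x SNPs).
#' @export
readDosageMatrix <- function(path, impute = c("mean", "drop"), mafMin = 0.05) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    m <- .readVcfDosages(path)
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (names(tab)[1] != "snp_id")
      .stopMalformed(path, "first column must be 'snp_id'")
    ids <- tab[[1]]
    tab <- .numericCells(tab[-1], path)
    m <- t(as.matrix(tab))
    colnames(m) <- ids
  }
  m <- .imputeDosages(m, impute, path)
  m <- .filterMaf(m, mafMin)
  DosageMatrix(m)
}

.readVcfDosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("var", seq_len(nrow(gt)))
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  })
  m <- t(dos)
  colnames(m) <- ids
  m
}

.imputeDosages <- function(m, impute, path) {
  if (!anyNA(m)) return(m)
  if (impute == "drop") {
    keep <- rowSums(is.na(m)) == 0L
    if (!any(keep)) .stopMalformed(path, "every sample has a missing genotype")
    m <- m[keep, , drop = FALSE]
  } else {
    for (j in which(colSums(is.na(m)) > 0L)) {
      v <- m[, j]
      if (all(is.na(v))) .stopMalformed(path, sprintf("SNP column %d all missing", j))
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      m[, j] <- v
    }
  }
  m
}

.filterMaf <- function(m, mafMin) {
  af <- colMeans(m) / 2
  maf <- pmin(af, 1 - af)
  variance <- apply(m, 2L, var)
  m[, maf >= mafMin & variance > 0, drop = FALSE]
}

#' Read an expression matrix
#'
#' Tab-delimited: first column `gene_id`, remaining columns sample ids.
#'
#' @param path file path.
#' @return An [ExpressionMatrix-class] (samples x genes).
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (names(tab)[1] != "gene_id")
    .stopMalformed(path, "first column must be 'gene_id'")
  ids <- tab[[1]]
  tab <- .numericCells(tab[-1], path)
  m <- t(as.matrix(tab))
  colnames(m) <- ids
  if (anyNA(m)) .stopMalformed(path, "missing expression values")
  ExpressionMatrix(m)
}

#' Read a phenotype table
#'
#' Tab-delimited: columns `sample_id`, `phenotype`, then zero or more
#' covariate columns.
#'
#' @param path file path.
#' @return A [PhenotypeVector-class].
#' @export
readPhenotype <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(tab)[1:2]))
    .stopMalformed(path, "first columns must be 'sample_id', 'phenotype'")
  y <- setNames(as.numeric(tab$phenotype), tab$sample_id)
  covNames <- setdiff(names(tab), c("sample_id", "phenotype"))
  cv <- NULL
  if (length(covNames)) {
    cv <- as.matrix(.numericCells(tab[covNames], path))
    rownames(cv) <- tab$sample_id
  }
  PhenotypeVector(y, cv)
}

#' Read a SCAN-style eQTL map export
#'
#' Tab-delimited: columns `snp_id`, `gene_id`, `pvalue`.
#'
#' @param path file path.
#' @return An [EqtlMap-class].
#' @export
readEqtlMap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene_id", "pvalue") %in% names(tab)))
    .stopMalformed(path, "columns must be snp_id, gene_id, pvalue")
  EqtlMap(tab[c("snp_id", "gene_id", "pvalue")])
}

#' Load and align a complete dataset
#'
#' Reads the four inputs and restricts the three sample-indexed objects to
#' the intersection of their sample ids, all reordered to the phenotype
#' file's order (the canonical one). Intersection size and per-input drop
#' counts are reported via `message()`.
#'
#' @param genotypePath,expressionPath,phenotypePath,eqtlPath input files in
#'   the dialects of the individual readers.
#' @param impute,mafMin genotype loading policy, see [readDosageMatrix()].
#' @return list with `dosages`, `expression`, `phenotype`, `eqtlMap`, sample
#'   ids aligned across the first three.
#' @export
loadTriangleData <- function(genotypePath, expressionPath, phenotypePath,
                             eqtlPath, impute = "mean", mafMin = 0.05) {
  dosages <- readDosageMatrix(genotypePath, impute, mafMin)
  expr <- readExpressionMatrix(expressionPath)
  pheno <- readPhenotype(phenotypePath)
  eqtl <- readEqtlMap(eqtlPath)
  shared <- intersect(sampleIds(pheno),
                      intersect(sampleIds(dosages), sampleIds(expr)))
  if (!length(shared))
    stop(sprintf("no shared samples among '%s', '%s' and '%s'",
                 genotypePath, expressionPath, phenotypePath))
  message(sprintf(
    "aligned %d shared samples (dropped: genotype %d, expression %d, phenotype %d)",
    length(shared), nrow(dosages) - length(shared),
    nrow(expr) - length(shared), length(phenotype(pheno)) - length(shared)))
  cv <- covariates(pheno)
  list(dosages = DosageMatrix(dosages@.Data[shared, , drop = FALSE]),
       expression = ExpressionMatrix(expr@.Data[shared, , drop = FALSE]),
       phenotype = PhenotypeVector(phenotype(pheno)[shared],
                                   if (ncol(cv)) cv[shared, , drop = FALSE]),
       eqtlMap = eqtl)
}

#' Write sample-indexed objects in their tab-delimited dialects
#'
#' Inverse operations of the corresponding readers: write-then-read is the
#' identity (up to MAF filtering at genotype load time).
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDosageMatrix <- function(x, path) {
  .writeFeatureTable(t(x@.Data), "snp_id", path)
}

#' @rdname writeDosageMatrix
#' @export
writeExpressionMatrix <- function(x, path) {
  .writeFeatureTable(t(x@.Data), "gene_id", path)
}

.writeFeatureTable <- function(m, idCol, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- idCol
  write.table(.fullPrecision(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

.fullPrecision <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE)
  df
}

#' @rdname writeDosageMatrix
#' @export
writePhenotype <- function(x, path) {
  df <- data.frame(sample_id = sampleIds(x), phenotype = phenotype(x),
                   stringsAsFactors = FALSE)
  cv <- covariates(x)
  if (ncol(cv)) df <- cbind(df, as.data.frame(cv, check.names = FALSE))
  write.table(.fullPrecision(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeDosageMatrix
#' @export
writeEqtlMap <- function(x, path) {
  write.table(.fullPrecision(eqtlRecords(x)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read an FdrTable
#'
#' Tab-delimited with columns `snp_id`, `genes`, `p_obs`, `naive_q`, `efdr`,
#' `q_efdr`, preceded by `#`-prefixed header comments recording lambda, pi0,
#' m, M0, the conservative flag and any metadata (thresholds, permutations,
#' seed). Numeric fields are written at full precision; write-then-read is
#' the identity on the table.
#'
#' @param x an [FdrTable-class].
#' @param path file path.
#' @return `writeFdrTable` returns `path` invisibly; `readFdrTable` an
#'   [FdrTable-class].
#' @export
writeFdrTable <- function(x, path) {
  meta <- c(list(lambda = x@lambda, pi0 = x@pi0, m = x@m, M0 = x@M0,
                 conservative = x@conservative), x@metadata)
  hdr <- sprintf("# %s=%s", names(meta),
                 vapply(meta, function(v) paste(format(v, digits = 17),
                                                collapse = ","), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(x@table), collapse = "\t"), con)
  if (nrow(x@table))
    write.table(.fullPrecision(x@table), con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeFdrTable
#' @export
readFdrTable <- function(path) {
  lines <- readLines(path)
  meta <- .parseHeaderMeta(lines[startsWith(lines, "#")])
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$snp_id <- as.character(tab$snp_id)
  tab$genes <- as.character(tab$genes)
  if (!nrow(tab))
    tab <- data.frame(snp_id = character(0), genes = character(0),
                      p_obs = numeric(0), naive_q = numeric(0),
                      efdr = numeric(0), q_efdr = numeric(0),
                      stringsAsFactors = FALSE)
  tab$genes[is.na(tab$genes)] <- ""
  num <- function(k, d) if (!is.null(meta[[k]])) as.numeric(meta[[k]]) else d
  extra <- meta[setdiff(names(meta), c("lambda", "pi0", "m", "M0", "conservative"))]
  new("FdrTable", table = tab, lambda = num("lambda", 0.5),
      pi0 = num("pi0", 1), m = as.integer(num("m", nrow(tab))),
      M0 = as.integer(num("M0", 0)),
      conservative = identical(meta[["conservative"]], "TRUE"),
      metadata = extra)
}
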