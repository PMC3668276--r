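#' Permute a phenotype (covariates relabelled in sync)
#'
#' Draws one uniformly random permutation of sample positions and applies it
#' to the trait values and to the covariate rows *together*, relative to the
#' fixed genotype/expression sample order. Sample ids keep their positions
#' (they index the fixed ordering of the genetic machinery); the multiset of
#' trait values is unchanged, and (y, covariate) pairs never decouple.
#'
#' @param pheno a [PhenotypeVector-class].
#' @param perm optional explicit permutation of `seq_along(phenotype(pheno))`
#'   (a test hook; e.g. the identity); drawn at random when `NULL`.
#' @return A [PhenotypeVector-class] with permuted rows.
#' @export
permutePhenotype <- function(pheno, perm = NULL) {
  y <- phenotype(pheno)
  n <- length(y)
  if (n == 0L) stop("phenotype is empty")
  if (is.null(perm)) perm <- sample.int(n)
  if (!identical(sort(perm), seq_len(n))) stop("not a permutation")
  ids <- names(y)
  ynew <- setNames(unname(y)[perm], ids)
  cv <- covariates(pheno)
  if (ncol(cv) > 0L) {
    cv <- cv[perm, , drop = FALSE]
    rownames(cv) <- ids
  } else {
    cv <- matrix(numeric(0), nrow = n, ncol = 0, dimnames = list(ids, NULL))
  }
  new("PhenotypeVector", y = ynew, covariates = cv)
}

#' Build the empirical null pool by phenotype permutation
#'
#' For each of `n` replicates, permutes the phenotype (covariates in sync)
#' and re-runs [runTriangle()] with the *same* eQTL map and the *same*
#' thresholds as the observed analysis, pooling the resulting SNP p-values.
#' Only the phenotype is ever permuted: the genotype-expression relationships
#' (the genetic machinery) and the correlation structure among genes and
#' among SNPs are preserved exactly, and the eQTL map is never recomputed.
#' Replicates with an empty selection contribute m_0s = 0 and no p-values.
#'
#' Each replicate runs on its own seed substream derived from `seed`, so the
#' pool is reproducible and independent of replicate execution order.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param pheno a [PhenotypeVector-class] (the observed phenotype).
#' @param dosages a [DosageMatrix-class].
#' @param eqtlMap the fixed [EqtlMap-class] used for the observed analysis.
#' @param thresholds the [TriangleThresholds-class] used for the observed
#'   analysis.
#' @param n number of permutation replicates (1000 is typical; desk-scale
#'   studies use a few hundred).
#' @param seed integer master seed.
#' @return A [NullPool-class] with pooled p-values, per-replicate counts
#'   m_0s, and M0 = sum(m_0s).
#' @export
buildNullPool <- function(expr, pheno, dosages, eqtlMap, thresholds,
                          n = 1000, seed = 1) {
  n <- as.integer(n)
  if (n < 1L) stop("need at least one permutation replicate")
  set.seed(as.integer(seed))
  repSeeds <- sample.int(.Machine$integer.max - 1L, n)
  pools <- vector("list", n)
  counts <- integer(n)
  for (s in seq_len(n)) {
    set.seed(repSeeds[s])
    permed <- permutePhenotype(pheno)
    res <- suppressWarnings(
      runTriangle(expr, permed, dosages, eqtlMap, thresholds))
    pv <- unname(snpPvalues(res))
    pools[[s]] <- pv
    counts[s] <- length(pv)
  }
  new("NullPool", pooledPvalues = unlist(pools, use.names = FALSE),
      perReplicateCounts = counts, n = n, seed = as.integer(seed))
}

#' Write / read a null pool as a two-column table
#'
#' The pool is persisted as tab-delimited `replicate`, `pvalue` rows (one per
#' pooled p-value; empty replicates appear only through the recorded `n`),
#' with header comments recording `n` and the seed, so eFDR estimation can be
#' run separately from the permutation step.
#'
#' @param pool a [NullPool-class].
#' @param path output file path.
#' @return `writeNullPool` returns `path` invisibly; `readNullPool` returns a
#'   [NullPool-class].
#' @export
writeNullPool <- function(pool, path) {
  rep_id <- rep.int(seq_len(pool@n), perReplicateCounts(pool))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_permutations=%d", pool@n),
               sprintf("# seed=%d", pool@seed),
               "replicate\tpvalue"), con)
  if (length(pooledPvalues(pool)))
    write.table(data.frame(replicate = rep_id,
                           pvalue = format(pooledPvalues(pool), digits = 17)),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeNullPool
#' @export
readNullPool <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- .parseHeaderMeta(hdr)
  n <- as.integer(meta[["n_permutations"]])
  seed <- as.integer(meta[["seed"]])
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  counts <- integer(n)
  if (nrow(tab)) {
    tb <- table(factor(tab$replicate, levels = seq_len(n)))
    counts <- as.integer(tb)
  }
  new("NullPool", pooledPvalues = as.numeric(tab$pvalue),
      perReplicateCounts = counts, n = n, seed = seed)
}

.parseHeaderMeta <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(as.list(vals), keys)
}
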