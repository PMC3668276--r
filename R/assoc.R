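#' Vectorized mass simple linear regression
#'
#' Fits, for every column of `X` at once, the simple linear regression of `y`
#' on that column and returns the slope and the two-sided t-test p-value of
#' the slope. With covariates, `y` and every predictor column are first
#' residualized on the covariates plus an intercept; the slope test on the
#' residualized variables is then identical to the slope test in the full
#' multiple regression (Frisch--Waugh), carried out with n - 2 - c degrees of
#' freedom. This is the workhorse for all three arms of the triangle: at
#' genome scale it replaces tens of thousands of `lm()` calls with a handful
#' of matrix operations.
#'
#' @param X numeric matrix, samples x features (dimnames optional; feature
#'   names are carried into the result).
#' @param y numeric response vector, length nrow(X).
#' @param covariates optional numeric matrix (samples x c).
#' @return A data.frame with columns `feature_id`, `beta`, `pvalue`. Constant
#'   (or covariate-collinear) predictor columns get beta 0 and p-value 1 with
#'   a warning rather than an error, so permutation loops survive degenerate
#'   replicates.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 20), 50, 20, dimnames = list(NULL, paste0("f", 1:20)))
#' y <- 0.5 * X[, 1] + rnorm(50)
#' head(massRegression(X, y))
#' @export
massRegression <- function(X, y, covariates = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  nc <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < 3L + nc) stop(sprintf("need at least %d samples, got %d", 3L + nc, n))

  if (nc > 0L) {
    Z <- cbind(`(Intercept)` = 1, as.matrix(covariates))
    qz <- qr(Z)
    yr <- qr.resid(qz, y)
    Xr <- qr.resid(qz, X)
  } else {
    yr <- y - mean(y)
    Xr <- sweep(X, 2L, colMeans(X), `-`)
  }

  df <- n - 2L - nc
  sxx <- colSums(Xr^2)
  syy <- sum(yr^2)
  # constant / covariate-collinear predictors have (numerically) zero
  # residual variance; flag and report p = 1
  tolv <- max(sxx, 1) * .Machine$double.eps * n
  degen <- sxx <= tolv
  sxx[degen] <- 1  # placeholder, overwritten below
  beta <- as.vector(crossprod(Xr, yr)) / sxx
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tt <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  tt[beta == 0 & se == 0] <- 0
  pv <- 2 * pt(-abs(tt), df = df)
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  if (any(degen)) {
    beta[degen] <- 0
    pv[degen] <- 1
    warning(sprintf("%d constant predictor column(s) assigned p = 1",
                    sum(degen)))
  }
  ids <- colnames(X)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(X)))
  data.frame(feature_id = ids, beta = beta, pvalue = pv,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build an eQTL map from genotype and expression data
#'
#' Regresses every gene's expression on every SNP's dosage (no covariates)
#' and records the (SNP, gene) pairs whose two-sided p-value falls strictly
#' below `pSnpGene`. This is the stand-in for a precomputed eQTL database
#' export when none is supplied; it is computed once per dataset, depends
#' only on genotype and expression, and is reused unchanged across all
#' phenotype permutations.
#'
#' Implemented through per-pair Pearson correlations: for simple regression
#' the slope t-statistic equals r * sqrt((n - 2) / (1 - r^2)), so the full
#' SNPs x genes p-value grid is two matrix products.
#'
#' @param dosages a [DosageMatrix-class].
#' @param expr an [ExpressionMatrix-class], samples aligned with `dosages`.
#' @param pSnpGene p-value cutoff in [0, 1] (strict `<`).
#' @return An [EqtlMap-class] of all pairs passing the cutoff.
#' @export
computeEqtlMap <- function(dosages, expr, pSnpGene = 1e-4) {
  if (pSnpGene < 0 || pSnpGene > 1) stop("pSnpGene must lie in [0, 1]")
  if (!identical(rownames(dosages), rownames(expr)))
    stop("dosage and expression samples are not aligned")
  n <- nrow(dosages)
  if (n < 3L) stop("need at least 3 samples")
  r <- suppressWarnings(cor(dosages@.Data, expr@.Data))
  r[!is.finite(r)] <- 0  # zero-variance guard
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * pt(-abs(tt), df = n - 2)
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  hit <- which(pv < pSnpGene, arr.ind = TRUE)
  EqtlMap(data.frame(
    snp_id = colnames(dosages)[hit[, 1L]],
    gene_id = colnames(expr)[hit[, 2L]],
    pvalue = pv[hit],
    stringsAsFactors = FALSE))
}
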