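#' Estimate pi0, the proportion of null SNPs, from the empirical null
#'
#' pi0 is estimated from the tails of the two distributions:
#' \deqn{\hat\pi_0 = \frac{\#\{p_{obs} > \lambda\}/m}{\#\{p_{sim} > \lambda\}/M_0}}
#' i.e. the observed tail mass above `lambda` relative to the *empirical*
#' null tail mass (not the uniform tail `1 - lambda`), then clamped to
#' (0, 1]. When either tail is empty (no simulated, or no observed, p-value
#' above `lambda`) the ratio is uninformative and the conservative value 1
#' is returned with a warning: at the small m typical of the triangle filter
#' an empty observed tail is common and any small positive stand-in would
#' deflate every FDR estimate downstream.
#'
#' @param obsP observed p-values (size m >= 1).
#' @param simP pooled null p-values (size M0 >= 1).
#' @param lambda tail cutoff in (0, 1); 0.5 by default.
#' @return The pi0 estimate in (0, 1].
#' @examples
#' pi0Hat(c(0.01, 0.2, 0.6, 0.9), c(0.05, 0.3, 0.55, 0.7, 0.95))  # 5/6
#' @export
pi0Hat <- function(obsP, simP, lambda = 0.5) {
  if (!length(obsP) || !length(simP)) stop("empty p-value pool")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  m <- length(obsP)
  simTail <- sum(simP > lambda)
  if (simTail == 0L) {
    warning("no simulated p-value above lambda; pi0 set to 1")
    return(1)
  }
  val <- (sum(obsP > lambda) / m) / (simTail / length(simP))
  if (val <= 0) {
    warning("no observed p-value above lambda; pi0 set to 1 (conservative)")
    return(1)
  }
  min(val, 1)
}

#' Empirical FDR at a single significance cutoff
#'
#' Estimates the FDR of rejecting all observed p-values at or below `t`
#' against the permutation null:
#' \deqn{eFDR(t) = \frac{\#\{p_{sim} \le t\}/M_0}{\#\{p_{obs} \le t\}/m}
#'   \cdot \hat\pi_0}
#' capped at 1. Counting is inclusive (\eqn{\le t}); in practice `t` is
#' always one of the observed p-values, so the denominator is positive.
#'
#' @param t significance cutoff in [0, 1].
#' @param obsP observed p-values.
#' @param simP pooled null p-values.
#' @param pi0 the pi0 factor (set 1 for the conservative bound).
#' @return eFDR(t) in [0, 1]; 0 when no simulated p-value reaches `t`.
#' @export
empiricalFdrAt <- function(t, obsP, simP, pi0 = 1) {
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  if (!length(obsP) || !length(simP)) stop("empty p-value pool")
  nObs <- sum(obsP <= t)
  if (nObs == 0L)
    stop("eFDR undefined where no observed p-value is <= t")
  nSim <- sum(simP <= t)
  if (nSim == 0L) return(0)
  min((nSim / length(simP)) / (nObs / length(obsP)) * pi0, 1)
}

.monotoneQ <- function(p, fdr) {
  # q(t) = min over observed p >= t of FDR(p); assumes p sorted ascending
  rev(cummin(rev(fdr)))
}

#' Naive Storey q-values under the uniform-null assumption
#'
#' The comparator whose failure motivates the empirical approach: assumes
#' the null p-values are uniform, so FDR(t) = pi0 * m * t / #\{p <= t\},
#' evaluated at each observed p-value, capped at 1 and monotonized by
#' q(t) = min over observed p >= t of FDR(p). For SNPs selected through
#' the correlated triangle filter this is anti-conservative.
#'
#' @param obsP observed p-values (any order).
#' @param pi0 proportion of nulls; 1 by default.
#' @return Numeric q-values in the *input* order of `obsP`.
#' @examples
#' storeyNaiveQvalues(c(0.01, 0.2, 0.6, 0.9))  # 0.04 0.40 0.80 0.90
#' @export
storeyNaiveQvalues <- function(obsP, pi0 = 1) {
  m <- length(obsP)
  if (!m) stop("empty p-value pool")
  ord <- order(obsP)
  ps <- obsP[ord]
  fdr <- pmin(pi0 * m * ps / vapply(ps, function(t) sum(ps <= t), 0L), 1)
  q <- .monotoneQ(ps, fdr)
  q[order(ord)]
}

#' Empirical FDR q-values for a prioritized SNP set
#'
#' Evaluates the empirical FDR at every observed p-value (tied p-values
#' share one cutoff, hence one eFDR and one q) and monotonizes:
#' \deqn{\hat q(t) = \min_{p \ge t} eFDR(p)} over the observed p-values.
#' pi0 is estimated once from the full pools via [pi0Hat()] unless
#' `conservative = TRUE`, which fixes pi0 = 1 (an upper bound on the FDR).
#' The naive uniform-null Storey q-value is computed alongside for
#' comparison.
#'
#' @param obs a [TriangleResult-class], or a named numeric vector of observed
#'   p-values.
#' @param pool a [NullPool-class], or a numeric vector of pooled null
#'   p-values (then taken as a single-replicate pool).
#' @param lambda tail cutoff for pi0 estimation.
#' @param conservative logical; fix pi0 = 1.
#' @param metadata optional list of run provenance stored in the result.
#' @return An [FdrTable-class], rows sorted by `p_obs`. When the null pool is
#'   empty (M0 = 0: no permutation ever selected a SNP) every eFDR is set to
#'   0 and a prominent warning marks the null as degenerate.
#' @examples
#' obs <- c(rs1 = 0.01, rs2 = 0.2, rs3 = 0.6, rs4 = 0.9)
#' sim <- c(0.05, 0.3, 0.55, 0.7, 0.95)
#' fdrTable(efdrQvalues(obs, sim))
#' @export
efdrQvalues <- function(obs, pool, lambda = 0.5, conservative = FALSE,
                        metadata = list()) {
  prov <- list()
  if (is(obs, "TriangleResult")) {
    prov <- provenance(obs)
    obs <- snpPvalues(obs)
  }
  if (is(pool, "NullPool")) {
    M0 <- nullSize(pool)
    simP <- pooledPvalues(pool)
  } else {
    simP <- as.numeric(pool)
    M0 <- length(simP)
  }
  m <- length(obs)
  if (!m) {
    return(new("FdrTable",
               table = data.frame(snp_id = character(0), genes = character(0),
                                  p_obs = numeric(0), naive_q = numeric(0),
                                  efdr = numeric(0), q_efdr = numeric(0),
                                  stringsAsFactors = FALSE),
               lambda = lambda, pi0 = 1, m = 0L, M0 = as.integer(M0),
               conservative = conservative, metadata = metadata))
  }
  ids <- names(obs)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  ord <- order(obs)
  ps <- unname(obs)[ord]
  ids <- ids[ord]

  if (M0 == 0L) {
    warning("DEGENERATE NULL: no permutation replicate ever selected a SNP ",
            "(M0 = 0); all eFDR values set to 0 and should not be trusted")
    pi0 <- 1
    efdr <- rep(0, m)
  } else {
    pi0 <- if (conservative) 1 else pi0Hat(ps, simP, lambda)
    efdr <- vapply(ps, empiricalFdrAt, 0, obsP = ps, simP = simP, pi0 = pi0)
  }
  # tied observed p-values share one cutoff t, hence one eFDR
  q <- .monotoneQ(ps, efdr)
  naive <- storeyNaiveQvalues(ps)
  genes <- vapply(ids, function(id) {
    g <- prov[[id]]
    if (is.null(g)) "" else paste(g, collapse = ",")
  }, "")
  new("FdrTable",
      table = data.frame(snp_id = ids, genes = unname(genes), p_obs = ps,
                         naive_q = naive, efdr = efdr, q_efdr = q,
                         stringsAsFactors = FALSE),
      lambda = lambda, pi0 = pi0, m = as.integer(m), M0 = as.integer(M0),
      conservative = conservative, metadata = metadata)
}

#' QQ-plot coordinates on the -log10 scale
#'
#' Expected quantile for rank i of m is i/(m + 1); observed p-values are
#' sorted ascending. Both axes are returned -log10-transformed, ready for
#' plotting or export.
#'
#' @param p p-values in (0, 1].
#' @return data.frame with columns `expected` and `observed` (-log10 scale),
#'   one row per p-value in ascending order of p.
#' @export
qqCoordinates <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(sort(p)))
}
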