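---
title: "Empirical FDR for eQTL-based integrative SNP prioritization"
author: "triangleFDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical FDR for eQTL-based integrative SNP prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triangleFDR)
```

## The model and its assumptions

The triangle method prioritizes SNPs for a quantitative phenotype $Y$
(e.g., log IC$_{50}$ of a cytotoxic drug measured on cell lines) by chaining
three association filters across datasets measured on the same samples:

1. **Gene–phenotype.** Regress each gene expression trait on $Y$
   (covariates adjusted) and keep genes with $p < p_{\text{gene-phenotype}}$.
2. **SNP–gene.** Keep SNPs that are eQTLs of at least `minGeneCount` of the
   selected genes at $p < p_{\text{SNP-gene}}$, either from a precomputed
   eQTL database export or computed once from the genotype and expression
   matrices. `minGeneCount > 1` implements the hub-eQTL (master-regulator)
   variant.
3. **SNP–phenotype.** Regress dosage on $Y$ for the surviving SNPs and keep
   $p < p_{\text{SNP-phenotype}}$ (default 1, i.e. no final filtering),
   yielding $m$ observed p-values $\{p_{\text{obs}}\}$.

All three cutoffs are applied with strict `<`; ties at a cutoff are
excluded. The cutoffs are prioritization devices, not significance claims —
the point of the package is to attach a valid overall significance measure
to the output *regardless* of the cutoffs chosen.

Because stage 2 conditions on genes that were selected for phenotype
association, and genes and SNPs are mutually correlated, the null
distribution of $\{p_{\text{obs}}\}$ is not uniform. The empirical FDR
therefore replaces the uniform-null assumption with a permutation null:
permute only the phenotype (covariate rows relabelled in sync), re-run the
*identical* filter $n$ times, and pool the resulting p-values
($M_0 = \sum_s m_{0,s}$). Permuting whole samples preserves the gene–gene
and SNP–SNP correlation structure exactly, and the eQTL map is never
recomputed — the genetic machinery is fixed; only its relation to $Y$ is
broken.

With $S(t) = \#\{p_{\text{obs}} \le t\}$ the estimators are

$$\widehat{\mathrm{eFDR}}(t) =
  \frac{\#\{p_{\text{sim}} \le t\}/M_0}{S(t)/m}\,\hat\pi_0,
  \qquad
  \hat\pi_0 = \frac{\#\{p_{\text{obs}} > \lambda\}/m}
                   {\#\{p_{\text{sim}} > \lambda\}/M_0},
  \qquad
  \hat q(t) = \min_{p \ge t} \widehat{\mathrm{eFDR}}(p),$$

evaluated at every observed p-value (the only cutoffs of practical
interest), with $\lambda = 0.5$. Counting is inclusive ($\le t$) in the FDR
ratio, while the filter thresholds are strict — both follow the method's
own conventions. Setting `conservative = TRUE` fixes $\hat\pi_0 = 1$, an
upper bound. Under confounding that inflates the number of
phenotype-associated genes, the permutation null acquires extra null eQTLs
as well, so the estimate errs conservative rather than anti-conservative.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `pGenePhenotype` | 0.05 | stage-1 gene–phenotype cutoff (p-value) |
| `pSnpGene` | 1e-4 | stage-2 eQTL cutoff (p-value) |
| `pSnpPhenotype` | 1 | stage-3 cutoff; default keeps every survivor, identically in observed and permuted runs (symmetry is required for validity) |
| `minGeneCount` | 1 | supporting selected genes per SNP; > 1 = hub-eQTL variant |
| `mafMin` | 0.05 | MAF floor at genotype load (monomorphic SNPs always dropped: the regression is undefined) |
| `n` (permutations) | 1000 | null replicates; desk-scale analyses in this package use 200 |
| `lambda` | 0.5 | $\hat\pi_0$ tail cutoff |

## Numerical choices and degenerate inputs

- **Mass regression.** Each arm is a vectorized simple linear regression;
  with covariates, response and predictors are residualized on the
  covariates plus intercept first (Frisch–Waugh), and the slope is tested
  with $n - 2 - c$ degrees of freedom — equivalent to the full multiple
  regression. Constant (or covariate-collinear) predictors get $p = 1$ with
  a warning instead of an error so permutation loops survive; too few
  samples ($n < 3 + c$) is fatal. P-values are floored at the smallest
  positive double, keeping them in $(0, 1]$.
- **$\hat\pi_0$ edge cases.** If no simulated — or no observed — p-value
  exceeds $\lambda$, the tail ratio is uninformative and $\hat\pi_0 = 1$ is
  used with a warning. At the small $m$ the filter typically leaves, an
  empty observed tail is common, and any small positive stand-in would
  deflate every downstream FDR estimate.
- **$M_0 = 0$.** If no permutation ever selects a SNP the null is
  degenerate; all eFDR values are set to 0 with a prominent warning rather
  than failing, since the condition is detectable and the practitioner must
  decide (usually: relax `pSnpGene` or inspect the eQTL map).
- **Ties.** Tied observed p-values share one cutoff $t$, hence one eFDR and
  one q-value. eFDR and q are capped at 1 (the raw ratio can exceed it, and
  an FDR above 1 is uninterpretable).
- **Seeding.** The null pool derives one sub-seed per replicate from the
  master seed up front, so results are independent of replicate execution
  order and bit-reproducible; the identity permutation is not excluded
  (excluding it would bias the null, and at $n$ in the hundreds its
  expected impact is negligible). Permutations are drawn with replacement
  from the permutation group.
- **Missing genotypes.** Mean-dosage imputation per SNP by default (keeps
  the design matrix dense); a pairwise-deletion alternative (`drop`) is
  available. These are engineering defaults; the method itself is agnostic.

## What the synthetic-data generator emulates

`TriangleScenario`/`simulateTriangleData` produce studies with the
structural features the method's validity depends on, at controllable
strength:

- **Genotypes**: Hardy–Weinberg dosages with per-SNP MAF drawn from
  `mafRange`, and LD through a haplotype-copying scheme — within a block,
  each haplotype allele copies the previous SNP's allele with probability
  `ldR`, giving adjacent-SNP dosage correlation $\approx$ `ldR` while
  guaranteeing valid dosages (a multivariate-normal threshold model would
  not).
- **Expression**: a low-rank factor model (each gene loads on one latent
  factor, loading $\sim U(0.3, 0.7)$, unit background variance) induces the
  gene–gene correlation the permutation must preserve; a fraction
  `eqtlFraction` of genes receives a planted eQTL of slope `eqtlEffect` on
  a distinct SNP.
- **Phenotype**: mediated through `nCausalGenes` randomly chosen genes with
  equal-magnitude, random-sign effects ($\gamma_g = \pm 1$, so each causal
  gene contributes comparably and "strong effects" is well defined per
  gene), noise scaled so the causal genes explain `phenotypeR2` of the
  variance; `phenotypeR2 = 0` is the pure-null scenario.
- **Truth labels**: the planted (SNP, gene) pairs, the causal genes, the
  *signal SNPs* (planted eQTLs of causal genes), and the *linked SNPs*
  (signal SNPs plus their LD block-mates). Genotype reaches the phenotype
  only through planted eQTLs of causal genes, so the linked SNPs are
  exactly the SNPs with truly nonzero marginal phenotype association;
  realized false discovery proportions are computed against that set —
  counting an LD tagging variant as a false discovery would mislabel a
  genuinely associated SNP.

The generator does **not** emulate realistic human LD maps, population
structure, cis-window geometry, batch effects, or non-normal expression
distributions. Passing calibration and power tests on these fixtures shows
the estimators behave as designed under the model's assumptions; it does
not certify performance on a particular real dataset.

## Problem sizes and design choices in the test suite

The package's calibration and power studies run at desk scale — 200
samples, 3000 SNPs in blocks of 10, 300 genes, 200 permutations, with 10–20
independent replicates per scenario — roughly a 30-fold reduction of a
full transcriptome study that preserves every structural feature. The three
standing scenarios are:

- *pure null* (`phenotypeR2 = 0`): the naive Storey q-value flags spurious
  SNPs in a nontrivial fraction of draws while eFDR discoveries stay near
  zero — the failure mode that motivates the method;
- *mixed* (`phenotypeR2 = 0.4`, 10 causal genes, `eqtlFraction = 0.3`):
  realized FDP among $\hat q \le 0.15$ calls averages near the nominal
  level;
- *strong signal* (`phenotypeR2 = 0.8`, 5 causal genes,
  `eqtlFraction = 1`, `eqtlEffect = 2.5`, MAF $\ge 0.2$): planted signal
  SNPs are recovered at $\hat q < 0.15$ and dominate the ranking.

Where a design was genuinely open we chose: q-value monotonization over
observed p-values only (they are the only evaluation points); one observed
p-value per SNP however many genes support it (the final arm tests the SNP
once; double-counting would inflate both pools); `pSnpPhenotype = 1`
applied identically to observed and permuted runs (symmetry by
construction); and an authoritative supplied eQTL map with
`computeEqtlMap()` as the stand-in when none is given.

## Known limitations

- Quantitative phenotypes only; binary outcomes would need a different
  association engine behind the same filter.
- One molecular layer (expression). The filter chain is an obvious
  extension point for protein or microRNA layers but only the single layer
  is implemented.
- $\hat\pi_0$ uses a single $\lambda$; no spline/smoothing across a
  $\lambda$ grid.
- The eFDR is a pointwise plug-in estimate; with small $m$ and small $M_0$
  it is noisy, and q-values near the boundary should be read with the pool
  sizes (reported in every `FdrTable`) in mind.
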