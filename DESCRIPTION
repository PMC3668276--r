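Package: triangleFDR
Title: Empirical False Discovery Rates for eQTL-Based Integrative SNP
    Prioritization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the integrative "triangle" approach to SNP
    prioritization (genes associated with a quantitative phenotype, SNPs
    that are eQTLs of those genes, the surviving SNPs tested against the
    phenotype) together with a permutation-based empirical false
    discovery rate. Because the triangle filter selects SNPs through
    correlated gene expression traits, the null distribution of the
    selected SNPs' association p-values is not uniform and the
    traditional Storey FDR is anti-conservative; the empirical FDR is
    estimated against a null p-value pool built by permuting only the
    phenotype (covariates relabelled in sync) and re-running the
    identical filter, so that the genetic machinery (genotype-expression
    relationships) is preserved. Includes vectorized mass simple linear
    regression, q-value computation with pi0 estimation, QQ-plot
    coordinates, and a synthetic-data generator (LD-block genotypes,
    factor-correlated expression with planted eQTLs, expression-mediated
    phenotypes) with truth labels for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), vcfR, withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
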