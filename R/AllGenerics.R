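#' @name accessors
#' @title Accessors for triangleFDR data objects
#'
#' @description
#' `sampleIds()` returns the ordered sample identifiers; `snpIds()` and
#' `geneIds()` the feature identifiers; `phenotype()` the trait vector and
#' `covariates()` the covariate matrix of a [PhenotypeVector-class];
#' `eqtlRecords()` the record data.frame of an [EqtlMap-class];
#' `snpPvalues()`, `selectedGenes()`, `provenance()` and `stageCounts()` the
#' components of a [TriangleResult-class]; `pooledPvalues()`,
#' `perReplicateCounts()` and `nullSize()` (M0) those of a
#' [NullPool-class]; `fdrTable()` and `pi0()` those of an [FdrTable-class].
#'
#' @param x an object of the documented class.
#' @return The component named by the accessor.
#' @examples
#' m <- matrix(0:1, 2, 1, dimnames = list(c("a", "b"), "rs1"))
#' sampleIds(DosageMatrix(m))
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("eqtlRecords", function(x) standardGeneric("eqtlRecords"))
#' @rdname accessors
#' @export
setGeneric("snpPvalues", function(x) standardGeneric("snpPvalues"))
#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))
#' @rdname accessors
#' @export
setGeneric("pooledPvalues", function(x) standardGeneric("pooledPvalues"))
#' @rdname accessors
#' @export
setGeneric("perReplicateCounts", function(x) standardGeneric("perReplicateCounts"))
#' @rdname accessors
#' @export
setGeneric("nullSize", function(x) standardGeneric("nullSize"))
#' @rdname accessors
#' @export
setGeneric("fdrTable", function(x) standardGeneric("fdrTable"))
#' @rdname accessors
#' @export
setGeneric("pi0", function(x) standardGeneric("pi0"))
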