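#' Accessors for coverage-QC result objects
#'
#' Small accessor generics for the report classes, in place of direct slot
#' access: `cdc()` and `cdcSpread()` return the CDC depth and its dispersion
#' companion, `nVariants()` the number of contributing SNV loci,
#' `variantClass()` the class label, `qcThreshold()` the coverage threshold a
#' report was built with, `sampleMedian()` the whole-sample weighted median
#' depth, `perChromosomeStats()` the per-chromosome summary table,
#' `snvDepths()` the per-locus depth table, `coveredFraction()` the per-class
#' fraction of loci covered at or above the threshold, `geneSymbol()` and
#' `exonStats()` the gene symbol and per-exon table of a gene report, and
#' `geneSpan()` the gene span as a `GRanges`.
#'
#' @param x a [CDCResult-class], [SNVScoreReport-class] or
#'   [GeneCoverageReport-class] object (as applicable).
#' @return See the individual description above; scalar values for
#'   `CDCResult`, named per-class vectors for report-level accessors.
#' @name accessors
#' @aliases cdc cdcSpread nVariants variantClass qcThreshold sampleMedian
#'   perChromosomeStats snvDepths coveredFraction geneSymbol exonStats
#'   geneSpan
NULL

#' @rdname accessors
#' @export
setGeneric("cdc", function(x) standardGeneric("cdc"))

#' @rdname accessors
#' @export
setGeneric("cdcSpread", function(x) standardGeneric("cdcSpread"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))

#' @rdname accessors
#' @export
setGeneric("qcThreshold", function(x) standardGeneric("qcThreshold"))

#' @rdname accessors
#' @export
setGeneric("sampleMedian", function(x) standardGeneric("sampleMedian"))

#' @rdname accessors
#' @export
setGeneric("perChromosomeStats",
           function(x) standardGeneric("perChromosomeStats"))

#' @rdname accessors
#' @export
setGeneric("snvDepths", function(x) standardGeneric("snvDepths"))

#' @rdname accessors
#' @export
setGeneric("coveredFraction", function(x) standardGeneric("coveredFraction"))

#' @rdname accessors
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))

#' @rdname accessors
#' @export
setGeneric("exonStats", function(x) standardGeneric("exonStats"))

#' @rdname accessors
#' @export
setGeneric("geneSpan", function(x) standardGeneric("geneSpan"))
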