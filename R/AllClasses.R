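#' @import methods
NULL

#' Clinical Depth Coverage result for one variant class
#'
#' Holds the CDC statistic for one class of pathogenic SNV loci (germline or
#' somatic): the positive integer depth that balances the number of loci
#' covered above and below it, the dispersion of the underlying depth
#' multiset, and the number of contributing loci.
#'
#' @slot variantClass character, `"germline"` or `"somatic"`.
#' @slot cdc integer, the CDC depth (>= 1).
#' @slot spread numeric, sample standard deviation of the SNV depth multiset
#'   (reported rounded to the nearest integer as the "+/-" companion).
#' @slot nVariants integer, number of SNV loci contributing.
#'
#' @seealso [computeCDC()]
#' @exportClass CDCResult
setClass("CDCResult",
  representation(variantClass = "character",
                 cdc = "integer",
                 spread = "numeric",
                 nVariants = "integer"))

setValidity("CDCResult", function(object) {
  msg <- character(0)
  if (length(object@variantClass) != 1L ||
      !object@variantClass %in% c("germline", "somatic"))
    msg <- c(msg, "variantClass must be 'germline' or 'somatic'")
  if (length(object@cdc) != 1L || is.na(object@cdc) || object@cdc < 1L)
    msg <- c(msg, "cdc must be a positive integer")
  if (length(object@nVariants) != 1L || object@nVariants < 1L)
    msg <- c(msg, "nVariants must be >= 1")
  if (length(object@spread) != 1L || is.na(object@spread) || object@spread < 0)
    msg <- c(msg, "spread must be a non-negative number")
  if (length(msg)) msg else TRUE
})

setClassUnion("CDCResultOrNULL", c("CDCResult", "NULL"))

#' Whole-sample pathogenic SNV coverage report
#'
#' Result of [runSnvScore()]: per-class CDC, per-class fraction of SNV loci
#' covered at or above the threshold, the whole-sample weighted median depth,
#' and a per-chromosome summary table. Individual SNV depths are retained in
#' the `snvDepths` slot for programmatic use.
#'
#' @slot sample character, stem of the sample coverage BED file.
#' @slot threshold integer coverage threshold used for the fractions.
#' @slot sampleMedian integer, weighted (lower) median depth over every base
#'   of the coverage BED.
#' @slot germline,somatic [CDCResult-class] for each class, or `NULL` when a
#'   class contributed no loci.
#' @slot germlineFraction,somaticFraction fraction of loci with depth >=
#'   threshold (`NA` when the class is empty).
#' @slot perChromosome data.frame of per-chromosome, per-class depth
#'   statistics.
#' @slot snvDepths data.frame with one row per SNV record: chrom, pos0
#'   (0-based), gene, variantClass, depth.
#'
#' @exportClass SNVScoreReport
setClass("SNVScoreReport",
  representation(sample = "character",
                 threshold = "integer",
                 sampleMedian = "integer",
                 germline = "CDCResultOrNULL",
                 somatic = "CDCResultOrNULL",
                 germlineFraction = "numeric",
                 somaticFraction = "numeric",
                 perChromosome = "data.frame",
                 snvDepths = "data.frame"))

setValidity("SNVScoreReport", function(object) {
  msg <- character(0)
  fr <- c(object@germlineFraction, object@somaticFraction)
  if (any(!is.na(fr) & (fr < 0 | fr > 1)))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (is.null(object@germline) && is.null(object@somatic))
    msg <- c(msg, "at least one variant class must be present")
  for (cls in c("germline", "somatic")) {
    res <- slot(object, cls)
    if (!is.null(res)) {
      n <- sum(object@snvDepths$variantClass == cls)
      if (n != res@nVariants)
        msg <- c(msg, sprintf("%s nVariants (%d) != rows in snvDepths (%d)",
                              cls, res@nVariants, n))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-gene exon and SNV coverage report
#'
#' Result of [runGeneCoverage()] for one gene: merged-exon geometry with
#' per-exon depth statistics and sub-threshold flags, the pathogenic SNV loci
#' falling inside the gene span (first merged exon start to last merged exon
#' end, introns included) with their depths, and per-class covered fractions.
#'
#' @slot gene character gene symbol.
#' @slot chrom character chromosome label (normalized, no "chr" prefix).
#' @slot spanStart0,spanEnd0 integer gene span bounds, 0-based half-open.
#' @slot threshold integer coverage threshold.
#' @slot exonTable data.frame: exonIndex, start0, end0, width, minDepth,
#'   meanDepth, flagged.
#' @slot snvTable data.frame: variantClass, pos0, gene, depth, covered.
#' @slot germlineFraction,somaticFraction fraction of in-span loci with depth
#'   >= threshold; `NA` when the class has no loci in the span.
#'
#' @exportClass GeneCoverageReport
setClass("GeneCoverageReport",
  representation(gene = "character",
                 chrom = "character",
                 spanStart0 = "integer",
                 spanEnd0 = "integer",
                 threshold = "integer",
                 exonTable = "data.frame",
                 snvTable = "data.frame",
                 germlineFraction = "numeric",
                 somaticFraction = "numeric"))

setValidity("GeneCoverageReport", function(object) {
  msg <- character(0)
  et <- object@exonTable
  if (nrow(et)) {
    if (is.unsorted(et$start0, strictly = TRUE))
      msg <- c(msg, "exon rows must be sorted by start")
    if (!identical(et$flagged, et$minDepth < object@threshold))
      msg <- c(msg, "flagged must equal (minDepth < threshold)")
  } else {
    msg <- c(msg, "exonTable must be non-empty")
  }
  fr <- c(object@germlineFraction, object@somaticFraction)
  if (any(!is.na(fr) & (fr < 0 | fr > 1)))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pre-render description of a two-panel gene coverage figure
#'
#' All semantic content of the figure -- per-base depth trace of the upper
#' panel, exon layout and depth segments of the lower panel, SNV dots, colors
#' and the threshold line -- as plain data, testable without rendering.
#'
#' @slot gene character gene symbol.
#' @slot threshold integer threshold drawn as a horizontal reference line.
#' @slot spanStart0,spanEnd0 integer gene span, 0-based half-open.
#' @slot upper data.frame (pos0, depth): depth trace over the span, max-pooled
#'   for very long spans so dips below threshold are never hidden.
#' @slot exonLayout data.frame (exonIndex, start0, end0, x0, x1, flagged,
#'   color): one row per exon with its genomic extent and allocated
#'   lower-panel x-range.
#' @slot exonSegments data.frame (exonIndex, segStart0, segEnd0, depth, x0,
#'   x1, color): constant-depth segments of each exon in lower-panel
#'   coordinates.
#' @slot dots data.frame (variantClass, pos0, depth, color): SNV overlay dots.
#' @slot palette named character vector of colors in use.
#'
#' @exportClass GeneFigureSpec
setClass("GeneFigureSpec",
  representation(gene = "character",
                 threshold = "integer",
                 spanStart0 = "integer",
                 spanEnd0 = "integer",
                 upper = "data.frame",
                 exonLayout = "data.frame",
                 exonSegments = "data.frame",
                 dots = "data.frame",
                 palette = "character"))

setValidity("GeneFigureSpec", function(object) {
  msg <- character(0)
  if (!nrow(object@exonLayout))
    msg <- c(msg, "exonLayout must contain at least one exon")
  if (nrow(object@dots) &&
      !all(object@dots$variantClass %in% c("germline", "somatic")))
    msg <- c(msg, "dot variantClass must be germline or somatic")
  if (length(msg)) msg else TRUE
})
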