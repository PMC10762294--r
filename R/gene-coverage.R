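#' Per-base depth profile of a gene
#'
#' Builds the data behind the two-panel gene figure: (a) the depth at every
#' base of the gene span -- first merged exon start to last merged exon end,
#' introns included, uncovered bases at depth 0 -- and (b) the clipped
#' constant-depth segments of each merged exon.
#'
#' @param coverage `GRanges` with `depth` for the gene's chromosome.
#' @param exons merged exon `GRanges` of one gene (see [readExonReference()]).
#' @return A list with `gene`, `chrom`, `spanStart0`, `spanEnd0`, `depth`
#'   (integer vector over the span) and `exonSegments` (list of `GRanges`,
#'   one per exon, in `exonIndex` order).
#' @export
geneProfile <- function(coverage, exons) {
  stopifnot(is(exons, "GRanges"), !is.null(exons$gene))
  if (!length(exons)) stop("gene has no exons in the reference", call. = FALSE)
  gene <- unique(exons$gene)
  if (length(gene) != 1L) {
    stop("geneProfile expects the exons of exactly one gene", call. = FALSE)
  }
  chrom <- unique(.normChrom(GenomeInfoDb::seqnames(exons)))
  stopifnot(length(chrom) == 1L)
  exons <- exons[order(GenomicRanges::start(exons))]
  span0 <- c(min(.bedStart(exons)), max(.bedEnd(exons)))

  v <- .coverageVectors(coverage, chrom)
  seg <- .overlapJoin1(v$s0, v$e0, v$d, span0[1L], span0[2L])
  depth <- integer(span0[2L] - span0[1L])
  for (i in seq_len(nrow(seg))) {
    depth[(seg$start[i] - span0[1L] + 1L):(seg$end[i] - span0[1L])] <-
      seg$depth[i]
  }
  exonSegments <- lapply(seq_along(exons), function(i) {
    s <- .overlapJoin1(v$s0, v$e0, v$d, .bedStart(exons)[i],
                       .bedEnd(exons)[i])
    .bedToGRanges(rep(chrom, nrow(s)), s$start, s$end, depth = s$depth)
  })
  names(exonSegments) <- as.character(exons$exonIndex)
  list(gene = gene, chrom = chrom, spanStart0 = span0[1L],
       spanEnd0 = span0[2L], depth = depth, exonSegments = exonSegments)
}

#' Flag exons whose minimum depth falls below a threshold
#'
#' An exon is flagged when any of its bases -- including bases covered by no
#' record, which count as depth 0 -- lies strictly below the threshold. A
#' single under-covered base can hide a variant, so the minimum, not the
#' mean, drives the flag; the mean is reported alongside for judgment.
#'
#' @param exonSegments list of per-exon segment `GRanges` (from
#'   [geneProfile()]).
#' @param exons the merged exon `GRanges` of the same gene.
#' @param threshold positive integer coverage threshold.
#' @return data.frame: exonIndex, start0, end0, width, minDepth, meanDepth,
#'   flagged.
#' @export
flagExons <- function(exonSegments, exons, threshold) {
  threshold <- .assertCount(threshold, "threshold")
  exons <- exons[order(GenomicRanges::start(exons))]
  rows <- lapply(seq_along(exons), function(i) {
    width <- .bedEnd(exons)[i] - .bedStart(exons)[i]
    seg <- exonSegments[[i]]
    segLen <- if (length(seg)) sum(.bedEnd(seg) - .bedStart(seg)) else 0L
    d <- if (length(seg)) as.integer(seg$depth) else integer(0)
    minDepth <- if (segLen < width) 0L else min(d)  # gaps are depth 0
    meanDepth <- if (length(d)) {
      sum(as.numeric(d) * (.bedEnd(seg) - .bedStart(seg))) / width
    } else 0
    data.frame(exonIndex = as.integer(exons$exonIndex[i]),
               start0 = .bedStart(exons)[i], end0 = .bedEnd(exons)[i],
               width = width, minDepth = minDepth, meanDepth = meanDepth,
               flagged = minDepth < threshold)
  })
  do.call(rbind, rows)
}

#' Per-gene exon and pathogenic SNV coverage evaluation
#'
#' For each requested gene: reads that chromosome's coverage, builds the
#' gene profile, flags sub-threshold exons, queries the depth at every
#' pathogenic SNV locus (both classes) falling inside the gene span --
#' membership is by genomic position, so intronic loci inside the span are
#' included -- and computes the per-class fraction covered at or above the
#' threshold. Optionally writes one tabular report and one two-panel figure
#' per gene.
#'
#' @param sampleBed path to the per-base coverage BED.
#' @param exonReference path to the exon reference BED.
#' @param germlineTable,somaticTable paths to the ClinVar-style SNV tables.
#' @param threshold positive integer coverage threshold.
#' @param genes one or more gene symbols; each must exist in the reference.
#' @param outDir if non-`NULL`, writes `<bed stem>_<gene>.tsv` and
#'   `<bed stem>_<gene>.png` there for each gene.
#' @param columns ClinVar column map, see [clinvarColumnMap()].
#' @return Named list (one element per gene) of
#'   [GeneCoverageReport-class] objects, invisibly when `outDir` is set.
#' @export
runGeneCoverage <- function(sampleBed, exonReference, germlineTable,
                            somaticTable, threshold, genes, outDir = NULL,
                            columns = clinvarColumnMap()) {
  threshold <- .assertCount(threshold, "threshold")
  if (!length(genes)) stop("at least one gene symbol is required",
                           call. = FALSE)
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  exons <- readExonReference(exonReference)
  germ <- readClinvarTable(germlineTable, "germline", columns)
  som <- readClinvarTable(somaticTable, "somatic", columns)
  # combine the two classes; seqlevels may be disjoint between tables
  snv <- suppressWarnings(c(germ, som))
  covCache <- new.env(parent = emptyenv())
  stem <- sub("\\.bed(\\.gz)?$", "", basename(sampleBed))
  out <- list()
  for (gene in genes) {
    gx <- exonsForGene(exons, gene)
    chrom <- unique(.normChrom(GenomeInfoDb::seqnames(gx)))
    if (!exists(chrom, envir = covCache)) {
      assign(chrom, readCoverageBed(sampleBed, chrom), envir = covCache)
    }
    coverage <- get(chrom, envir = covCache)
    profile <- geneProfile(coverage, gx)
    exonTable <- flagExons(profile$exonSegments, gx, threshold)

    inSpan <- .normChrom(GenomeInfoDb::seqnames(snv)) == chrom &
      .bedStart(snv) >= profile$spanStart0 &
      .bedStart(snv) < profile$spanEnd0
    loci <- snv[inSpan]
    locDepth <- if (length(loci)) pointDepths(coverage, loci) else integer(0)
    snvTable <- data.frame(
      variantClass = as.character(loci$variantClass),
      pos0 = .bedStart(loci),
      gene = as.character(loci$gene),
      depth = locDepth,
      covered = locDepth >= threshold,
      stringsAsFactors = FALSE)
    snvTable <- snvTable[order(snvTable$pos0, snvTable$variantClass), ,
                         drop = FALSE]
    rownames(snvTable) <- NULL
    frac <- vapply(c("germline", "somatic"), function(cls) {
      d <- snvTable$depth[snvTable$variantClass == cls]
      if (!length(d)) NA_real_ else mean(d >= threshold)
    }, numeric(1L))

    report <- new("GeneCoverageReport",
                  gene = gene, chrom = chrom,
                  spanStart0 = as.integer(profile$spanStart0),
                  spanEnd0 = as.integer(profile$spanEnd0),
                  threshold = threshold,
                  exonTable = exonTable, snvTable = snvTable,
                  germlineFraction = unname(frac[["germline"]]),
                  somaticFraction = unname(frac[["somatic"]]))
    if (!is.null(outDir)) {
      writeGeneCoverageReport(report,
                              file.path(outDir,
                                        sprintf("%s_%s.tsv", stem, gene)))
      renderGeneFigure(report, profile,
                       file.path(outDir, sprintf("%s_%s.png", stem, gene)))
    }
    out[[gene]] <- report
  }
  if (is.null(outDir)) out else invisible(out)
}

.fracLine <- function(frac, cls, threshold) {
  sprintf("# fraction of %s SNVs in span covered >= %dx: %s", cls, threshold,
          if (is.na(frac)) "not applicable (no loci)" else .fmtNum(frac, 4L))
}

#' Write a per-gene coverage report as tab-separated text
#'
#' A `#`-prefixed header block (gene, span, threshold, per-class covered
#' fractions) followed by the per-exon table and the per-SNV table.
#'
#' @param report a [GeneCoverageReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneCoverageReport <- function(report, path) {
  stopifnot(is(report, "GeneCoverageReport"))
  et <- report@exonTable
  st <- report@snvTable
  lines <- c(
    sprintf("# geneCoverage report for gene: %s", report@gene),
    sprintf("# chromosome: %s | span (0-based, half-open): %d-%d",
            report@chrom, report@spanStart0, report@spanEnd0),
    sprintf("# coverage threshold: %d", report@threshold),
    .fracLine(report@germlineFraction, "germline", report@threshold),
    .fracLine(report@somaticFraction, "somatic", report@threshold),
    sprintf("# exons: %d (%d below threshold)", nrow(et), sum(et$flagged)),
    paste(c("exon_index", "start", "end", "width", "min_depth", "mean_depth",
            "flagged"), collapse = "\t"),
    sprintf("%d\t%d\t%d\t%d\t%d\t%s\t%s", et$exonIndex, et$start0, et$end0,
            et$width, et$minDepth, .fmtNum(et$meanDepth), et$flagged),
    sprintf("# SNVs in gene span: %d", nrow(st)),
    paste(c("variant_class", "position", "gene", "depth", "covered"),
          collapse = "\t"))
  if (nrow(st)) {
    lines <- c(lines,
               sprintf("%s\t%d\t%s\t%d\t%s", st$variantClass, st$pos0 + 1L,
                       st$gene, st$depth, st$covered))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("geneSymbol", "GeneCoverageReport", function(x) x@gene)

#' @rdname accessors
#' @export
setMethod("exonStats", "GeneCoverageReport", function(x) x@exonTable)

#' @rdname accessors
#' @export
setMethod("snvDepths", "GeneCoverageReport", function(x) x@snvTable)

#' @rdname accessors
#' @export
setMethod("qcThreshold", "GeneCoverageReport", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("coveredFraction", "GeneCoverageReport", function(x)
  c(germline = x@germlineFraction, somatic = x@somaticFraction))

#' @rdname accessors
#' @export
setMethod("geneSpan", "GeneCoverageReport", function(x)
  .bedToGRanges(x@chrom, x@spanStart0, x@spanEnd0, gene = x@gene))

setMethod("show", "GeneCoverageReport", function(object) {
  et <- object@exonTable
  cat(sprintf("GeneCoverageReport for %s (chr%s:%d-%d)\n", object@gene,
              object@chrom, object@spanStart0 + 1L, object@spanEnd0))
  cat(sprintf("  threshold: %dx | exons: %d (%d flagged below threshold)\n",
              object@threshold, nrow(et), sum(et$flagged)))
  cat(sprintf("  SNVs in span: %d | germline fraction >= %dx: %s | somatic: %s\n",
              nrow(object@snvTable), object@threshold,
              .fmtNum(object@germlineFraction, 4L),
              .fmtNum(object@somaticFraction, 4L)))
})
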