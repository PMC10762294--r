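#' Clinical Depth Coverage (CDC) of an SNV depth multiset
#'
#' CDC is the positive integer depth m at which the number of pathogenic SNV
#' loci covered deeper than m best balances the number covered shallower:
#' the smallest m in `1 .. max(depth) + 1` minimizing
#' `|sum_i sgn(depth_i - m)|` with `sgn(0) = 0`. For an odd number of loci
#' with a unique middle depth this is exactly the median depth; ties are
#' broken toward the smallest (most conservative) m. The dispersion
#' companion is the sample standard deviation of the depth multiset.
#'
#' @param depths non-negative integer depths, one per SNV locus (duplicate
#'   loci each count once per record).
#' @param variantClass `"germline"` or `"somatic"`.
#' @return A [CDCResult-class].
#' @examples
#' cdc(computeCDC(c(10, 20, 30)))        # 20
#' cdc(computeCDC(c(5, 5, 50, 50)))      # 6: smallest balancing depth
#' @export
computeCDC <- function(depths, variantClass = c("germline", "somatic")) {
  variantClass <- match.arg(variantClass)
  depths <- as.integer(depths)
  if (!length(depths)) {
    stop("cannot compute CDC: no variants on processed chromosomes",
         call. = FALSE)
  }
  if (anyNA(depths) || any(depths < 0L)) {
    stop("depths must be non-negative integers", call. = FALSE)
  }
  n <- length(depths)
  maxd <- max(depths)
  grid <- seq_len(maxd + 1L)
  # counts below/above each m from the cumulative depth tabulation:
  # cb[i] = #{depth <= i - 1} = #{depth < i}
  cb <- cumsum(tabulate(depths + 1L, nbins = maxd + 2L))
  below <- cb[grid]
  above <- n - cb[grid + 1L]
  best <- grid[which.min(abs(above - below))]  # which.min -> smallest m
  sdv <- if (n > 1L) stats::sd(depths) else 0
  new("CDCResult", variantClass = variantClass, cdc = as.integer(best),
      spread = sdv, nVariants = n)
}

#' Fraction of loci covered at or above a threshold
#'
#' @param depths non-negative integer depths, one per SNV locus.
#' @param threshold positive integer coverage threshold; "covered" is
#'   inclusive (`depth >= threshold`).
#' @return Fraction in `[0, 1]`.
#' @export
fractionAbove <- function(depths, threshold) {
  threshold <- .assertCount(threshold, "threshold")
  if (!length(depths)) {
    stop("cannot compute a covered fraction of an empty depth set",
         call. = FALSE)
  }
  mean(depths >= threshold)
}

#' Whole-sample evaluation of pathogenic SNV coverage
#'
#' Streams a per-base coverage BED once, in bounded-memory chunks, while (a)
#' accumulating a depth histogram over every base for the whole-sample
#' weighted median and (b) querying the depth at every pathogenic SNV locus
#' of both ClinVar tables. Finishes by computing the per-class CDC, the
#' per-class fraction of loci covered at or above `threshold`, and a
#' per-chromosome summary table.
#'
#' Loci on chromosomes absent from the BED are scored depth 0 with a
#' warning: an unsequenced pathogenic locus is a coverage failure, not
#' missing data.
#'
#' @param sampleBed path to the per-base coverage BED.
#' @param germlineTable,somaticTable paths to ClinVar-style tables of
#'   pathogenic germline and somatic SNVs.
#' @param threshold positive integer coverage threshold; defaults to 1
#'   ("covered at all").
#' @param outDir if non-`NULL`, the tabular report is written there as
#'   `<bed stem>_snvScore.tsv`.
#' @param chunkLines lines per streaming chunk (memory bound).
#' @param columns ClinVar column map, see [clinvarColumnMap()].
#' @param verbose message per-chunk progress.
#' @return An [SNVScoreReport-class].
#' @export
runSnvScore <- function(sampleBed, germlineTable, somaticTable,
                        threshold = 1L, outDir = NULL,
                        chunkLines = 200000L,
                        columns = clinvarColumnMap(), verbose = FALSE) {
  threshold <- .assertCount(threshold, "threshold")
  germ <- readClinvarTable(germlineTable, "germline", columns)
  som <- readClinvarTable(somaticTable, "somatic", columns)
  if (!length(germ) && !length(som)) {
    stop("no SNVs parsed from either ClinVar table", call. = FALSE)
  }
  snv <- rbind(
    data.frame(chrom = .normChrom(GenomeInfoDb::seqnames(germ)),
               pos0 = .bedStart(germ), gene = germ$gene,
               variantClass = rep("germline", length(germ)),
               stringsAsFactors = FALSE),
    data.frame(chrom = .normChrom(GenomeInfoDb::seqnames(som)),
               pos0 = .bedStart(som), gene = som$gene,
               variantClass = rep("somatic", length(som)),
               stringsAsFactors = FALSE))

  idxByChrom <- split(seq_len(nrow(snv)), snv$chrom)
  depths <- integer(nrow(snv))
  seen <- character(0)
  histDepth <- integer(0)
  histLen <- numeric(0)

  .scanBedChunks(sampleBed, function(df) {
    df$chrom <- .normChrom(df$chrom)
    seen <<- union(seen, unique(df$chrom))
    agg <- rowsum(as.numeric(df$end - df$start), group = df$depth)
    histDepth <<- c(histDepth, as.integer(rownames(agg)))
    histLen <<- c(histLen, agg[, 1L])
    for (ch in intersect(unique(df$chrom), names(idxByChrom))) {
      sub <- df[df$chrom == ch, , drop = FALSE]
      ord <- order(sub$start)
      idx <- idxByChrom[[ch]]
      hit <- .pointDepths1(sub$start[ord], sub$end[ord], sub$depth[ord],
                           snv$pos0[idx])
      nz <- hit != 0L
      depths[idx[nz]] <<- hit[nz]
    }
    if (verbose) {
      message(sprintf("processed %d coverage rows (chromosome(s) %s)",
                      nrow(df), paste(unique(df$chrom), collapse = ", ")))
    }
  }, chunkLines = chunkLines)

  absent <- setdiff(names(idxByChrom), seen)
  if (length(absent)) {
    warning(sprintf(
      "chromosome(s) %s present in SNV tables but absent from the coverage BED; their SNVs scored as depth 0",
      paste(absent, collapse = ", ")), call. = FALSE)
  }
  if (!length(histDepth)) {
    stop(sprintf("coverage BED '%s' contains no rows", basename(sampleBed)),
         call. = FALSE)
  }
  # consolidate the per-chunk histogram before the weighted median
  agg <- rowsum(histLen, group = histDepth)
  med <- weightedMedian(agg[, 1L], as.integer(rownames(agg)))

  snv$depth <- depths
  byClass <- split(snv$depth, snv$variantClass)
  res <- list(germline = NULL, somatic = NULL)
  frac <- c(germline = NA_real_, somatic = NA_real_)
  for (cls in c("germline", "somatic")) {
    d <- byClass[[cls]]
    if (length(d)) {
      res[[cls]] <- computeCDC(d, cls)
      frac[[cls]] <- fractionAbove(d, threshold)
    }
  }
  report <- new("SNVScoreReport",
                sample = sub("\\.bed(\\.gz)?$", "", basename(sampleBed)),
                threshold = threshold,
                sampleMedian = as.integer(med),
                germline = res$germline, somatic = res$somatic,
                germlineFraction = unname(frac[["germline"]]),
                somaticFraction = unname(frac[["somatic"]]),
                perChromosome = .perChromosomeTable(snv, threshold),
                snvDepths = snv[, c("chrom", "pos0", "gene", "variantClass",
                                    "depth")])
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outDir, paste0(report@sample, "_snvScore.tsv"))
    writeSnvScoreReport(report, path)
  }
  report
}

.perChromosomeTable <- function(snv, threshold) {
  chroms <- unique(snv$chrom)
  chroms <- chroms[.chromOrder(chroms)]
  statRow <- function(d) {
    if (!length(d)) {
      c(n = 0, mean = NA_real_, median = NA_real_, min = NA_real_,
        max = NA_real_, frac = NA_real_)
    } else {
      c(n = length(d), mean = mean(d), median = stats::median(d),
        min = min(d), max = max(d), frac = mean(d >= threshold))
    }
  }
  rows <- lapply(chroms, function(ch) {
    g <- statRow(snv$depth[snv$chrom == ch & snv$variantClass == "germline"])
    s <- statRow(snv$depth[snv$chrom == ch & snv$variantClass == "somatic"])
    data.frame(chrom = ch,
               germline_n = g[["n"]], germline_mean = g[["mean"]],
               germline_median = g[["median"]], germline_min = g[["min"]],
               germline_max = g[["max"]], germline_frac = g[["frac"]],
               somatic_n = s[["n"]], somatic_mean = s[["mean"]],
               somatic_median = s[["median"]], somatic_min = s[["min"]],
               somatic_max = s[["max"]], somatic_frac = s[["frac"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.cdcLine <- function(res) {
  if (is.null(res)) return("NA (no variants)")
  sprintf("%d +/- %d (n = %d)", res@cdc, round(res@spread), res@nVariants)
}

#' Write an SNV score report as tab-separated text
#'
#' A `#`-prefixed header block (threshold, per-class CDC with its "+/- sd"
#' dispersion companion, covered fractions, whole-sample median) followed by
#' the per-chromosome statistics table. Output is byte-deterministic for
#' identical inputs.
#'
#' @param report an [SNVScoreReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSnvScoreReport <- function(report, path) {
  stopifnot(is(report, "SNVScoreReport"))
  pc <- report@perChromosome
  fmtRow <- function(i) {
    r <- pc[i, ]
    paste(c(r$chrom,
            r$germline_n, .fmtNum(r$germline_mean), .fmtNum(r$germline_median, 1L),
            .fmtNum(r$germline_min, 0L), .fmtNum(r$germline_max, 0L),
            .fmtNum(r$germline_frac, 4L),
            r$somatic_n, .fmtNum(r$somatic_mean), .fmtNum(r$somatic_median, 1L),
            .fmtNum(r$somatic_min, 0L), .fmtNum(r$somatic_max, 0L),
            .fmtNum(r$somatic_frac, 4L)),
          collapse = "\t")
  }
  lines <- c(
    sprintf("# snvScore report for sample: %s", report@sample),
    sprintf("# coverage threshold: %d", report@threshold),
    sprintf("# germline CDC (+/- sd): %s", .cdcLine(report@germline)),
    sprintf("# somatic CDC (+/- sd): %s", .cdcLine(report@somatic)),
    sprintf("# fraction of germline variants covered >= %dx: %s",
            report@threshold, .fmtNum(report@germlineFraction, 4L)),
    sprintf("# fraction of somatic variants covered >= %dx: %s",
            report@threshold, .fmtNum(report@somaticFraction, 4L)),
    sprintf("# sample coverage median (weighted over all bases): %d",
            report@sampleMedian),
    paste(c("chrom",
            "germline_n", "germline_mean", "germline_median", "germline_min",
            "germline_max", "germline_frac",
            "somatic_n", "somatic_mean", "somatic_median", "somatic_min",
            "somatic_max", "somatic_frac"), collapse = "\t"),
    vapply(seq_len(nrow(pc)), fmtRow, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("cdc", "CDCResult", function(x) x@cdc)

#' @rdname accessors
#' @export
setMethod("cdcSpread", "CDCResult", function(x) x@spread)

#' @rdname accessors
#' @export
setMethod("nVariants", "CDCResult", function(x) x@nVariants)

#' @rdname accessors
#' @export
setMethod("variantClass", "CDCResult", function(x) x@variantClass)

setMethod("show", "CDCResult", function(object) {
  cat(sprintf("CDCResult (%s): CDC = %d +/- %d over %d SNV loci\n",
              object@variantClass, object@cdc, round(object@spread),
              object@nVariants))
})

.classOrNA <- function(res, what) {
  if (is.null(res)) NA_integer_ else slot(res, what)
}

#' @rdname accessors
#' @export
setMethod("cdc", "SNVScoreReport", function(x)
  c(germline = .classOrNA(x@germline, "cdc"),
    somatic = .classOrNA(x@somatic, "cdc")))

#' @rdname accessors
#' @export
setMethod("cdcSpread", "SNVScoreReport", function(x)
  c(germline = if (is.null(x@germline)) NA_real_ else x@germline@spread,
    somatic = if (is.null(x@somatic)) NA_real_ else x@somatic@spread))

#' @rdname accessors
#' @export
setMethod("nVariants", "SNVScoreReport", function(x)
  c(germline = .classOrNA(x@germline, "nVariants"),
    somatic = .classOrNA(x@somatic, "nVariants")))

#' @rdname accessors
#' @export
setMethod("qcThreshold", "SNVScoreReport", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("sampleMedian", "SNVScoreReport", function(x) x@sampleMedian)

#' @rdname accessors
#' @export
setMethod("perChromosomeStats", "SNVScoreReport", function(x)
  x@perChromosome)

#' @rdname accessors
#' @export
setMethod("snvDepths", "SNVScoreReport", function(x) x@snvDepths)

#' @rdname accessors
#' @export
setMethod("coveredFraction", "SNVScoreReport", function(x)
  c(germline = x@germlineFraction, somatic = x@somaticFraction))

setMethod("show", "SNVScoreReport", function(object) {
  cat(sprintf("SNVScoreReport for sample '%s'\n", object@sample))
  cat(sprintf("  threshold: %dx | sample median depth: %d\n",
              object@threshold, object@sampleMedian))
  cat(sprintf("  germline: CDC %s | fraction >= %dx: %s\n",
              .cdcLine(object@germline), object@threshold,
              .fmtNum(object@germlineFraction, 4L)))
  cat(sprintf("  somatic:  CDC %s | fraction >= %dx: %s\n",
              .cdcLine(object@somatic), object@threshold,
              .fmtNum(object@somaticFraction, 4L)))
  cat(sprintf("  chromosomes: %d (see perChromosomeStats())\n",
              nrow(object@perChromosome)))
})
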