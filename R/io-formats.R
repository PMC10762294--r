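#' Read a per-base coverage BED file
#'
#' Reads the 4-column per-base output dialect of depth tools run on
#' alignments: tab-separated `chrom, start, end, depth` with 0-based
#' half-open coordinates, each row one maximal run of constant depth. The
#' file is scanned in chunks; when `chrom` is given only that chromosome's
#' rows are kept, so memory stays bounded by one chromosome regardless of
#' file size.
#'
#' Chromosome labels are normalized by stripping an optional `"chr"` prefix,
#' so `chrom = "chr2"` and `chrom = "2"` select the same rows. Rows arriving
#' unsorted within a chromosome are sorted with a warning; overlapping rows
#' within a chromosome are rejected.
#'
#' @param path path to the coverage BED file.
#' @param chrom optional single chromosome label to restrict to.
#' @param chunkLines number of lines read per chunk.
#' @return A `GRanges` (1-based closed, i.e. BED start + 1) with an integer
#'   `depth` metadata column, in file order per chromosome after sorting.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t110\t5", "chr1\t110\t130\t8"), bed)
#' readCoverageBed(bed)
#' @export
readCoverageBed <- function(path, chrom = NULL, chunkLines = 200000L) {
  want <- if (is.null(chrom)) NULL else .normChrom(chrom)
  parts <- list()
  .scanBedChunks(path, function(df) {
    df$chrom <- .normChrom(df$chrom)
    if (!is.null(want)) df <- df[df$chrom %in% want, , drop = FALSE]
    if (nrow(df)) parts[[length(parts) + 1L]] <<- df
  }, chunkLines = chunkLines)
  df <- if (length(parts)) do.call(rbind, parts) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               depth = integer(0))
  df <- .validateCoverageFrame(df, path)
  .bedToGRanges(df$chrom, df$start, df$end, depth = df$depth)
}

# Sortedness / disjointness checks per chromosome, on the BED-convention
# frame. Unsorted input is sorted with a warning; overlap is an error.
.validateCoverageFrame <- function(df, path) {
  if (!nrow(df)) return(df)
  pieces <- split(seq_len(nrow(df)), df$chrom)
  warned <- FALSE
  for (idx in pieces) {
    s <- df$start[idx]
    if (is.unsorted(s)) {
      if (!warned) {
        warning(sprintf(
          "coverage BED '%s': rows unsorted within a chromosome; sorting in memory",
          basename(path)), call. = FALSE)
        warned <- TRUE
      }
      idx <- idx[order(s)]
      pieces[[as.character(df$chrom[idx[1L]])]] <- idx
      s <- df$start[idx]
    }
    e <- df$end[idx]
    if (length(idx) > 1L && any(e[-length(e)] > s[-1L])) {
      stop(sprintf(
        "coverage BED '%s': overlapping intervals on chromosome %s",
        basename(path), df$chrom[idx[1L]]), call. = FALSE)
    }
  }
  ord <- unlist(pieces[unique(df$chrom)], use.names = FALSE)
  df[ord, , drop = FALSE]
}

#' Write coverage intervals back to BED
#'
#' Inverse of [readCoverageBed()]: writes `chrom, start, end, depth` rows,
#' tab-separated, 0-based half-open, no header.
#'
#' @param coverage `GRanges` with a `depth` metadata column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCoverageBed <- function(coverage, path) {
  stopifnot(is(coverage, "GRanges"), !is.null(coverage$depth))
  lines <- sprintf("%s\t%d\t%d\t%d",
                   as.character(GenomeInfoDb::seqnames(coverage)),
                   .bedStart(coverage), .bedEnd(coverage),
                   as.integer(coverage$depth))
  writeLines(lines, path)
  invisible(path)
}

#' Read an exon reference BED and merge isoform exons per gene
#'
#' The exon reference is a BED file whose 4th column is a gene symbol, with
#' one row per (transcript, exon). Within each gene, overlapping or
#' book-ended rows -- exons shared or extended across isoforms -- are merged
#' into disjoint intervals, sorted by start, and numbered `exonIndex = 1..k`.
#'
#' @param path path to the exon BED file.
#' @return A `GRanges` with metadata columns `gene` and `exonIndex`, grouped
#'   by gene and sorted by start within each gene.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr7\t100\t200\tG1", "chr7\t150\t250\tG1",
#'              "chr7\t300\t400\tG1"), bed)
#' readExonReference(bed)  # G1 exons: (100,250) and (300,400)
#' @export
readExonReference <- function(path) {
  parts <- list()
  .scanBedChunks(path, function(df) parts[[length(parts) + 1L]] <<- df,
                 what = "exon reference BED", geneColumn = TRUE)
  if (!length(parts)) {
    stop(sprintf("exon reference '%s' contains no rows", basename(path)),
         call. = FALSE)
  }
  df <- do.call(rbind, parts)
  gr <- .bedToGRanges(.normChrom(df$chrom), df$start, df$end, gene = df$gene)
  merged <- lapply(split(gr, gr$gene), function(g) {
    chroms <- unique(as.character(GenomeInfoDb::seqnames(g)))
    if (length(chroms) > 1L) {
      stop(sprintf("gene '%s' maps to multiple chromosomes: %s",
                   g$gene[1L], paste(chroms, collapse = ", ")),
           call. = FALSE)
    }
    r <- GenomicRanges::reduce(g)  # merges overlapping and book-ended rows
    r$gene <- g$gene[1L]
    r$exonIndex <- seq_along(r)
    r
  })
  out <- unlist(GenomicRanges::GRangesList(merged), use.names = FALSE)
  out[order(match(out$gene, names(merged)), GenomicRanges::start(out))]
}

#' Exons of one gene
#'
#' @param exons the merged exon `GRanges` from [readExonReference()].
#' @param gene a single gene symbol.
#' @return The gene's exons, sorted by start. Errors with near-match
#'   suggestions when the symbol is absent.
#' @export
exonsForGene <- function(exons, gene) {
  stopifnot(is(exons, "GRanges"), !is.null(exons$gene))
  hit <- exons[exons$gene == gene]
  if (!length(hit)) {
    near <- unique(agrep(gene, unique(exons$gene), max.distance = 0.3,
                         value = TRUE, ignore.case = TRUE))
    stop(sprintf("gene '%s' not found in the exon reference%s", gene,
                 if (length(near))
                   sprintf(" (did you mean: %s?)",
                           paste(utils::head(near, 5L), collapse = ", "))
                 else ""),
         call. = FALSE)
  }
  hit[order(GenomicRanges::start(hit))]
}

#' Default ClinVar tabular-export column names
#'
#' Names of the chromosome, 1-based position and gene columns in a ClinVar
#' web-export table. Pass a modified copy to [readClinvarTable()] for other
#' dialects.
#'
#' @param chrom,position,gene column names.
#' @return Named character vector with entries `chrom`, `position`, `gene`.
#' @export
clinvarColumnMap <- function(chrom = "GRCh38Chromosome",
                             position = "GRCh38Location",
                             gene = "Gene(s)") {
  c(chrom = chrom, position = position, gene = gene)
}

#' Read a ClinVar-style pathogenic SNV table
#'
#' Reads a tab-separated table with a header line, keeping one record per
#' single-nucleotide locus. Positions are 1-based in the file and converted
#' to 0-based internally (the returned `GRanges` is 1-based closed, so
#' `start(gr) - 1` is the 0-based offset). Rows whose position field is
#' empty, non-numeric, or a range of two numbers (not a single-nucleotide
#' locus) are skipped; the skip count is recorded in
#' `S4Vectors::metadata(gr)$skippedRows` and messaged.
#'
#' @param path path to the table.
#' @param variantClass `"germline"` or `"somatic"`.
#' @param columns column map from [clinvarColumnMap()].
#' @return A width-1 `GRanges` with metadata columns `gene` and
#'   `variantClass`.
#' @export
readClinvarTable <- function(path, variantClass = c("germline", "somatic"),
                             columns = clinvarColumnMap()) {
  variantClass <- match.arg(variantClass)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  missing <- setdiff(unname(columns), names(tab))
  if (length(missing)) {
    stop(sprintf("SNV table '%s' lacks required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  pos <- trimws(tab[[columns[["position"]]]])
  valid <- grepl("^[0-9]+$", pos)
  skipped <- sum(!valid)
  if (skipped) {
    message(sprintf(
      "%s: skipped %d row(s) without a single-nucleotide position",
      basename(path), skipped))
  }
  keep <- which(valid)
  pos1 <- as.integer(pos[keep])
  gr <- .bedToGRanges(.normChrom(tab[[columns[["chrom"]]]][keep]),
                      pos1 - 1L, pos1,
                      gene = trimws(tab[[columns[["gene"]]]][keep]),
                      variantClass = rep(variantClass, length(keep)))
  S4Vectors::metadata(gr)$skippedRows <- skipped
  gr
}
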