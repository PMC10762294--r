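# Internal helpers shared by the readers and the interval engine.

# Chromosome labels are compared after stripping an optional "chr" prefix so
# that depth-tool BEDs ("chr17") and ClinVar exports ("17") interoperate.
.normChrom <- function(x) sub("^chr", "", as.character(x))

# Stable human-genome-ish ordering: numeric chromosomes first, then X, Y, MT,
# then anything else alphabetically.
.chromOrder <- function(chroms) {
  base <- .normChrom(chroms)
  num <- suppressWarnings(as.integer(base))
  special <- match(toupper(base), c("X", "Y", "MT", "M"))
  key <- ifelse(!is.na(num), num,
                ifelse(!is.na(special), 1000L + special, 2000L))
  order(key, base)
}

.assertCount <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x) ||
      (positive && x < 1) || (!positive && x < 0)) {
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  as.integer(x)
}

# Parse a block of BED-like lines into a data.frame, reporting absolute file
# line numbers on failure. `lineNos` runs parallel to `lines`.
.parseBedRows <- function(lines, lineNos, what = "coverage BED",
                          geneColumn = FALSE) {
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  minFields <- 4L
  if (any(nf < minFields)) {
    i <- which(nf < minFields)[1L]
    stop(sprintf(
      "%s parse error at line %d: expected at least %d tab-separated fields, found %d",
      what, lineNos[i], minFields, nf[i]), call. = FALSE)
  }
  chrom <- vapply(f, `[[`, character(1L), 1L)
  start <- suppressWarnings(as.integer(vapply(f, `[[`, character(1L), 2L)))
  end <- suppressWarnings(as.integer(vapply(f, `[[`, character(1L), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s parse error at line %d: non-integer start/end",
                 what, lineNos[bad[1L]]), call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("%s parse error at line %d: start (%d) must be < end (%d)",
                 what, lineNos[bad[1L]], start[bad[1L]], end[bad[1L]]),
         call. = FALSE)
  }
  bad <- which(start < 0L)
  if (length(bad)) {
    stop(sprintf("%s parse error at line %d: negative start coordinate",
                 what, lineNos[bad[1L]]), call. = FALSE)
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (geneColumn) {
    gene <- vapply(f, `[[`, character(1L), 4L)
    bad <- which(!nzchar(gene))
    if (length(bad)) {
      stop(sprintf("%s parse error at line %d: empty gene symbol",
                   what, lineNos[bad[1L]]), call. = FALSE)
    }
    out$gene <- gene
  } else {
    depth <- suppressWarnings(as.integer(vapply(f, `[[`, character(1L), 4L)))
    bad <- which(is.na(depth))
    if (length(bad)) {
      stop(sprintf("%s parse error at line %d: non-integer depth",
                   what, lineNos[bad[1L]]), call. = FALSE)
    }
    bad <- which(depth < 0L)
    if (length(bad)) {
      stop(sprintf("%s parse error at line %d: negative depth",
                   what, lineNos[bad[1L]]), call. = FALSE)
    }
    out$depth <- depth
  }
  out
}

# Stream a BED file in chunks of at most `chunkLines` lines, calling
# `fun(df, lineNos)` on each parsed non-empty block. Memory is bounded by one
# chunk; the whole file is never materialized here.
.scanBedChunks <- function(path, fun, chunkLines = 200000L,
                           what = "coverage BED", geneColumn = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  con <- file(path, open = "r")
  on.exit(close(con))
  offset <- 0L
  repeat {
    lines <- readLines(con, n = chunkLines)
    if (!length(lines)) break
    keep <- which(nzchar(lines) & !startsWith(lines, "#"))
    if (length(keep)) {
      df <- .parseBedRows(lines[keep], keep + offset, what = what,
                          geneColumn = geneColumn)
      fun(df)
    }
    offset <- offset + length(lines)
  }
  invisible(NULL)
}

# GRanges (1-based closed) from BED-convention fields (0-based half-open).
.bedToGRanges <- function(chrom, start0, end0, ...) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0))
  mc <- list(...)
  if (length(mc)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  }
  gr
}

.bedStart <- function(gr) GenomicRanges::start(gr) - 1L
.bedEnd <- function(gr) GenomicRanges::end(gr)

.fmtNum <- function(x, digits = 2L) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}
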