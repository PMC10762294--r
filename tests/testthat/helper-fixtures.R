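# Shared helpers: tiny in-code fixtures and independent per-base oracles.

# Coverage GRanges from BED-convention vectors (0-based half-open).
covGR <- function(chrom, s0, e0, d) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0),
                         depth = as.integer(d))
}

# Write BED lines (0-based half-open) to a temp file.
writeBed <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent per-base rasterization of coverage records over [from0, to0).
rasterizeDepth <- function(s0, e0, d, from0, to0) {
  v <- integer(to0 - from0)
  for (i in seq_along(s0)) {
    lo <- max(s0[i], from0)
    hi <- min(e0[i], to0)
    if (lo < hi) v[(lo - from0 + 1L):(hi - from0)] <- d[i]
  }
  v
}

# Maximal constant-depth nonzero-record-backed runs of a rasterized vector,
# restricted to bases backed by a record (we mark unbacked bases NA).
rasterizeSegments <- function(s0, e0, d, from0, to0) {
  v <- rep(NA_integer_, to0 - from0)
  for (i in seq_along(s0)) {
    lo <- max(s0[i], from0)
    hi <- min(e0[i], to0)
    if (lo < hi) v[(lo - from0 + 1L):(hi - from0)] <- d[i]
  }
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- !is.na(runs$values)
  data.frame(start = from0 + starts[keep], end = from0 + ends[keep],
             depth = runs$values[keep])
}

# Exhaustive scan of the CDC definition: smallest m in 1..max+1 minimizing
# the absolute sign-sum. Independent of computeCDC's tabulation shortcut.
bruteForceCDC <- function(depths) {
  grid <- seq_len(max(depths) + 1L)
  score <- vapply(grid, function(m) abs(sum(sign(depths - m))), numeric(1L))
  grid[which.min(score)]
}

# Random sorted non-overlapping coverage records on [0, limit).
randomCoverage <- function(n, limit = 1000L, maxDepth = 50L) {
  cuts <- sort(sample.int(limit, min(2L * n, limit - 1L)))
  s0 <- cuts[seq(1L, length(cuts) - 1L, by = 2L)]
  e0 <- cuts[seq(2L, length(cuts), by = 2L)]
  ok <- s0 < e0
  s0 <- s0[ok]; e0 <- e0[ok]
  list(s0 = s0, e0 = e0, d = sample.int(maxDepth, length(s0), replace = TRUE))
}

# A small deterministic two-gene fixture used across module tests.
standardFixtureSpec <- function(depthModel = depthConstant(20),
                                threshold = 15, seed = 11) {
  fixtureSpec(
    chromLengths = c(chr1 = 6000, chr2 = 4000),
    depthModel = depthModel,
    genes = data.frame(gene = c("G1", "G1", "G2"),
                       chrom = c("1", "1", "2"),
                       start0 = c(100, 600, 200),
                       end0 = c(300, 900, 1200)),
    placement = list(germlineExon = 8, germlineIntron = 2,
                     somaticExon = 8, somaticIntron = 2),
    threshold = threshold, seed = seed)
}
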