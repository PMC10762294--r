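# Core interval geometry: clip sorted constant-depth runs onto targets,
# answer point-depth queries, and compute length-weighted order statistics.
# All public interfaces use GRanges; the arithmetic runs on 0-based
# half-open vectors.

# Workhorse on BED-convention vectors (s0 < e0 sorted, disjoint). Returns a
# data.frame of clipped segments, adjacent equal-depth segments merged so
# each output row is a maximal constant-depth run within the target.
.overlapJoin1 <- function(s0, e0, d, tStart0, tEnd0) {
  if (length(s0) && is.unsorted(s0)) {
    stop("coverage intervals must be sorted by start (contract violation)",
         call. = FALSE)
  }
  keep <- which(e0 > tStart0 & s0 < tEnd0)
  s <- pmax(s0[keep], tStart0)
  e <- pmin(e0[keep], tEnd0)
  d <- d[keep]
  if (length(s) > 1L) {
    # merge book-ended runs of equal depth into maximal segments
    newRun <- c(TRUE, s[-1L] != e[-length(e)] | d[-1L] != d[-length(d)])
    grp <- cumsum(newRun)
    s <- s[newRun]
    e <- as.integer(tapply(e, grp, max))
    d <- d[newRun]
  }
  data.frame(start = s, end = e, depth = d)
}

.coverageVectors <- function(coverage, chrom = NULL) {
  stopifnot(is(coverage, "GRanges"), !is.null(coverage$depth))
  if (!is.null(chrom)) {
    coverage <- coverage[.normChrom(GenomeInfoDb::seqnames(coverage)) ==
                           .normChrom(chrom)]
  } else if (length(unique(as.character(GenomeInfoDb::seqnames(coverage)))) > 1L) {
    stop("coverage spans multiple chromosomes; supply 'chrom'",
         call. = FALSE)
  }
  list(s0 = .bedStart(coverage), e0 = .bedEnd(coverage),
       d = as.integer(coverage$depth))
}

#' Clip coverage runs onto a target interval
#'
#' Joins sorted, non-overlapping constant-depth coverage runs onto one target
#' interval: every maximal sub-interval of the target where a coverage record
#' gives a constant depth is returned, clipped to the target bounds. Bases of
#' the target not covered by any record are not emitted -- callers treat them
#' as depth 0.
#'
#' @param coverage `GRanges` with `depth` (one chromosome, or any if `target`
#'   carries a chromosome).
#' @param target a length-1 `GRanges` giving the interval (its seqname
#'   selects the chromosome from `coverage`).
#' @return `GRanges` of disjoint, sorted segments contained in the target,
#'   with a `depth` metadata column.
#' @examples
#' cov <- GenomicRanges::GRanges("1", IRanges::IRanges(101, 110), depth = 5L)
#' tgt <- GenomicRanges::GRanges("1", IRanges::IRanges(106, 120))
#' overlapJoin(cov, tgt)  # one segment: bases 106..110 at depth 5
#' @export
overlapJoin <- function(coverage, target) {
  stopifnot(is(target, "GRanges"), length(target) == 1L)
  v <- .coverageVectors(coverage, as.character(GenomeInfoDb::seqnames(target)))
  seg <- .overlapJoin1(v$s0, v$e0, v$d,
                       .bedStart(target), .bedEnd(target))
  .bedToGRanges(rep(.normChrom(GenomeInfoDb::seqnames(target)), nrow(seg)),
                seg$start, seg$end, depth = seg$depth)
}

# Point query on BED-convention vectors; positions anywhere, depth 0 where no
# record covers. Single forward pass via findInterval on sorted starts.
.pointDepths1 <- function(s0, e0, d, pos0) {
  if (!length(pos0)) return(integer(0))
  if (!length(s0)) return(integer(length(pos0)))
  if (is.unsorted(s0)) {
    stop("coverage intervals must be sorted by start (contract violation)",
         call. = FALSE)
  }
  i <- findInterval(pos0, s0)
  hit <- i >= 1L & pos0 < e0[pmax(i, 1L)]
  out <- integer(length(pos0))
  out[hit] <- d[i[hit]]
  out
}

#' Depth at individual positions
#'
#' Queries the depth of sorted constant-depth coverage runs at point
#' positions. Positions covered by no record have depth 0 (an unsequenced
#' locus counts as uncovered, not missing). The right boundary of a run is
#' exclusive: with a run over 0-based `[100, 110)`, position 110 has depth 0.
#'
#' @param coverage `GRanges` with `depth`.
#' @param positions either a width-1 `GRanges` of loci (chromosome-aware), or
#'   an integer vector of 0-based offsets (then `coverage` must be a single
#'   chromosome).
#' @return Integer vector of depths, parallel to `positions`.
#' @export
pointDepths <- function(coverage, positions) {
  if (is(positions, "GRanges")) {
    stopifnot(all(GenomicRanges::width(positions) == 1L))
    out <- integer(length(positions))
    chroms <- .normChrom(GenomeInfoDb::seqnames(positions))
    covChrom <- .normChrom(GenomeInfoDb::seqnames(coverage))
    for (ch in unique(chroms)) {
      sel <- which(chroms == ch)
      sub <- coverage[covChrom == ch]
      ord <- order(.bedStart(sub))
      out[sel] <- .pointDepths1(.bedStart(sub)[ord], .bedEnd(sub)[ord],
                                as.integer(sub$depth)[ord],
                                .bedStart(positions)[sel])
    }
    return(out)
  }
  v <- .coverageVectors(coverage)
  .pointDepths1(v$s0, v$e0, v$d, as.integer(positions))
}

#' Length-weighted lower median depth
#'
#' The lower median of the virtual per-base depth multiset in which each
#' depth value is repeated `lengths` times, computed by a cumulative-weight
#' scan over depth-sorted entries -- the multiset is never expanded. With
#' total length T, the result is the element at rank `floor((T + 1) / 2)`,
#' an integer whenever the depths are integers (no interpolation).
#'
#' @param lengths positive integer run lengths (or base counts).
#' @param depths non-negative integer depth per run.
#' @return The weighted lower median depth.
#' @examples
#' weightedMedian(c(4, 6), c(1, 9))  # 10 virtual bases, lower median = 9
#' @export
weightedMedian <- function(lengths, depths) {
  stopifnot(length(lengths) == length(depths))
  if (!length(lengths) || sum(lengths) < 1) {
    stop("weightedMedian requires at least one base of coverage",
         call. = FALSE)
  }
  if (any(lengths <= 0)) stop("run lengths must be positive", call. = FALSE)
  ord <- order(depths)
  cum <- cumsum(as.numeric(lengths[ord]))
  total <- cum[length(cum)]
  rank <- (total + 1) %/% 2
  depths[ord][which(cum >= rank)[1L]]
}
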