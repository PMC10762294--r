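.defaultPalette <- c(germline = "red", somatic = "darkblue",
                     lowCoverage = "red", exonFill = "lightblue",
                     trace = "grey35", threshold = "black")

# Max-pool a per-base vector into bins so long gene spans stay drawable.
# Max-pooling never hides a sub-threshold dip -- a pooled bin is below the
# threshold only if every base in it is (the converse, a dip shown where
# none exists, cannot happen either since the pooled value is attained).
.maxPool <- function(depth, maxPoints = 200000L) {
  n <- length(depth)
  if (n <= maxPoints) {
    return(data.frame(offset = seq_len(n) - 1L, depth = depth))
  }
  bin <- ceiling(n / maxPoints)
  grp <- (seq_len(n) - 1L) %/% bin
  pooled <- as.integer(tapply(depth, grp, max))
  data.frame(offset = unique(grp) * bin, depth = pooled)
}

#' Build the figure specification for a gene coverage figure
#'
#' Assembles all semantic content of the two-panel figure as plain data:
#' upper panel depth trace over the gene span (max-pooled beyond 200 kb),
#' lower panel exon layout with per-exon x-ranges allocated proportionally
#' to exon length but never below a minimum visible width (so many-exon
#' genes stay legible), per-segment fill colors (flagged exons in the
#' low-coverage color), and SNV overlay dots at (locus, depth).
#'
#' @param report a [GeneCoverageReport-class].
#' @param profile the matching [geneProfile()] result.
#' @param palette named color overrides (names as in the default: germline,
#'   somatic, lowCoverage, exonFill, trace, threshold).
#' @param minExonFrac minimum lower-panel width of one exon, as a fraction
#'   of the total exon length.
#' @return A [GeneFigureSpec-class].
#' @export
geneFigureSpec <- function(report, profile, palette = character(0),
                           minExonFrac = 0.01) {
  stopifnot(is(report, "GeneCoverageReport"))
  if (!identical(report@gene, profile$gene)) {
    stop("report and profile describe different genes", call. = FALSE)
  }
  pal <- .defaultPalette
  pal[names(palette)] <- palette

  pooled <- .maxPool(profile$depth)
  upper <- data.frame(pos0 = report@spanStart0 + pooled$offset,
                      depth = pooled$depth)

  et <- report@exonTable
  totalLen <- sum(et$width)
  w <- pmax(et$width, minExonFrac * totalLen)
  gap <- 0.15 * mean(w)
  x1 <- cumsum(w + gap) - gap
  x0 <- x1 - w
  exonLayout <- data.frame(
    exonIndex = et$exonIndex, start0 = et$start0, end0 = et$end0,
    x0 = x0, x1 = x1, flagged = et$flagged,
    color = ifelse(et$flagged, pal[["lowCoverage"]], pal[["exonFill"]]),
    stringsAsFactors = FALSE)

  segRows <- lapply(seq_len(nrow(et)), function(i) {
    seg <- profile$exonSegments[[i]]
    if (!length(seg)) {
      return(NULL)
    }
    scale <- (x1[i] - x0[i]) / et$width[i]
    s0 <- .bedStart(seg)
    e0 <- .bedEnd(seg)
    data.frame(exonIndex = et$exonIndex[i], segStart0 = s0, segEnd0 = e0,
               depth = as.integer(seg$depth),
               x0 = x0[i] + (s0 - et$start0[i]) * scale,
               x1 = x0[i] + (e0 - et$start0[i]) * scale,
               color = exonLayout$color[i],
               stringsAsFactors = FALSE)
  })
  exonSegments <- do.call(rbind, c(segRows, list(
    data.frame(exonIndex = integer(0), segStart0 = integer(0),
               segEnd0 = integer(0), depth = integer(0), x0 = numeric(0),
               x1 = numeric(0), color = character(0),
               stringsAsFactors = FALSE))))

  st <- report@snvTable
  dots <- data.frame(variantClass = st$variantClass, pos0 = st$pos0,
                     depth = st$depth,
                     color = unname(pal[st$variantClass]),
                     stringsAsFactors = FALSE)

  new("GeneFigureSpec", gene = report@gene, threshold = report@threshold,
      spanStart0 = report@spanStart0, spanEnd0 = report@spanEnd0,
      upper = upper, exonLayout = exonLayout, exonSegments = exonSegments,
      dots = dots, palette = pal)
}

setMethod("show", "GeneFigureSpec", function(object) {
  cat(sprintf(
    "GeneFigureSpec for %s: %d upper-panel points, %d exons (%d red), %d SNV dots\n",
    object@gene, nrow(object@upper), nrow(object@exonLayout),
    sum(object@exonLayout$flagged), nrow(object@dots)))
})

#' Render the two-panel gene coverage figure
#'
#' Upper panel: depth over the whole gene span (exons and introns) against
#' the genomic coordinate, exon extents shaded, pathogenic germline (red)
#' and somatic (dark blue) SNV loci as dots at their reported depth, and
#' the coverage threshold as a horizontal line. Lower panel: per-exon depth
#' segments on the proportional exon layout, sub-threshold exons filled in
#' red, x-ticks labelled with the genomic start of each exon.
#'
#' @param report a [GeneCoverageReport-class].
#' @param profile the matching [geneProfile()] result.
#' @param outPath output PNG path.
#' @param spec optionally a pre-built [GeneFigureSpec-class] (otherwise
#'   built from `report` and `profile`).
#' @param width,height,res PNG device geometry.
#' @return The [GeneFigureSpec-class] rendered, invisibly.
#' @export
renderGeneFigure <- function(report, profile, outPath, spec = NULL,
                             width = 1400, height = 900, res = 110) {
  if (is.null(spec)) spec <- geneFigureSpec(report, profile)
  pal <- spec@palette
  yMax <- max(c(spec@upper$depth, spec@exonSegments$depth, spec@dots$depth,
                spec@threshold, 1L)) * 1.08
  grDevices::png(outPath, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2L, 1L), mar = c(4.2, 4.2, 2.5, 1.0))

  # upper panel: span-wide trace
  graphics::plot(NA, xlim = c(spec@spanStart0, spec@spanEnd0),
                 ylim = c(0, yMax), xlab = "genomic locus",
                 ylab = "depth of coverage",
                 main = sprintf("%s coverage (gene span)", spec@gene))
  for (i in seq_len(nrow(spec@exonLayout))) {
    graphics::rect(spec@exonLayout$start0[i], 0, spec@exonLayout$end0[i],
                   yMax, col = grDevices::adjustcolor(pal[["exonFill"]], 0.35),
                   border = NA)
  }
  graphics::lines(spec@upper$pos0, spec@upper$depth, col = pal[["trace"]],
                  lwd = 1.2)
  graphics::abline(h = spec@threshold, lty = 2, col = pal[["threshold"]])
  if (nrow(spec@dots)) {
    graphics::points(spec@dots$pos0, spec@dots$depth, pch = 19, cex = 0.8,
                     col = spec@dots$color)
  }

  # lower panel: exon-only layout
  xMax <- max(spec@exonLayout$x1)
  graphics::plot(NA, xlim = c(0, xMax), ylim = c(0, yMax),
                 xlab = "exon start locus", ylab = "depth of coverage",
                 main = sprintf("%s coverage (exons, threshold %dx)",
                                spec@gene, spec@threshold),
                 xaxt = "n")
  nE <- nrow(spec@exonLayout)
  lab <- seq_len(nE)
  showLab <- if (nE > 15L) unique(round(seq(1L, nE, length.out = 15L))) else lab
  graphics::axis(1, at = (spec@exonLayout$x0 + spec@exonLayout$x1)[showLab] / 2,
                 labels = formatC(spec@exonLayout$start0[showLab] + 1L,
                                  format = "d"),
                 las = 2, cex.axis = 0.7)
  for (i in seq_len(nrow(spec@exonSegments))) {
    graphics::rect(spec@exonSegments$x0[i], 0, spec@exonSegments$x1[i],
                   spec@exonSegments$depth[i],
                   col = spec@exonSegments$color[i], border = NA)
  }
  # outline uncovered exons too, so depth-0 exons remain visible
  for (i in seq_len(nE)) {
    graphics::rect(spec@exonLayout$x0[i], 0, spec@exonLayout$x1[i], yMax,
                   border = grDevices::adjustcolor("grey50", 0.5), lty = 3)
  }
  graphics::abline(h = spec@threshold, lty = 2, col = pal[["threshold"]])
  if (nrow(spec@dots)) {
    # place dots at their exon-layout x where the locus falls in an exon
    el <- spec@exonLayout
    for (j in seq_len(nrow(spec@dots))) {
      p <- spec@dots$pos0[j]
      i <- which(el$start0 <= p & p < el$end0)
      if (length(i) == 1L) {
        x <- el$x0[i] + (p - el$start0[i]) / (el$end0[i] - el$start0[i]) *
          (el$x1[i] - el$x0[i])
        graphics::points(x, spec@dots$depth[j], pch = 19, cex = 0.8,
                         col = spec@dots$color[j])
      }
    }
  }
  invisible(spec)
}
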