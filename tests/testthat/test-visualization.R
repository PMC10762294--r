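fixtureReport <- function(spec, genes = "G1", threshold = 15) {
  fx <- makeFixture(spec, tempfile("fxviz"))
  cov <- readCoverageBed(fx$paths$coverage)
  ex <- readExonReference(fx$paths$exons)
  reps <- runGeneCoverage(fx$paths$coverage, fx$paths$exons,
                          fx$paths$germline, fx$paths$somatic, threshold,
                          genes)
  list(fx = fx, reports = reps,
       profiles = lapply(genes, function(g)
         geneProfile(readCoverageBed(fx$paths$coverage,
                                     chrom = reps[[g]]@chrom),
                     exonsForGene(ex, g))))
}

test_that("figure spec places every SNV dot at its reported depth", {
  r <- fixtureReport(standardFixtureSpec(depthPoisson(20), seed = 5))
  spec <- geneFigureSpec(r$reports$G1, r$profiles[[1L]])
  st <- snvDepths(r$reports$G1)
  expect_equal(nrow(spec@dots), nrow(st))
  expect_equal(spec@dots$depth, st$depth)
  expect_equal(spec@dots$pos0, st$pos0)
  expect_equal(spec@dots$color[spec@dots$variantClass == "germline"][1],
               "red")
  expect_true(all(spec@dots$color[spec@dots$variantClass == "somatic"] ==
                    "darkblue"))
})

test_that("exactly the flagged exons are drawn in red", {
  dir <- tempfile("fxflag")
  spec <- fixtureSpec(
    chromLengths = c(chr1 = 2000),
    depthModel = depthPiecewise(data.frame(
      chrom = "1", start0 = c(0, 1000), end0 = c(1000, 2000),
      depth = c(10, 30))),
    genes = data.frame(gene = "G1", chrom = "1",
                       start0 = c(100, 1200), end0 = c(300, 1400)),
    snvs = data.frame(chrom = "1", pos0 = 1250, variantClass = "somatic"),
    threshold = 15, seed = 4)
  fx <- makeFixture(spec, dir)
  ex <- readExonReference(fx$paths$exons)
  rep <- runGeneCoverage(fx$paths$coverage, fx$paths$exons,
                         fx$paths$germline, fx$paths$somatic, 15, "G1")$G1
  pr <- geneProfile(readCoverageBed(fx$paths$coverage, chrom = "1"),
                    exonsForGene(ex, "G1"))
  fs <- geneFigureSpec(rep, pr)
  expect_equal(sum(fs@exonLayout$color == "red"), 1L)
  expect_equal(fs@exonLayout$flagged, exonStats(rep)$flagged)
  expect_true(all(fs@exonSegments$color[fs@exonSegments$exonIndex == 1L] ==
                    "red"))
  expect_true(all(fs@exonSegments$color[fs@exonSegments$exonIndex == 2L] ==
                    "lightblue"))
  # palette override propagates
  fs2 <- geneFigureSpec(rep, pr, palette = c(lowCoverage = "orange"))
  expect_equal(sum(fs2@exonLayout$color == "orange"), 1L)
})

test_that("a 27-exon gene keeps every exon visible in the lower panel", {
  s0 <- seq(1000L, by = 3000L, length.out = 27L)
  w <- rep(c(80L, 2000L), length.out = 27L)  # mix tiny and large exons
  dir <- tempfile("fx27")
  spec <- fixtureSpec(
    chromLengths = c(chr7 = 100000),
    depthModel = depthConstant(25),
    genes = data.frame(gene = "CFTRlike", chrom = "7", start0 = s0,
                       end0 = s0 + w),
    snvs = data.frame(chrom = "7", pos0 = c(1005, 4010),
                      variantClass = c("germline", "somatic")),
    threshold = 15, seed = 6)
  fx <- makeFixture(spec, dir)
  ex <- readExonReference(fx$paths$exons)
  rep <- runGeneCoverage(fx$paths$coverage, fx$paths$exons,
                         fx$paths$germline, fx$paths$somatic, 15,
                         "CFTRlike")$CFTRlike
  pr <- geneProfile(readCoverageBed(fx$paths$coverage, chrom = "7"),
                    exonsForGene(ex, "CFTRlike"))
  fs <- geneFigureSpec(rep, pr)
  expect_equal(nrow(fs@exonLayout), 27L)
  expect_equal(fs@exonLayout$exonIndex, 1:27)
  # every exon, however small, gets at least the minimum visible width
  widths <- fs@exonLayout$x1 - fs@exonLayout$x0
  expect_true(all(widths >= 0.01 * sum(exonStats(rep)$width) - 1e-9))
  expect_true(all(diff(fs@exonLayout$x0) > 0))
})

test_that("very long spans are max-pooled without hiding sub-threshold dips", {
  depth <- rep(50L, 500000L)
  depth[250000L] <- 3L  # one-base dip
  pooled <- ClinCoverage:::.maxPool(depth, maxPoints = 1000L)
  expect_lte(nrow(pooled), 1000L)
  expect_equal(max(pooled$depth), 50L)
  # the pooled trace still contains a bin whose maximum is the dip only if
  # the dip fills its bin; with max-pooling a lone dip inside a high bin is
  # absorbed upward, never creating a spurious sub-threshold bin
  expect_true(all(pooled$depth %in% c(3L, 50L)))
})

test_that("rendering writes a non-empty PNG for a one-exon gene", {
  r <- fixtureReport(standardFixtureSpec())
  out <- tempfile(fileext = ".png")
  spec <- renderGeneFigure(r$reports$G1, r$profiles[[1L]], out)
  expect_s4_class(spec, "GeneFigureSpec")
  expect_true(file.exists(out))
  expect_gt(file.size(out), 1000)
})
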