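# In-code exon reference + coverage for direct engine-level tests.
exonGR <- function(gene, chrom, s0, e0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0),
                         gene = gene, exonIndex = seq_along(s0))
}

test_that("geneProfile rasterizes the span with intronic gaps at depth 0", {
  ex <- exonGR("G1", "1", 100L, 110L)
  cov <- covGR("1", 100L, 110L, 5L)
  pr <- geneProfile(cov, ex)
  expect_equal(pr$depth, rep(5L, 10L))
  expect_equal(GenomicRanges::start(pr$exonSegments[[1L]]) - 1L, 100L)

  ex2 <- exonGR("G1", "1", c(100L, 200L), c(110L, 210L))
  cov2 <- covGR("1", c(100L, 200L), c(110L, 210L), c(5L, 9L))
  pr2 <- geneProfile(cov2, ex2)
  expect_equal(length(pr2$depth), 110L)
  expect_equal(pr2$depth[11:100], rep(0L, 90L))  # intron uncovered
  expect_equal(pr2$depth[101:110], rep(9L, 10L))
})

test_that("geneProfile span vector matches the rasterization oracle", {
  set.seed(808)
  for (rep in 1:20) {
    cov <- randomCoverage(40L, limit = 3000L)
    gr <- covGR("1", cov$s0, cov$e0, cov$d)
    bounds <- sort(sample.int(2999L, 4L))
    ex <- exonGR("GX", "1", bounds[c(1L, 3L)], bounds[c(2L, 4L)])
    pr <- geneProfile(gr, ex)
    expect_equal(pr$depth,
                 rasterizeDepth(cov$s0, cov$e0, cov$d, bounds[1L], bounds[4L]))
  }
})

test_that("flagExons flags any exon with a base strictly below threshold", {
  ex <- exonGR("G", "1", c(0L, 100L, 200L), c(10L, 110L, 210L))
  cov <- covGR("1", c(0L, 100L, 200L), c(9L, 110L, 210L), c(20L, 14L, 20L))
  pr <- geneProfile(cov, ex)
  tab <- flagExons(pr$exonSegments, ex, 15L)
  # exon 1: base 9 uncovered (depth 0) -> flagged despite depth 20 elsewhere
  expect_equal(tab$flagged, c(TRUE, TRUE, FALSE))
  expect_equal(tab$minDepth, c(0L, 14L, 20L))
  tabLow <- flagExons(pr$exonSegments, ex, 20L)
  expect_equal(tabLow$flagged, c(TRUE, TRUE, FALSE))  # min 20 is not < 20
})

test_that("runGeneCoverage summarizes a constant-depth fixture", {
  fx <- makeFixture(standardFixtureSpec(depthConstant(20), threshold = 15),
                    tempfile("fxgene"))
  reps <- runGeneCoverage(fx$paths$coverage, fx$paths$exons,
                          fx$paths$germline, fx$paths$somatic, 15,
                          c("G1", "G2"))
  for (g in c("G1", "G2")) {
    r <- reps[[g]]
    expect_s4_class(r, "GeneCoverageReport")
    expect_false(any(exonStats(r)$flagged))
    fr <- coveredFraction(r)
    expect_true(all(fr[!is.na(fr)] == 1))
    expect_true(all(snvDepths(r)$depth == 20L))
  }
  # threshold above the constant depth flips everything
  reps25 <- runGeneCoverage(fx$paths$coverage, fx$paths$exons,
                            fx$paths$germline, fx$paths$somatic, 25, "G1")
  expect_true(all(exonStats(reps25$G1)$flagged))
  fr <- coveredFraction(reps25$G1)
  expect_true(all(fr[!is.na(fr)] == 0))
})

test_that("per-class fractions use hand-countable in-span depths", {
  dir <- tempfile("fxfrac")
  spec <- fixtureSpec(
    chromLengths = c(chr1 = 2000),
    depthModel = depthPiecewise(data.frame(
      chrom = "1", start0 = c(0, 1000), end0 = c(1000, 2000),
      depth = c(10, 20))),
    genes = data.frame(gene = "G1", chrom = "1", start0 = c(500, 1400),
                       end0 = c(700, 1600)),
    snvs = data.frame(chrom = "1", pos0 = c(600, 1500),
                      variantClass = "germline"),
    threshold = 15, seed = 2)
  fx <- makeFixture(spec, dir)
  r <- runGeneCoverage(fx$paths$coverage, fx$paths$exons, fx$paths$germline,
                       fx$paths$somatic, 15, "G1")$G1
  expect_equal(coveredFraction(r)[["germline"]], 0.5)  # depths {10, 20}
  # no somatic loci in span: not applicable, not zero
  expect_true(is.na(coveredFraction(r)[["somatic"]]))
})

test_that("span membership, not exon membership, decides SNV inclusion", {
  dir <- tempfile("fxintron")
  spec <- fixtureSpec(
    chromLengths = c(chr1 = 2000),
    depthModel = depthConstant(30),
    genes = data.frame(gene = "G1", chrom = "1", start0 = c(100, 900),
                       end0 = c(200, 1000)),
    snvs = data.frame(chrom = "1", pos0 = c(150, 500, 1500),
                      variantClass = "germline"),
    threshold = 15, seed = 2)
  fx <- makeFixture(spec, dir)
  r <- runGeneCoverage(fx$paths$coverage, fx$paths$exons, fx$paths$germline,
                       fx$paths$somatic, 15, "G1")$G1
  # 150 (exonic) and 500 (intronic, inside span) included; 1500 outside
  expect_equal(sort(snvDepths(r)$pos0), c(150L, 500L))
  cov <- readCoverageBed(fx$paths$coverage, chrom = "1")
  expect_equal(snvDepths(r)$depth, pointDepths(cov, snvDepths(r)$pos0))
})

test_that("multi-gene runs equal single-gene runs per gene", {
  fx <- makeFixture(standardFixtureSpec(depthPoisson(18), seed = 31),
                    tempfile("fxmulti"))
  both <- runGeneCoverage(fx$paths$coverage, fx$paths$exons,
                          fx$paths$germline, fx$paths$somatic, 15,
                          c("G1", "G2"))
  for (g in c("G1", "G2")) {
    single <- runGeneCoverage(fx$paths$coverage, fx$paths$exons,
                              fx$paths$germline, fx$paths$somatic, 15, g)[[g]]
    expect_equal(exonStats(both[[g]]), exonStats(single))
    expect_equal(snvDepths(both[[g]]), snvDepths(single))
    expect_equal(coveredFraction(both[[g]]), coveredFraction(single))
  }
})

test_that("unknown genes fail with near-match suggestions", {
  fx <- makeFixture(standardFixtureSpec(), tempfile("fxunknown"))
  expect_error(runGeneCoverage(fx$paths$coverage, fx$paths$exons,
                               fx$paths$germline, fx$paths$somatic, 15,
                               "G11"),
               "G11.*not found.*G1")
})

test_that("gene reports and figures are written per gene", {
  fx <- makeFixture(standardFixtureSpec(), tempfile("fxout"))
  out <- tempfile("geneout")
  runGeneCoverage(fx$paths$coverage, fx$paths$exons, fx$paths$germline,
                  fx$paths$somatic, 15, c("G1", "G2"), outDir = out)
  for (g in c("G1", "G2")) {
    tsv <- file.path(out, sprintf("coverage_%s.tsv", g))
    png <- file.path(out, sprintf("coverage_%s.png", g))
    expect_true(file.exists(tsv))
    expect_true(file.size(png) > 0)
    expect_true(any(grepl("^exon_index", readLines(tsv))))
  }
})
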