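test_that("computeCDC balances loci above and below the reported depth", {
  expect_equal(cdc(computeCDC(rep(7L, 5L))), 7L)
  expect_equal(cdc(computeCDC(c(10L, 20L, 30L))), 20L)   # brute scan over 1..31
  # |sign sum| is 0 for every m in 6..49; smallest-m tie-break picks 6
  expect_equal(cdc(computeCDC(c(5L, 5L, 50L, 50L))), 6L)
  expect_equal(cdc(computeCDC(c(0L, 0L))), 1L)           # uncovered loci
  expect_error(computeCDC(integer(0)), "no variants")
  res <- computeCDC(c(10L, 20L, 30L), "somatic")
  expect_s4_class(res, "CDCResult")
  expect_equal(variantClass(res), "somatic")
  expect_equal(nVariants(res), 3L)
  expect_equal(cdcSpread(res), sd(c(10, 20, 30)))
})

test_that("computeCDC equals exhaustive minimization on random multisets", {
  set.seed(515)
  for (rep in 1:200) {
    d <- sample.int(301L, sample.int(200L, 1L), replace = TRUE) - 1L
    expect_equal(cdc(computeCDC(d)), bruteForceCDC(d))
  }
})

test_that("for odd N with a unique middle value the CDC is the median", {
  set.seed(616)
  for (rep in 1:100) {
    n <- 2L * sample.int(40L, 1L) + 1L
    d <- sample.int(500L, n)  # distinct values => unique middle
    expect_equal(cdc(computeCDC(d)), as.integer(stats::median(d)))
  }
})

test_that("fractionAbove counts inclusively and decreases with threshold", {
  expect_equal(fractionAbove(c(10L, 20L, 30L), 15L), 2 / 3)
  expect_equal(fractionAbove(c(0L, 0L), 1L), 0)
  expect_equal(fractionAbove(15L, 15L), 1)
  expect_error(fractionAbove(integer(0), 1L), "empty")
  set.seed(717)
  d <- rpois(200L, 20)
  fr <- vapply(1:60, function(t) fractionAbove(d, t), numeric(1L))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[1L], mean(d > 0))
})

test_that("runSnvScore reproduces a constant-coverage fixture exactly", {
  fx <- makeFixture(standardFixtureSpec(depthConstant(20), threshold = 15),
                    tempfile("fxconst"))
  rep <- runSnvScore(fx$paths$coverage, fx$paths$germline, fx$paths$somatic,
                     threshold = 15)
  expect_equal(unname(cdc(rep)), c(20L, 20L))
  expect_equal(unname(coveredFraction(rep)), c(1, 1))
  expect_equal(sampleMedian(rep), 20L)
  # per-chromosome counts sum to the class totals
  pc <- perChromosomeStats(rep)
  expect_equal(sum(pc$germline_n), nVariants(rep)[["germline"]])
  expect_equal(sum(pc$somatic_n), nVariants(rep)[["somatic"]])
})

test_that("runSnvScore recovers engineered per-class depth multisets", {
  dir <- tempfile("fxpiece")
  spec <- fixtureSpec(
    chromLengths = c(chr1 = 3000),
    depthModel = depthPiecewise(data.frame(
      chrom = "1", start0 = c(0, 1000, 2000), end0 = c(1000, 2000, 3000),
      depth = c(5, 50, 7))),
    snvs = data.frame(chrom = "1",
                      pos0 = c(100, 200, 1100, 1200, 2100, 2200, 2300),
                      variantClass = c(rep("germline", 4), rep("somatic", 3))),
    threshold = 15, seed = 1)
  fx <- makeFixture(spec, dir)
  rep <- runSnvScore(fx$paths$coverage, fx$paths$germline, fx$paths$somatic,
                     threshold = 15)
  expect_equal(unname(cdc(rep)), c(6L, 7L))   # {5,5,50,50} -> 6; {7,7,7} -> 7
  expect_equal(unname(coveredFraction(rep)), c(0.5, 0))
  expect_equal(sort(snvDepths(rep)$depth[snvDepths(rep)$variantClass ==
                                           "germline"]),
               c(5L, 5L, 50L, 50L))
})

test_that("SNVs on chromosomes absent from the BED score depth 0 with a warning", {
  bed <- writeBed("chr1\t0\t100\t30")
  header <- "Name\tGene(s)\tGRCh38Chromosome\tGRCh38Location\tClinicalSignificance"
  germ <- writeBed(c(header, "v1\tG\t1\t50\tPathogenic",
                     "v2\tG\t9\t10\tPathogenic"), ext = ".txt")
  som <- writeBed(c(header, "v3\tG\t1\t60\tPathogenic"), ext = ".txt")
  expect_warning(rep <- runSnvScore(bed, germ, som, threshold = 15),
                 "absent from the coverage BED")
  d <- snvDepths(rep)
  expect_equal(d$depth[d$chrom == "9"], 0L)
  expect_equal(unname(coveredFraction(rep)), c(0.5, 1))
})

test_that("chunked streaming yields byte-identical reports to one big read", {
  fx <- makeFixture(standardFixtureSpec(depthPoisson(20), threshold = 15,
                                        seed = 23),
                    tempfile("fxstream"))
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  r1 <- runSnvScore(fx$paths$coverage, fx$paths$germline, fx$paths$somatic,
                    threshold = 15, chunkLines = 17L)
  r2 <- runSnvScore(fx$paths$coverage, fx$paths$germline, fx$paths$somatic,
                    threshold = 15, chunkLines = 10000000L)
  writeSnvScoreReport(r1, p1)
  writeSnvScoreReport(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(cdc(r1), cdc(r2))
  expect_equal(sampleMedian(r1), sampleMedian(r2))
})

test_that("report writing is deterministic and parseable", {
  fx <- makeFixture(standardFixtureSpec(), tempfile("fxdet"))
  out <- tempfile()
  rep <- runSnvScore(fx$paths$coverage, fx$paths$germline, fx$paths$somatic,
                     threshold = 15, outDir = out)
  path <- file.path(out, "coverage_snvScore.tsv")
  expect_true(file.exists(path))
  lines <- readLines(path)
  expect_true(any(grepl("^# germline CDC", lines)))
  tab <- read.delim(text = lines[!startsWith(lines, "#")])
  expect_equal(nrow(tab), nrow(perChromosomeStats(rep)))
})
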