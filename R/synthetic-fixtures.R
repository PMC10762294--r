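# Synthetic fixture generation: coverage BEDs, exon references and
# ClinVar-style SNV tables with analytically known ground truth, so every
# pipeline stage is testable without external downloads.

#' Depth models for synthetic fixtures
#'
#' `depthConstant(value)`: every base of every chromosome at `value`.
#' `depthPiecewise(segments)`: explicit constant-depth segments
#' (data.frame `chrom, start0, end0, depth`, 0-based half-open,
#' non-overlapping); bases outside any segment have depth 0.
#' `depthPoisson(lambda)`: i.i.d. Poisson(`lambda`) depth per base, drawn
#' under the fixture seed.
#'
#' @param value,lambda model parameters.
#' @param segments segment data.frame for the piecewise model.
#' @return A depth-model description for [fixtureSpec()].
#' @name depthModels
NULL

#' @rdname depthModels
#' @export
depthConstant <- function(value) {
  list(type = "constant", value = .assertCount(value, "value", positive = FALSE))
}

#' @rdname depthModels
#' @export
depthPiecewise <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start0", "end0", "depth") %in% names(segments)))
  list(type = "piecewise", segments = segments)
}

#' @rdname depthModels
#' @export
depthPoisson <- function(lambda) {
  stopifnot(length(lambda) == 1L, lambda > 0)
  list(type = "poisson", lambda = lambda)
}

#' Describe a synthetic coverage fixture
#'
#' Declares chromosome lengths, a depth model, gene/exon layouts, pathogenic
#' SNV placements for each variant class, the coverage threshold the ground
#' truth is evaluated at, and a seed that makes generation deterministic.
#' SNV loci are given either explicitly (`snvs`: data.frame
#' `chrom, pos0, variantClass`) or as counts to place uniformly at random in
#' exons / introns of the declared genes (`placement`: named list with any
#' of `germlineExon`, `germlineIntron`, `somaticExon`, `somaticIntron`).
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param depthModel one of [depthConstant()], [depthPiecewise()],
#'   [depthPoisson()].
#' @param genes data.frame `gene, chrom, start0, end0`, one row per declared
#'   exon (overlapping exons of one gene are merged with a warning).
#' @param snvs optional explicit SNV placement data.frame.
#' @param placement optional random-placement counts (see above).
#' @param threshold positive integer threshold for the ground truth.
#' @param seed integer seed for all randomness in generation.
#' @return A validated fixture specification (list, class `"fixtureSpec"`).
#' @export
fixtureSpec <- function(chromLengths, depthModel, genes = NULL, snvs = NULL,
                        placement = NULL, threshold = 15L, seed = 1L) {
  stopifnot(is.numeric(chromLengths), !is.null(names(chromLengths)),
            all(chromLengths >= 1))
  names(chromLengths) <- .normChrom(names(chromLengths))
  if (!is.null(genes)) {
    stopifnot(is.data.frame(genes),
              all(c("gene", "chrom", "start0", "end0") %in% names(genes)))
    genes$chrom <- .normChrom(genes$chrom)
    stopifnot(all(genes$chrom %in% names(chromLengths)),
              all(genes$end0 <= chromLengths[genes$chrom]),
              all(genes$start0 >= 0), all(genes$start0 < genes$end0))
  }
  if (!is.null(snvs)) {
    stopifnot(is.data.frame(snvs),
              all(c("chrom", "pos0", "variantClass") %in% names(snvs)))
    snvs$chrom <- .normChrom(snvs$chrom)
    stopifnot(all(snvs$chrom %in% names(chromLengths)),
              all(snvs$pos0 >= 0),
              all(snvs$pos0 < chromLengths[snvs$chrom]),
              all(snvs$variantClass %in% c("germline", "somatic")))
  }
  if (!is.null(placement)) {
    stopifnot(is.list(placement),
              all(names(placement) %in% c("germlineExon", "germlineIntron",
                                          "somaticExon", "somaticIntron")),
              !is.null(genes))
  }
  structure(list(chromLengths = chromLengths, depthModel = depthModel,
                 genes = genes, snvs = snvs, placement = placement,
                 threshold = .assertCount(threshold, "threshold"),
                 seed = as.integer(seed)),
            class = "fixtureSpec")
}

# Per-base depth vector of one chromosome, straight from the model spec --
# the fixture's source of truth, independent of the readers and the engine.
.modelPerBase <- function(model, chrom, len) {
  switch(model$type,
    constant = rep(model$value, len),
    piecewise = {
      v <- integer(len)
      seg <- model$segments[.normChrom(model$segments$chrom) == chrom, ,
                            drop = FALSE]
      for (i in seq_len(nrow(seg))) {
        v[(seg$start0[i] + 1L):seg$end0[i]] <- seg$depth[i]
      }
      v
    },
    poisson = stats::rpois(len, model$lambda),
    stop("unknown depth model type"))
}

# Independent re-derivation of the CDC definition for ground truth: explicit
# scan of the absolute sign-sum over the full grid.
.bruteCDC <- function(d) {
  grid <- seq_len(max(d) + 1L)
  score <- vapply(grid, function(m) abs(sum(sign(d - m))), numeric(1L))
  grid[which.min(score)]
}

.exonBaseSet <- function(genes, gene) {
  g <- genes[genes$gene == gene, , drop = FALSE]
  unique(unlist(lapply(seq_len(nrow(g)),
                       function(i) g$start0[i]:(g$end0[i] - 1L))))
}

#' Generate a synthetic fixture with ground truth
#'
#' Writes a per-base coverage BED (consecutive equal-depth bases merged into
#' runs, matching real depth-tool output), an exon reference BED, two
#' ClinVar-style SNV tables, and a JSON ground-truth record holding the
#' analytically known CDC per class, covered fractions, sample median,
#' per-gene flagged exons and per-SNV depths implied by the spec. The
#' coverage BED uses "chr"-prefixed labels while the SNV tables do not,
#' deliberately exercising label normalization.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return List with `paths` (coverage, exons, germline, somatic, truth) and
#'   `truth` (the ground-truth record as an R list).
#' @export
makeFixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(spec$seed)

  chroms <- names(spec$chromLengths)
  perBase <- lapply(chroms, function(ch)
    .modelPerBase(spec$depthModel, ch, spec$chromLengths[[ch]]))
  names(perBase) <- chroms

  # coverage BED: run-length encoded per-base depths, chr-prefixed labels
  covLines <- unlist(lapply(chroms, function(ch) {
    r <- rle(perBase[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    sprintf("chr%s\t%d\t%d\t%d", ch, s, e, r$values)
  }))
  covPath <- file.path(dir, "coverage.bed")
  writeLines(covLines, covPath)

  # exon reference (merge overlapping declared exons per gene, warn)
  genes <- spec$genes
  exonPath <- NULL
  if (!is.null(genes)) {
    merged <- list()
    for (g in unique(genes$gene)) {
      rows <- genes[genes$gene == g, , drop = FALSE]
      ir <- IRanges::IRanges(rows$start0 + 1L, rows$end0)
      red <- IRanges::reduce(ir)
      if (length(red) < nrow(rows)) {
        warning(sprintf(
          "fixture gene '%s': overlapping declared exons merged", g),
          call. = FALSE)
      }
      merged[[g]] <- data.frame(gene = g, chrom = rows$chrom[1L],
                                start0 = IRanges::start(red) - 1L,
                                end0 = IRanges::end(red))
    }
    genes <- do.call(rbind, merged)
    rownames(genes) <- NULL
    exonPath <- file.path(dir, "exons.bed")
    writeLines(sprintf("chr%s\t%d\t%d\t%s", genes$chrom, genes$start0,
                       genes$end0, genes$gene), exonPath)
  }

  # SNV placements
  snvs <- spec$snvs
  if (!is.null(spec$placement)) {
    place <- function(class, where, n) {
      if (is.null(n) || n < 1L) return(NULL)
      pool <- unlist(lapply(unique(genes$gene), function(g) {
        ex <- .exonBaseSet(genes, g)
        if (where == "exon") {
          ex
        } else {
          gSpan <- range(c(genes$start0[genes$gene == g],
                           genes$end0[genes$gene == g]))
          setdiff(gSpan[1L]:(gSpan[2L] - 1L), ex)
        }
      }))
      # pool positions are genomic offsets; recover chromosome by span lookup
      pos <- sample(pool, n, replace = TRUE)
      ch <- vapply(pos, function(p) {
        hit <- genes$chrom[genes$start0 <= p & p < genes$end0]
        if (length(hit)) hit[1L] else {
          # intronic: find the gene span containing p
          for (g in unique(genes$gene)) {
            sp <- range(c(genes$start0[genes$gene == g],
                          genes$end0[genes$gene == g]))
            if (sp[1L] <= p && p < sp[2L])
              return(genes$chrom[genes$gene == g][1L])
          }
          chroms[1L]
        }
      }, character(1L))
      data.frame(chrom = ch, pos0 = pos, variantClass = class,
                 stringsAsFactors = FALSE)
    }
    snvs <- rbind(snvs,
                  place("germline", "exon", spec$placement$germlineExon),
                  place("germline", "intron", spec$placement$germlineIntron),
                  place("somatic", "exon", spec$placement$somaticExon),
                  place("somatic", "intron", spec$placement$somaticIntron))
  }
  if (is.null(snvs) || !nrow(snvs)) {
    stop("fixture spec declares no SNVs (explicit or placed)", call. = FALSE)
  }
  rownames(snvs) <- NULL

  geneOf <- function(ch, p) {
    if (is.null(genes)) return("")
    for (g in unique(genes$gene)) {
      rows <- genes[genes$gene == g, , drop = FALSE]
      if (rows$chrom[1L] == ch) {
        sp <- range(c(rows$start0, rows$end0))
        if (sp[1L] <= p && p < sp[2L]) return(g)
      }
    }
    ""
  }
  snvs$gene <- mapply(geneOf, snvs$chrom, snvs$pos0)
  snvs$depth <- mapply(function(ch, p) perBase[[ch]][p + 1L],
                       snvs$chrom, snvs$pos0)

  writeTable <- function(sub, path) {
    header <- paste(c("Name", "Gene(s)", "GRCh38Chromosome",
                      "GRCh38Location", "ClinicalSignificance"),
                    collapse = "\t")
    lines <- sprintf("synthetic_snv_%d\t%s\t%s\t%d\tPathogenic",
                     seq_len(nrow(sub)), sub$gene, sub$chrom, sub$pos0 + 1L)
    writeLines(c(header, lines), path)
    path
  }
  germPath <- writeTable(snvs[snvs$variantClass == "germline", , drop = FALSE],
                         file.path(dir, "snv_germline_synthetic.txt"))
  somPath <- writeTable(snvs[snvs$variantClass == "somatic", , drop = FALSE],
                        file.path(dir, "snv_somatic_synthetic.txt"))

  # ---- ground truth, straight from the per-base model ----
  th <- spec$threshold
  classTruth <- function(class) {
    d <- snvs$depth[snvs$variantClass == class]
    if (!length(d)) return(NULL)
    list(cdc = .bruteCDC(d), fraction = mean(d >= th), n = length(d),
         sd = if (length(d) > 1L) stats::sd(d) else 0)
  }
  allBases <- unlist(perBase, use.names = FALSE)
  sorted <- sort(allBases)
  medTruth <- sorted[(length(sorted) + 1) %/% 2]

  geneTruth <- NULL
  if (!is.null(genes)) {
    geneTruth <- lapply(unique(genes$gene), function(g) {
      rows <- genes[genes$gene == g, , drop = FALSE]
      rows <- rows[order(rows$start0), , drop = FALSE]
      ch <- rows$chrom[1L]
      exonStats <- lapply(seq_len(nrow(rows)), function(i) {
        v <- perBase[[ch]][(rows$start0[i] + 1L):rows$end0[i]]
        list(exonIndex = i, minDepth = min(v), meanDepth = mean(v),
             flagged = min(v) < th)
      })
      sp <- c(min(rows$start0), max(rows$end0))
      inSpan <- snvs$chrom == ch & snvs$pos0 >= sp[1L] & snvs$pos0 < sp[2L]
      frac <- vapply(c("germline", "somatic"), function(cls) {
        d <- snvs$depth[inSpan & snvs$variantClass == cls]
        if (!length(d)) NA_real_ else mean(d >= th)
      }, numeric(1L))
      list(gene = g, chrom = ch, span = sp,
           flaggedExons = which(vapply(exonStats, `[[`, TRUE, "flagged")),
           exonStats = exonStats,
           germlineFraction = frac[["germline"]],
           somaticFraction = frac[["somatic"]])
    })
    names(geneTruth) <- unique(genes$gene)
  }

  truth <- list(threshold = th,
                sampleMedian = medTruth,
                germline = classTruth("germline"),
                somatic = classTruth("somatic"),
                genes = geneTruth,
                snvs = snvs)
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  list(paths = list(coverage = covPath, exons = exonPath,
                    germline = germPath, somatic = somPath,
                    truth = truthPath),
       truth = truth)
}
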