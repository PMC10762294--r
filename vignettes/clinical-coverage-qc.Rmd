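---
title: "Clinical depth-of-coverage QC: model, parameters and design"
author: "ClinCoverage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical depth-of-coverage QC: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClinCoverage)
```

## The problem

A sequencing sample destined for clinical interpretation must be deep
enough *where it matters*: at loci known to carry pathogenic
single-nucleotide variants, and across the exons of the genes under
investigation. Genome-wide averages hide local failures — a 30× genome can
still leave a BRCA1 exon at 4×. ClinCoverage evaluates a sample's per-base
coverage profile against two clinically anchored target sets: ClinVar-style
tables of pathogenic germline and somatic SNV loci, and a merged-exon gene
reference.

## The model

### Clinical Depth Coverage

Let the class *t* ∈ {germline, somatic} have loci with depths
*C(v₁), …, C(v_N)*. The sign-sum

s(m) = Σᵢ sgn(C(vᵢ) − m), with sgn(0) = 0,

counts loci deeper than *m* minus loci shallower. As a function of *m* it
is non-increasing, so its raw minimum over ℕ⁺ is unbounded below in *m*;
the meaningful balance point is where |s(m)| is smallest. We therefore
define

CDC(t) = min { m ∈ {1, …, max C + 1} : |s(m)| is minimal },

the smallest depth at which loci above and below balance. Two properties
anchor the definition:

* for odd *N* with a unique middle value, CDC equals the sample median of
  the depths (the suite verifies this on random multisets);
* when |s(m)| = 0 on a whole interval — e.g. depths {5, 5, 50, 50}, where
  every m in 6..49 balances — the smallest m is reported. This tie-break is
  deterministic and conservative: a bimodal depth profile yields a low CDC
  rather than an optimistic midpoint, and the reported dispersion (the
  sample standard deviation of the depth multiset, printed as the "+/-"
  companion) flags the spread.

Uncovered loci participate with depth 0. This is a deliberate modelling
choice, not a fallback: a pathogenic locus absent from the coverage record
is the most serious failure the report can surface, so it must depress the
CDC and the covered fractions.

### Covered fractions and the sample median

The per-class *covered fraction* is the proportion of loci with depth ≥ a
user threshold; "covered" is inclusive (a locus at exactly 15× passes a 15×
threshold). The *sample coverage median* is the length-weighted lower
median over every base in the coverage BED, computed from a depth histogram
by a cumulative-weight scan — the per-base multiset (gigabases for a real
genome) is never expanded, and the lower median keeps the statistic an
integer like the depths themselves.

### Per-gene evaluation

A gene is the union of its isoforms' exons: overlapping or book-ended exon
rows are merged per gene and numbered 1..k. The *gene span* runs from the
first merged exon's start to the last merged exon's end, introns included.
An exon is flagged when its *minimum* per-base depth (gaps count as 0)
falls strictly below the threshold — one under-covered base can hide a
variant, so the minimum, not the mean, drives the flag; the mean is
reported next to it for human judgment. SNV loci are attached to a gene by
span membership (coordinates), not by the gene-symbol string in the
ClinVar table: symbol fields in ClinVar exports are multi-valued and
inconsistent, while coordinates are unambiguous. Consequently intronic
pathogenic loci inside the span are counted and drawn; a class with no loci
in the span reports "not applicable" rather than 0.

## Coordinates and labels

Coverage and exon BEDs are 0-based half-open (the BED standard and the
output convention of depth tools); ClinVar positions are 1-based and
converted on read. Rows whose position field is empty, non-numeric, or a
two-number range (not a single-nucleotide locus) are skipped and counted.
Chromosome labels are compared after stripping an optional `chr` prefix,
because per-base BEDs and ClinVar exports disagree on this dialect.
Internally all intervals are `GRanges` (1-based closed); the conversion
happens once at each I/O boundary.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `threshold` | minimum depth (×) for "covered" loci and unflagged exons | 15 in examples; 1 when omitted from `snvScore`-style calls | 15× is the common clinical screening bar; the whole-sample score treats "covered at all" as the weakest meaningful question when no threshold is given |
| `chunkLines` | coverage rows read per streaming chunk | 200 000 | bounds memory at roughly a few MB per chunk regardless of file size; any value gives byte-identical reports |
| `columns` | ClinVar column map | `GRCh38Chromosome`, `GRCh38Location`, `Gene(s)` | the ClinVar web-export dialect; other exports differ, so the map is configuration rather than a constant |
| `minExonFrac` | minimum lower-panel width of an exon | 0.01 of total exon length | keeps 80 bp exons visible next to 2 kb ones in many-exon genes |

## Streaming

`runSnvScore` makes a single pass over the coverage BED in bounded chunks,
accumulating (a) a depth histogram — sufficient statistic for the weighted
median — and (b) per-chunk point queries against the SNV loci of each
chromosome present in the chunk. Because coverage rows are disjoint, a
locus is resolved by exactly one chunk and chunking cannot change any
result; the suite asserts byte-identical reports across chunk sizes from 1
row to whole-file. Chromosomes present in the SNV tables but absent from
the BED are scored 0 with a warning.

## Numerical choices

* `sgn(0) = 0`: a locus exactly at *m* pulls in neither direction.
* CDC grid `1 .. max(depth) + 1`: above `max + 1` the sign-sum is constant
  at −N, so nothing larger can be a strict improvement; the `+ 1` endpoint
  matters when all depths are equal or 0 (all-zero depths give CDC 1, the
  smallest admissible depth, with covered fraction 0 telling the real
  story).
* Lower median everywhere (no interpolation): integer statistics for
  integer depths.
* The overlap join merges book-ended equal-depth records so every emitted
  segment is a maximal constant-depth run; real depth-tool output is
  already maximal, but the invariant should not depend on that.
* Unsorted coverage input is sorted per chromosome with a warning
  (depth tools emit sorted output; the contract degrades gracefully);
  overlapping coverage rows are rejected as a format violation.
* Exon references with a gene on two chromosomes are rejected.

## Visualization

The figure is specified as data before it is drawn: a `GeneFigureSpec`
holds the upper-panel trace, the exon layout with per-exon x-ranges, the
per-segment fill colors and the SNV dots. Tests assert on this object —
dot y-values equal reported depths, red extents equal flagged exons —
because pixel comparison ties tests to a rendering backend without adding
semantics. Spans beyond 200 kb are max-pooled for the upper panel;
max-pooling can absorb a lone dip into a high bin but never invents a
sub-threshold bin, so the rendered trace errs toward showing high coverage
only where some base truly reaches it, and the exon panel (never pooled)
carries the diagnostic detail. Colors follow the conventional scheme
(germline red, somatic dark blue, sub-threshold red fill, exon fill light
blue) and can be overridden.

## The synthetic-data generator

`fixtureSpec()`/`makeFixture()` emulate the three input files with known
ground truth: per-base depths from a constant, piecewise-constant or
i.i.d. Poisson model, run-length-encoded into BED rows exactly as depth
tools emit them; an exon BED with `chr`-prefixed labels; ClinVar-style
tables without the prefix (deliberately exercising label normalization);
and a JSON truth record computed directly from the per-base model — CDC by
an independent exhaustive scan, fractions and exon flags by per-base
lookup — never through the readers or the engine under test.

What the generator does *not* emulate: mapping artifacts (depth is i.i.d.
across bases, while real coverage is autocorrelated and GC-biased),
multi-allelic ClinVar records at one position, contig names outside the
`chr`/plain dialects, and real-genome scale. Passing tests therefore
demonstrate correctness of the computation, not robustness to every
real-world file quirk; the published whole-genome numbers for benchmark
samples additionally depend on the ClinVar snapshot used and are not
targets of this package's validation.

## Problem sizes in the validation suite

The suite runs fixtures of 4–10 kb chromosomes for deterministic models and
60–80 kb for Poisson models with 1000 loci; the CDC oracle check covers
1000 random multisets (N ≤ 200, depths ≤ 300) against exhaustive
minimization, and the interval engine is checked against per-base
rasterization on hundreds of random record/target configurations. These
sizes make every oracle exactly computable while exercising the same code
paths a whole-genome run uses; only `chunkLines` and file length differ at
scale.

## Known limitations

* One sample per run; no cohort aggregation.
* BAM/CRAM are upstream: the package starts from the per-base BED.
* ClinVar tables are taken as given — no significance-string filtering or
  network retrieval; what counts as "pathogenic" is the curator's choice.
* The CDC of a strongly bimodal depth profile is intentionally pessimistic
  (smallest balancing depth); read it together with the reported spread.
* Structural-variant inspection is a human use of the figures, not a
  computation the package performs.
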