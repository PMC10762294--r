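Package: ClinCoverage
Title: Clinical Depth-of-Coverage QC for Pathogenic Variant Loci and Gene
    Exons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control of sequencing depth at clinically relevant
    positions. Reads per-base coverage BED files produced by depth tools,
    an exon reference BED with gene symbols, and ClinVar-style tables of
    pathogenic germline and somatic single-nucleotide variant (SNV) loci.
    Computes the Clinical Depth Coverage (CDC) statistic -- the integer
    depth that balances the number of pathogenic SNV loci covered above
    and below it -- together with the fraction of loci covered at or
    above a user threshold, per-chromosome coverage summaries, per-gene
    exon coverage reports with sub-threshold exon flagging, and two-panel
    gene coverage figures. Includes a synthetic fixture generator with
    analytically known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Coverage, QualityControl, Sequencing, VariantAnnotation,
    Visualization
RoxygenNote: 7.3.3
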