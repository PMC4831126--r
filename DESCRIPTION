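Package: mbddiff
Title: Differential DNA Methylation from Methyl-Capture Sequencing with
    Bisulfite Amplicon Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide differential DNA
    methylation analysis from methyl-CpG binding domain capture sequencing
    (MBD-seq). Calls methylated regions per sample with a Poisson
    enrichment test, merges regions across samples by reciprocal overlap,
    counts non-redundant reads per region, filters on reads-per-million,
    and tests each case individually against a control group with a
    negative-binomial exact test under Benjamini-Hochberg adjustment.
    Downstream tools intersect per-case calls into shared-region sets,
    score regions for ZFP57 binding-motif (TGCCGC) content, overlap with
    allele-specific-methylation datasets, CpG islands and transcripts, and
    quantify per-CpG methylation from indexed bisulfite amplicon reads for
    cross-platform validation. A synthetic-data generator emulating a
    small patient/heterozygote/control cohort provides ground truth for
    parameter-recovery and calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
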