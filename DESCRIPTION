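Package: methtrail
Title: Organ-Specific DNA Methylation Signatures, DMRs and iPSC
    Epigenetic Memory from 450K Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Illumina 450K methylation beta values
    from isogenic multi-organ designs: probe-level quality control (bead
    count, detection p-value, success rate, SNP and sex-chromosome
    exclusion), genic and CpG-island-centric probe annotation relative to
    the nearest TSS, pairwise delta-beta calling of organ-specific hyper-
    and hypomethylated CpGs, consecutive-CpG differentially methylated
    region (DMR) calling, pluripotency-barcode and triplet epigenetic
    memory calling for induced pluripotent stem cell clones, integration
    of promoter and gene-body methylation changes with organ-unique
    differentially expressed genes, and odds-ratio enrichment across
    genomic categories and chromatin states. Includes a seeded synthetic
    data generator that emulates the full study design so every stage is
    testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
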