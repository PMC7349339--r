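Package: chimeraNIPT
Title: Non-Invasive Prenatal Testing from Long Chimeric cfDNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for non-invasive prenatal aneuploidy
    testing based on long chimeric cell-free DNA reads. Short (40-50 bp)
    cfDNA sub-fragments are randomly self-ligated into long (>300 bp)
    chimeric molecules so that a single paired-end read carries several
    genomic tags. The package simulates such libraries with known ground
    truth (reference, cfDNA length mixtures, fragmentase products,
    chimeric read pairs, truth alignments, SNP amplicon allele counts),
    deconstructs chimeric alignments into filtered genomic fragment tags,
    calls fetal trisomy 13/18/21 from corrected bin counts and chromosomal
    Z-scores against a control cohort, estimates fetal fraction from SNP
    allele counts and chromosome-Y coverage, designs SNP amplicon panels,
    and computes diagnostic-performance statistics (cross-validated
    sensitivity/specificity/AUC, Wilson score intervals, prevalence-indexed
    PPV/NPV).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
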