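Package: methdmr
Title: Promoter DMC and Windowed DMR Calling for Whole-Genome Bisulfite Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential-methylation analysis of whole-genome bisulfite
    sequencing (WGBS) cytosine call files for small two-group designs.
    Reads Bismark-style per-CpG reports, destrands CpG dyads, unifies
    sites covered in every sample into a rate matrix, calls promoter
    differentially methylated cytosines (DMCs) by a per-site t-test plus
    a 20-percentage-point effect filter, extracts differentially
    methylated regions (DMRs) as runs of at least 10 CpGs within 300 bp
    whose average group difference is at least 20 points, relates DMRs to
    scored histone-acetylation ChIP peaks within a 1 kb flank, and
    compares embryo methylomes at CpGs common to all samples with
    classification bins and sample-level PCA. A beta-binomial simulator
    plants DMCs, DMRs and peaks with known truth so every stage can be
    benchmarked offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
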