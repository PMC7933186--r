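Package: mztclear
Title: Small-RNA-Guided Clearance of Maternal mRNAs in Early Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of Argonaute/22G-RNA-guided clearance of
    maternal mRNAs during the C. elegans maternal-to-zygotic transition.
    Provides immunoprecipitation-based small-RNA target calling with RPM
    density tiers, stage-resolved maternal transcript classification,
    per-gene decay and translation statistics (degradation rate, degradation
    efficiency, translational efficiency, fold changes, enrichment factors),
    scaled TSS-to-TTS coverage metaprofiles, relative synonymous codon usage,
    single-molecule FISH spot detection, the group-comparison statistics used
    throughout, and a seed-reproducible synthetic data generator that plants
    the structure the analysis assumes so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
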