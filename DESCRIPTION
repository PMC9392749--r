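Package: tcgtscan
Title: Discovery of Transposable-Element-Driven Chimeric Gene Transcripts in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transpochimeric gene transcripts (TcGTs), mRNAs that
    initiate inside a transposable element and splice into exons of an
    annotated gene, from per-sample transcript assemblies. Provides curation
    of RepeatMasker repeat annotation (fusion of fragmented elements and
    grouping of flanking LTRs with their internal ERV counterparts),
    per-sample chimera calling against curated repeats and coding exons,
    cohort-level aggregation of calls by transcription start site with a
    tumor/normal recurrence filter, classification of the predicted protein
    product relative to the canonical protein, and a deterministic synthetic
    cohort generator with machine-readable ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
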