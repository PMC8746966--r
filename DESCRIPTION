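Package: ncatsr
Title: Cas9-Targeted Nanopore Enrichment and Per-Read Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing Cas9-targeted nanopore sequencing (nCATS)
    experiments on large plant genomes: guide-RNA panel geometry (protospacer
    and PAM location, predicted cut sites and excised fragments), read QC and
    on-target/enrichment accounting, conversion of per-read cytosine
    methylation calls into standard SAM MM/ML base-modification tags,
    per-read and per-haplotype methylation profiling (promoter versus gene
    body), CpG-island and k-mer self-similarity (dot-plot) sequence
    characterisation, and a deterministic synthetic-data generator that
    emulates nCATS-like target enrichment with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
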