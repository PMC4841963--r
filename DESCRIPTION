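Package: genepoolmarkers
Title: Genic Marker Discovery from Transcriptome Variant and SSR Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to discover and filter genic molecular markers from
    transcriptome data across a crop genepool. Mines perfect di-, tri- and
    tetranucleotide microsatellites (SSRs) with motif canonicalization,
    localizes them relative to predicted open reading frames, classifies
    multi-species variant calls (SNPs and INDELs) into intraspecific and
    interspecific sets, applies a genotyping-suitability filter cascade
    including CAPS detection by differential restriction digestion, and
    emits summary tables. A seeded simulator produces transcripts, ORFs,
    SSRs and a multi-species VCF with planted ground truth for closed-loop
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
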