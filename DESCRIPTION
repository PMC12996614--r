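Package: fusimba
Title: Expression-Imbalance Fusion Inference and QC Gating for Clinical RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers likely gene fusions from stranded whole-transcriptome
    sequencing of FFPE tumor samples when no split reads or discordant mates
    are available, by quantifying the 5' versus 3' expression imbalance of a
    target gene around a recurrent or automatically determined breakpoint.
    Provides strand-aware per-exon coverage and splice-junction counting from
    BAM alignments, an exact single-changepoint step-model fit for automatic
    breakpoint determination, a four-criterion FFPE quality-control gate with
    fallback routing to targeted panels, fusion-caller output harmonization
    and filtering, a deterministic stranded paired-end read simulator with
    analytic truth, and cohort-level concordance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
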