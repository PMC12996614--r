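# Generics for the package's S4 accessors and alignment-consuming
# operations. Alignment-consuming generics dispatch on the alignment source:
# a path to a BAM/SAM file, or the in-memory record table produced by the
# simulator.

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' @export
setGeneric("geneChrom", function(x) standardGeneric("geneChrom"))

#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))

#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @export
setGeneric("exonCount", function(x) standardGeneric("exonCount"))

#' @export
setGeneric("exonWidths", function(x) standardGeneric("exonWidths"))

#' @export
setGeneric("boundaryExon", function(x) standardGeneric("boundaryExon"))

#' @export
setGeneric("retainedSide", function(x) standardGeneric("retainedSide"))

#' @export
setGeneric("senseDepth", function(x) standardGeneric("senseDepth"))

#' @export
setGeneric("antisenseDepth", function(x) standardGeneric("antisenseDepth"))

#' @export
setGeneric("foldChange", function(x) standardGeneric("foldChange"))

#' @export
setGeneric("isFlagged", function(x) standardGeneric("isFlagged"))

#' Strand-aware per-exon coverage of a gene
#'
#' @param alignments a BAM/SAM file path or a simulator record table.
#' @param gene a [GeneModel-class].
#' @param orientation library orientation: `"RF"` (reverse-stranded,
#'   TruSeq-stranded convention, the default) or `"FR"`.
#' @param ... passed to methods.
#' @return a [StrandedCoverage-class].
#' @export
setGeneric("strandedExonCoverage",
    function(alignments, gene, orientation = "RF", ...)
        standardGeneric("strandedExonCoverage"))

#' Strand-aware spliced-read counts around a breakpoint
#'
#' @inheritParams strandedExonCoverage
#' @param bp a [BreakpointSpec-class] for `gene`.
#' @return a [JunctionCounts-class].
#' @export
setGeneric("countSplicedReads",
    function(alignments, gene, bp, orientation = "RF", ...)
        standardGeneric("countSplicedReads"))

#' Median insert size from paired-end alignments
#'
#' Median of the absolute template length over primary, properly paired
#' records, counting each pair once (via its leftmost mate). Even counts use
#' the lower median, so the result is always an observed integer value.
#'
#' @param alignments a BAM/SAM file path or a simulator record table.
#' @param ... passed to methods.
#' @return median insert size in bp.
#' @export
setGeneric("medianInsertSize",
    function(alignments, ...) standardGeneric("medianInsertSize"))

#' Unique fragment count after duplicate collapsing
#'
#' Counts distinct (contig, fragment start, fragment end, fragment
#' orientation) keys among primary properly paired records — coordinate
#' duplicate collapsing, the post-sequencing "unique reads" QC metric.
#'
#' @inheritParams medianInsertSize
#' @return number of unique fragments.
#' @export
setGeneric("countUniqueFragments",
    function(alignments, ...) standardGeneric("countUniqueFragments"))
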