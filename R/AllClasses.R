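#' @import methods
#' @importFrom IRanges IRanges start end width reduce
NULL

#' GeneModel: exon structure of a target gene in transcription order
#'
#' Holds the union-merged exon intervals of one gene. Exons are stored in
#' transcription order, i.e. exon 1 is the 5'-most exon of the transcript:
#' for a plus-strand gene genomic starts increase with exon index, for a
#' minus-strand gene they decrease. Coordinates are 1-based closed genomic
#' intervals ([IRanges::IRanges]).
#'
#' @slot geneId gene identifier (e.g. Ensembl id or symbol).
#' @slot geneName human-readable gene symbol.
#' @slot chrom contig name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon intervals in transcription order.
#' @seealso [geneModel()], [exonPartition()]
#' @export
setClass("GeneModel",
    representation(
        geneId   = "character",
        geneName = "character",
        chrom    = "character",
        strand   = "character",
        exons    = "IRanges"
    )
)

setValidity("GeneModel", function(object) {
    msg <- character()
    ex <- object@exons
    if (length(object@geneId) != 1L || !nzchar(object@geneId))
        msg <- c(msg, "geneId must be a single non-empty string")
    if (!(object@strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(ex) == 0L)
        msg <- c(msg, "a GeneModel needs at least one exon")
    if (length(ex) > 0L) {
        if (any(width(ex) < 1L))
            msg <- c(msg, "exon intervals must have positive width")
        if (any(start(ex) < 1L))
            msg <- c(msg, "exon starts must be >= 1")
        if (length(reduce(ex)) != length(ex))
            msg <- c(msg, "exons must be non-overlapping and non-adjacent after union-merge")
        if (length(ex) > 1L) {
            d <- diff(start(ex))
            ok <- if (object@strand == "+") all(d > 0L) else all(d < 0L)
            if (!ok)
                msg <- c(msg,
                    "exons must be in transcription order (strand-aware)")
        }
    }
    if (length(msg)) msg else TRUE
})

#' BreakpointSpec: a 5'/3' partition point of a gene
#'
#' Specifies where a gene is split into its 5' and 3' parts for the
#' imbalance assay: between exon `boundaryExon` and exon `boundaryExon + 1`
#' in transcription order. `retainedSide` is the side expected retained (and
#' therefore overexpressed) in a fusion transcript, e.g. `"3prime"` for the
#' kinase domain of ALK.
#'
#' @slot geneId gene identifier the breakpoint refers to.
#' @slot boundaryExon integer k: partition between exon k and exon k+1.
#' @slot genomicPos optional genomic coordinate of the boundary (NA if unknown).
#' @slot retainedSide `"5prime"` or `"3prime"`.
#' @slot source `"recurrent"` (from a breakpoint table) or `"automatic"`
#'   (from [autoBreakpoint()]).
#' @seealso [breakpointSpec()], [loadBreakpointTable()]
#' @export
setClass("BreakpointSpec",
    representation(
        geneId       = "character",
        boundaryExon = "integer",
        genomicPos   = "numeric",
        retainedSide = "character",
        source       = "character"
    )
)

setValidity("BreakpointSpec", function(object) {
    msg <- character()
    if (length(object@boundaryExon) != 1L || is.na(object@boundaryExon) ||
        object@boundaryExon < 1L)
        msg <- c(msg, "boundaryExon must be an integer >= 1")
    if (!(object@retainedSide %in% c("5prime", "3prime")))
        msg <- c(msg, "retainedSide must be '5prime' or '3prime'")
    if (!(object@source %in% c("recurrent", "automatic")))
        msg <- c(msg, "source must be 'recurrent' or 'automatic'")
    if (length(msg)) msg else TRUE
})

#' StrandedCoverage: per-exon sense/antisense mean depth
#'
#' Mean read depth (x coverage) over each exon of a gene, computed
#' separately for reads assigned to the gene's own strand (sense) and to the
#' opposite strand (antisense) under a stranded library protocol. The
#' antisense track exists to expose confounders such as unspliced pre-mRNA
#' of a neighboring gene on the opposite strand; it never enters the
#' imbalance statistic.
#'
#' @slot geneId gene identifier.
#' @slot senseDepth numeric vector, one mean depth per exon (transcription order).
#' @slot antisenseDepth numeric vector, same length.
#' @slot exonWidths integer vector of exon widths in bp.
#' @seealso [strandedExonCoverage()], [imbalanceStatistic()]
#' @export
setClass("StrandedCoverage",
    representation(
        geneId         = "character",
        senseDepth     = "numeric",
        antisenseDepth = "numeric",
        exonWidths     = "integer"
    )
)

setValidity("StrandedCoverage", function(object) {
    msg <- character()
    n <- length(object@exonWidths)
    if (length(object@senseDepth) != n || length(object@antisenseDepth) != n)
        msg <- c(msg, "senseDepth, antisenseDepth and exonWidths must have equal length")
    if (any(object@senseDepth < 0) || any(object@antisenseDepth < 0))
        msg <- c(msg, "depths must be non-negative")
    if (n > 0L && any(object@exonWidths < 1L))
        msg <- c(msg, "exon widths must be positive")
    if (length(msg)) msg else TRUE
})

#' JunctionCounts: strand-aware spliced-read tallies around a breakpoint
#'
#' @slot n5 spliced reads on the gene strand whose junctions lie entirely in
#'   the 5' partition.
#' @slot n3 likewise for the 3' partition.
#' @slot nSpanning spliced reads with a junction crossing the breakpoint
#'   boundary (wild-type splicing evidence; excluded from n5/n3).
#' @seealso [countSplicedReads()]
#' @export
setClass("JunctionCounts",
    representation(n5 = "integer", n3 = "integer", nSpanning = "integer")
)

setValidity("JunctionCounts", function(object) {
    if (any(c(object@n5, object@n3, object@nSpanning) < 0L))
        "junction counts must be non-negative" else TRUE
})

#' ImbalanceThresholds: decision rule parameters for flagging
#'
#' All values are assay configuration, exposed because the underlying
#' decision ("significantly different transcriptional activity") has no
#' universal cutoff; defaults were chosen by simulation (see the package
#' vignette).
#'
#' @slot minFoldChange minimum retained/other fold change (default 10).
#' @slot minRetainedDepth minimum mean depth on the retained side, x coverage
#'   (default 2.0).
#' @slot minJunctionDelta minimum absolute difference between retained-side
#'   and other-side junction counts (default 5).
#' @slot pseudocount epsilon added to both means in the fold change
#'   (default 0.05 x), required because the unexpressed side is often 0.
#' @seealso [imbalanceThresholds()], [evaluateImbalance()]
#' @export
setClass("ImbalanceThresholds",
    representation(
        minFoldChange    = "numeric",
        minRetainedDepth = "numeric",
        minJunctionDelta = "integer",
        pseudocount      = "numeric"
    )
)

setValidity("ImbalanceThresholds", function(object) {
    v <- c(object@minFoldChange, object@minRetainedDepth,
           object@minJunctionDelta, object@pseudocount)
    if (any(!is.finite(v)) || any(v <= 0))
        "all thresholds must be strictly positive" else TRUE
})

#' ImbalanceResult: the outcome of the imbalance assay for one gene/breakpoint
#'
#' @slot geneId gene identifier.
#' @slot breakpoint the [BreakpointSpec-class] evaluated.
#' @slot mean5 length-weighted mean sense depth over the 5' partition.
#' @slot mean3 likewise over the 3' partition.
#' @slot foldChange (mean_retained + eps) / (mean_other + eps).
#' @slot junctions [JunctionCounts-class].
#' @slot flagged logical; NA until [evaluateImbalance()] has been applied.
#' @slot recommendation `"none"` or `"orthogonal_confirmation"`.
#' @export
setClass("ImbalanceResult",
    representation(
        geneId         = "character",
        breakpoint     = "BreakpointSpec",
        mean5          = "numeric",
        mean3          = "numeric",
        foldChange     = "numeric",
        junctions      = "JunctionCounts",
        flagged        = "logical",
        recommendation = "character"
    )
)

setValidity("ImbalanceResult", function(object) {
    msg <- character()
    if (object@mean5 < 0 || object@mean3 < 0)
        msg <- c(msg, "means must be non-negative")
    if (!is.na(object@foldChange) && object@foldChange <= 0)
        msg <- c(msg, "foldChange must be positive")
    if (!(object@recommendation %in% c("none", "orthogonal_confirmation")))
        msg <- c(msg, "recommendation must be 'none' or 'orthogonal_confirmation'")
    if (isTRUE(object@flagged) && object@recommendation != "orthogonal_confirmation")
        msg <- c(msg, "a flagged result must recommend orthogonal confirmation")
    if (length(msg)) msg else TRUE
})

#' QCMetrics: the four gate metrics for one sample
#'
#' Tumor cell content (TCC) and RNA input are pre-analytic metadata supplied
#' by the pathologist/lab; unique reads and median insert size are computed
#' from the alignments. The package never imputes the metadata fields.
#'
#' @slot sampleId sample identifier.
#' @slot tcc tumor cell content, percent (0-100); NA if not recorded.
#' @slot rnaInput RNA input, ng.
#' @slot uniqueReads unique fragments after duplicate collapsing.
#' @slot medianInsert median insert size, bp.
#' @seealso [qcMetrics()], [evaluateQC()]
#' @export
setClass("QCMetrics",
    representation(
        sampleId     = "character",
        tcc          = "numeric",
        rnaInput     = "numeric",
        uniqueReads  = "numeric",
        medianInsert = "numeric"
    )
)

setValidity("QCMetrics", function(object) {
    msg <- character()
    if (!is.na(object@tcc) && (object@tcc < 0 || object@tcc > 100))
        msg <- c(msg, "tcc must be in [0, 100]")
    for (nm in c("rnaInput", "uniqueReads", "medianInsert")) {
        v <- slot(object, nm)
        if (!is.na(v) && v < 0) msg <- c(msg, paste(nm, "must be >= 0"))
    }
    if (length(msg)) msg else TRUE
})

#' QCThresholds: the four-criterion gate
#'
#' Defaults are the clinical gate: TCC >= 40 %, RNA input >= 50 ng,
#' >= 50 million unique fragments, median insert size >= 100 bp. All four
#' comparisons are inclusive (>=); see the vignette for the rationale.
#'
#' @slot minTcc percent.
#' @slot minRnaInput ng.
#' @slot minUniqueReads fragment count.
#' @slot minMedianInsert bp.
#' @seealso [qcThresholds()], [evaluateQC()]
#' @export
setClass("QCThresholds",
    representation(
        minTcc          = "numeric",
        minRnaInput     = "numeric",
        minUniqueReads  = "numeric",
        minMedianInsert = "numeric"
    )
)

setValidity("QCThresholds", function(object) {
    v <- c(object@minTcc, object@minRnaInput, object@minUniqueReads,
           object@minMedianInsert)
    if (any(is.na(v)) || any(v < 0)) "thresholds must be >= 0" else TRUE
})

#' QCDecision: gate outcome and routing for one sample
#'
#' @slot sampleId sample identifier.
#' @slot tccOk,inputOk,readsOk,insertOk per-criterion pass flags.
#' @slot overallPass TRUE iff all four flags are TRUE.
#' @slot routing `"WTS"` if the sample passes the gate, `"targeted_panel"`
#'   otherwise (fallback assay).
#' @export
setClass("QCDecision",
    representation(
        sampleId    = "character",
        tccOk       = "logical",
        inputOk     = "logical",
        readsOk     = "logical",
        insertOk    = "logical",
        overallPass = "logical",
        routing     = "character"
    )
)

setValidity("QCDecision", function(object) {
    msg <- character()
    flags <- c(object@tccOk, object@inputOk, object@readsOk, object@insertOk)
    if (object@overallPass != all(flags))
        msg <- c(msg, "overallPass must equal the conjunction of the four flags")
    if (!(object@routing %in% c("WTS", "targeted_panel")))
        msg <- c(msg, "routing must be 'WTS' or 'targeted_panel'")
    if ((object@routing == "WTS") != object@overallPass)
        msg <- c(msg, "routing must be WTS iff overallPass")
    if (length(msg)) msg else TRUE
})

#' GeneSet: a gene list with its read-support threshold
#'
#' Mirrors the two filtering regimes used in practice: a validated
#' diagnostic gene set with minimum support 1, and an expanded exploratory
#' list with a stricter threshold of 10 reads.
#'
#' @slot name set name.
#' @slot genes character vector of gene symbols.
#' @slot minSupport minimum supporting read count (>= 1).
#' @seealso [geneSet()], [applyFilters()]
#' @export
setClass("GeneSet",
    representation(name = "character", genes = "character", minSupport = "integer")
)

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@genes) == 0L)
        msg <- c(msg, "gene set must be non-empty")
    if (is.na(object@minSupport) || object@minSupport < 1L)
        msg <- c(msg, "minSupport must be >= 1")
    if (length(msg)) msg else TRUE
})

setClassUnion("BreakpointSpecOrNULL", c("BreakpointSpec", "NULL"))

#' SimConfig: one simulated stranded FFPE RNA-seq sample
#'
#' Describes the data-generating situation the simulator emulates: a fusion
#' transcript expressed only on the retained side of a breakpoint, scaled by
#' tumor cell content; a full-length wild-type background present in all
#' cells; optional unspliced antisense pre-mRNA contamination from a
#' neighboring gene; and FFPE-like log-normal insert sizes.
#'
#' @slot gene [GeneModel-class] of the target gene.
#' @slot breakpoint [BreakpointSpec-class], or NULL for a wild-type sample.
#' @slot tcc tumor cell content, percent; scales the fusion expression.
#' @slot fusionExpression x coverage of the fusion transcript in pure tumor.
#' @slot wildtypeExpression x coverage of the full-length transcript in all cells.
#' @slot antisenseDepth x coverage of unspliced opposite-strand contamination.
#' @slot antisenseSpan genomic interval (length-2 integer, 1-based closed) of
#'   the contamination; length-0 means the gene's genomic span.
#' @slot insertMedian median insert size, bp.
#' @slot insertSd insert-size spread, bp (converted to the log-normal sdlog).
#' @slot readLength bp.
#' @slot seed integer RNG seed (mandatory: identical config => identical SAM).
#' @seealso [simConfig()], [simulateSample()]
#' @export
setClass("SimConfig",
    representation(
        gene               = "GeneModel",
        breakpoint         = "BreakpointSpecOrNULL",
        tcc                = "numeric",
        fusionExpression   = "numeric",
        wildtypeExpression = "numeric",
        antisenseDepth     = "numeric",
        antisenseSpan      = "integer",
        insertMedian       = "numeric",
        insertSd           = "numeric",
        readLength         = "integer",
        seed               = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@tcc < 0 || object@tcc > 100)
        msg <- c(msg, "tcc must be in [0, 100]")
    if (object@fusionExpression < 0 || object@wildtypeExpression < 0 ||
        object@antisenseDepth < 0)
        msg <- c(msg, "expression levels must be >= 0")
    if (object@insertMedian < object@readLength)
        msg <- c(msg, "insertMedian must be >= readLength")
    if (object@readLength < 1L)
        msg <- c(msg, "readLength must be positive")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a seed is required")
    if (!is.null(object@breakpoint) &&
        object@breakpoint@geneId != object@gene@geneId)
        msg <- c(msg, "breakpoint geneId must match the gene")
    if (length(object@antisenseSpan) %in% c(0L, 2L) == FALSE)
        msg <- c(msg, "antisenseSpan must be length 0 or 2")
    if (length(msg)) msg else TRUE
})

#' SimTruth: ground truth accompanying a simulated sample
#'
#' @slot config the [SimConfig-class] that generated the sample.
#' @slot nFusionFragments,nWildtypeFragments,nAntisenseFragments realized
#'   fragment counts per transcript class.
#' @slot boundaryExon true boundary exon (NA for wild-type samples).
#' @slot expectedSenseDepth analytic expected sense mean depth per exon,
#'   accounting for fragment-placement edge effects.
#' @export
setClass("SimTruth",
    representation(
        config              = "SimConfig",
        nFusionFragments    = "integer",
        nWildtypeFragments  = "integer",
        nAntisenseFragments = "integer",
        boundaryExon        = "integer",
        expectedSenseDepth  = "numeric"
    )
)

#' CohortSummary: headline statistics of a cohort ledger
#'
#' All percentages are rounded half-up to one decimal unless the summary was
#' computed with `integerPct = TRUE` (then the detection rate is printed as
#' an integer percent). Undefined rates (e.g. detection rate with no
#' fusion-positive samples) are NA.
#'
#' @slot nSamples,nFusionPositive,nDetected counts.
#' @slot detectionRatePct detected / fusion-positive.
#' @slot nConcordantSamples,sampleConcordancePct sample-level concordance
#'   (detected positives + confirmed negatives).
#' @slot nFusionsTotal,nFusionsCalled,fusionCallRatePct fusion-level tallies.
#' @slot qcFailCounts named integer vector: per-criterion failure counts.
#' @slot nQcFail,qcFailPct,nQcPass,qcPassPct gate tallies.
#' @slot concordanceAmongQcPassPct sample concordance restricted to
#'   QC-passing samples.
#' @slot nRoutedPanel,routedPanelPct fallback-routing tallies.
#' @seealso [summarizeCohort()]
#' @export
setClass("CohortSummary",
    representation(
        nSamples                  = "integer",
        nFusionPositive           = "integer",
        nDetected                 = "integer",
        detectionRatePct          = "numeric",
        nConcordantSamples        = "integer",
        sampleConcordancePct      = "numeric",
        nFusionsTotal             = "integer",
        nFusionsCalled            = "integer",
        fusionCallRatePct         = "numeric",
        qcFailCounts              = "integer",
        nQcFail                   = "integer",
        qcFailPct                 = "numeric",
        nQcPass                   = "integer",
        qcPassPct                 = "numeric",
        concordanceAmongQcPassPct = "numeric",
        nRoutedPanel              = "integer",
        routedPanelPct            = "numeric"
    )
)
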