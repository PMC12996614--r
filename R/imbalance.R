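#' Construct JunctionCounts
#'
#' @param n5,n3 spliced reads on the gene strand whose junctions lie
#'   entirely within the 5' / 3' partition.
#' @param nSpanning spliced reads with a junction crossing the boundary.
#' @export
junctionCounts <- function(n5 = 0L, n3 = 0L, nSpanning = 0L) {
    methods::new("JunctionCounts", n5 = as.integer(n5), n3 = as.integer(n3),
                 nSpanning = as.integer(nSpanning))
}

setMethod("show", "JunctionCounts", function(object) {
    cat("JunctionCounts: n5 =", object@n5, ", n3 =", object@n3,
        ", spanning =", object@nSpanning, "\n")
})

#' Construct ImbalanceThresholds
#'
#' @param minFoldChange minimum fold change (default 10).
#' @param minRetainedDepth minimum retained-side mean depth, x (default 2.0).
#' @param minJunctionDelta minimum |retained - other| junction-count
#'   difference (default 5).
#' @param pseudocount epsilon of the fold-change formula, x (default 0.05).
#' @return an [ImbalanceThresholds-class].
#' @export
imbalanceThresholds <- function(minFoldChange = 10, minRetainedDepth = 2.0,
                                minJunctionDelta = 5L, pseudocount = 0.05) {
    methods::new("ImbalanceThresholds",
        minFoldChange = minFoldChange, minRetainedDepth = minRetainedDepth,
        minJunctionDelta = as.integer(minJunctionDelta),
        pseudocount = pseudocount)
}

#' @describeIn strandedExonCoverage construct directly from per-exon values
#'   (mainly for tests and downstream tools).
#' @param geneId gene identifier.
#' @param sense,antisense numeric per-exon mean depths (transcription order).
#' @param widths integer exon widths.
#' @export
strandedCoverage <- function(geneId, sense, antisense = numeric(length(sense)),
                             widths) {
    methods::new("StrandedCoverage", geneId = geneId,
        senseDepth = as.numeric(sense), antisenseDepth = as.numeric(antisense),
        exonWidths = as.integer(widths))
}

#' @describeIn strandedExonCoverage per-exon sense mean depth.
#' @param x a `StrandedCoverage`.
#' @export
setMethod("senseDepth", "StrandedCoverage", function(x) x@senseDepth)

#' @describeIn strandedExonCoverage per-exon antisense mean depth.
#' @export
setMethod("antisenseDepth", "StrandedCoverage", function(x) x@antisenseDepth)

#' @describeIn strandedExonCoverage gene identifier.
#' @export
setMethod("geneId", "StrandedCoverage", function(x) x@geneId)

setMethod("show", "StrandedCoverage", function(object) {
    cat("StrandedCoverage for", object@geneId, "over",
        length(object@exonWidths), "exons\n")
    cat("  sense:     ", paste(round(object@senseDepth, 2), collapse = " "),
        "\n")
    cat("  antisense: ", paste(round(object@antisenseDepth, 2),
        collapse = " "), "\n")
})

# Shared implementation over the canonical record table.
.coverageFromRecords <- function(rec, gene, orientation, minMapq = 1L) {
    rec <- .primaryRecords(rec, minMapq)
    rec <- rec[rec$rname == geneChrom(gene), , drop = FALSE]
    ex <- exonRanges(gene)
    w <- IRanges::width(ex)
    meanDepth <- function(sel) {
        if (!any(sel)) return(numeric(length(ex)))
        ir <- unlist(.alignedBlocks(rec[sel, , drop = FALSE]),
                     use.names = FALSE)
        covWidth <- max(max(IRanges::end(ex)),
                        if (length(ir)) max(IRanges::end(ir)) else 0L)
        cov <- IRanges::coverage(ir, width = covWidth)
        as.numeric(IRanges::viewSums(IRanges::Views(cov, ex))) / w
    }
    ts <- .transcriptStrand(rec$flag, orientation)
    strandedCoverage(geneId(gene),
        sense = meanDepth(ts == geneStrand(gene)),
        antisense = meanDepth(ts == .flipStrand(geneStrand(gene))),
        widths = w)
}

#' @describeIn strandedExonCoverage from a coordinate-sorted, indexed BAM
#'   (or SAM, converted on the fly).
#' @param minMapq minimum mapping quality retained in the pileup (default 1).
#' @export
setMethod("strandedExonCoverage", "character",
    function(alignments, gene, orientation = "RF", minMapq = 1L) {
        ex <- exonRanges(gene)
        rec <- .readRecords(alignments, geneChrom(gene),
                            min(IRanges::start(ex)), max(IRanges::end(ex)))
        .coverageFromRecords(rec, gene, orientation, minMapq)
    })

#' @describeIn strandedExonCoverage from an in-memory record table (e.g.
#'   `simulateSample(...)$records`).
#' @export
setMethod("strandedExonCoverage", "data.frame",
    function(alignments, gene, orientation = "RF", minMapq = 1L) {
        .coverageFromRecords(alignments, gene, orientation, minMapq)
    })

#' @describeIn strandedExonCoverage from a simulator result list.
#' @export
setMethod("strandedExonCoverage", "list",
    function(alignments, gene, orientation = "RF", minMapq = 1L) {
        .coverageFromRecords(.recordsFrom(alignments), gene, orientation,
                             minMapq)
    })

# Classify each gene-strand spliced read as 5', 3' or boundary-spanning.
.junctionsFromRecords <- function(rec, gene, bp, orientation, minMapq = 1L) {
    rec <- .primaryRecords(rec, minMapq)
    rec <- rec[rec$rname == geneChrom(gene), , drop = FALSE]
    ts <- .transcriptStrand(rec$flag, orientation)
    rec <- rec[ts == geneStrand(gene), , drop = FALSE]
    b <- bp@genomicPos
    if (is.na(b)) b <- breakpointGenomicPos(gene, boundaryExon(bp))
    jr <- .junctionRanges(rec)
    spliced <- S4Vectors::elementNROWS(jr) > 0L
    n5 <- n3 <- nSpan <- 0L
    if (any(spliced)) {
        jr <- jr[spliced]
        grp <- rep(seq_along(jr), S4Vectors::elementNROWS(jr))
        ends <- unlist(IRanges::end(jr), use.names = FALSE)
        starts <- unlist(IRanges::start(jr), use.names = FALSE)
        perReadLeft <- as.logical(tapply(ends < b, grp, all))
        perReadRight <- as.logical(tapply(starts > b, grp, all))
        spanning <- !(perReadLeft | perReadRight)
        if (geneStrand(gene) == "+") {
            n5 <- sum(perReadLeft); n3 <- sum(perReadRight)
        } else {
            n5 <- sum(perReadRight); n3 <- sum(perReadLeft)
        }
        nSpan <- sum(spanning)
    }
    junctionCounts(n5, n3, nSpan)
}

#' @describeIn countSplicedReads from a BAM/SAM file.
#' @param minMapq minimum mapping quality (default 1).
#' @export
setMethod("countSplicedReads", "character",
    function(alignments, gene, bp, orientation = "RF", minMapq = 1L) {
        ex <- exonRanges(gene)
        rec <- .readRecords(alignments, geneChrom(gene),
                            min(IRanges::start(ex)), max(IRanges::end(ex)))
        .junctionsFromRecords(rec, gene, bp, orientation, minMapq)
    })

#' @describeIn countSplicedReads from an in-memory record table.
#' @export
setMethod("countSplicedReads", "data.frame",
    function(alignments, gene, bp, orientation = "RF", minMapq = 1L) {
        .junctionsFromRecords(alignments, gene, bp, orientation, minMapq)
    })

#' @describeIn countSplicedReads from a simulator result list.
#' @export
setMethod("countSplicedReads", "list",
    function(alignments, gene, bp, orientation = "RF", minMapq = 1L) {
        .junctionsFromRecords(.recordsFrom(alignments), gene, bp,
                              orientation, minMapq)
    })

#' The 5'/3' imbalance statistic
#'
#' Computes the length-weighted mean sense depth over the 5' and 3'
#' partitions of a gene and the pseudocounted fold change
#' `(mean_retained + eps) / (mean_other + eps)`. The pseudocount is needed
#' because the non-retained side of a fusion-bearing unexpressed gene is
#' typically at or near zero coverage.
#'
#' @param cov a [StrandedCoverage-class].
#' @param partition result of [exonPartition()].
#' @param retainedSide `"5prime"` or `"3prime"`.
#' @param epsilon pseudocount (x coverage, default 0.05).
#' @param junctions a [JunctionCounts-class] (default: all zero).
#' @param bp optional [BreakpointSpec-class] carried into the result; if
#'   NULL, one is derived from the partition.
#' @param lengthWeighted if FALSE, use the plain mean of per-exon means
#'   instead of the length-weighted mean.
#' @return an [ImbalanceResult-class] with `flagged = NA` (see
#'   [evaluateImbalance()]).
#' @examples
#' cov <- strandedCoverage("ALK", sense = c(rep(0.03, 19), rep(7.37, 15)),
#'                         widths = rep(150L, 34))
#' part <- list(fivePrime = 1:19, threePrime = 20:34)
#' res <- imbalanceStatistic(cov, part, "3prime")
#' foldChange(res)  # (7.37 + 0.05) / (0.03 + 0.05) = 92.75
#' @export
imbalanceStatistic <- function(cov, partition, retainedSide = c("3prime", "5prime"),
                               epsilon = 0.05, junctions = junctionCounts(),
                               bp = NULL, lengthWeighted = TRUE) {
    retainedSide <- match.arg(retainedSide)
    five <- partition$fivePrime
    three <- partition$threePrime
    if (length(five) == 0L || length(three) == 0L)
        stop("both partition sides must be non-empty")
    n <- length(cov@senseDepth)
    if (length(five) + length(three) != n)
        stop("partition does not match the coverage's exon count")
    w <- if (lengthWeighted) as.numeric(cov@exonWidths) else rep(1, n)
    mean5 <- stats::weighted.mean(cov@senseDepth[five], w[five])
    mean3 <- stats::weighted.mean(cov@senseDepth[three], w[three])
    retained <- if (retainedSide == "3prime") mean3 else mean5
    other <- if (retainedSide == "3prime") mean5 else mean3
    fc <- (retained + epsilon) / (other + epsilon)
    if (is.null(bp))
        bp <- breakpointSpec(cov@geneId, max(five), retainedSide,
                             source = "recurrent")
    methods::new("ImbalanceResult", geneId = cov@geneId, breakpoint = bp,
        mean5 = mean5, mean3 = mean3, foldChange = fc,
        junctions = junctions, flagged = NA, recommendation = "none")
}

#' @describeIn imbalanceStatistic fold change of an ImbalanceResult.
#' @param x an `ImbalanceResult`.
#' @export
setMethod("foldChange", "ImbalanceResult", function(x) x@foldChange)

#' @describeIn imbalanceStatistic flag status of an ImbalanceResult.
#' @export
setMethod("isFlagged", "ImbalanceResult", function(x) x@flagged)

#' @describeIn imbalanceStatistic gene identifier of an ImbalanceResult.
#' @export
setMethod("geneId", "ImbalanceResult", function(x) x@geneId)

setMethod("show", "ImbalanceResult", function(object) {
    j <- object@junctions
    cat("ImbalanceResult ", object@geneId, " (boundary exon ",
        object@breakpoint@boundaryExon, ", retained ",
        object@breakpoint@retainedSide, ")\n", sep = "")
    cat(sprintf("  mean5 = %.3fx, mean3 = %.3fx, fold change = %.2f\n",
        object@mean5, object@mean3, object@foldChange))
    cat("  junctions: 5' =", j@n5, ", 3' =", j@n3, ", spanning =",
        j@nSpanning, "\n")
    cat("  flagged:", object@flagged, "->", object@recommendation, "\n")
})

#' Apply the flagging rule to an imbalance result
#'
#' A gene/breakpoint is flagged — and recommended for orthogonal
#' confirmation with a targeted panel, FISH or CISH — when all three hold:
#' the fold change reaches `minFoldChange`, the retained-side mean depth
#' reaches `minRetainedDepth`, and the junction-count difference between
#' the retained and the other side reaches `minJunctionDelta`.
#'
#' @param result an [ImbalanceResult-class] from [imbalanceStatistic()].
#' @param thresholds an [ImbalanceThresholds-class].
#' @return the result with `flagged` and `recommendation` filled in.
#' @export
evaluateImbalance <- function(result, thresholds = imbalanceThresholds()) {
    side <- result@breakpoint@retainedSide
    retained <- if (side == "3prime") result@mean3 else result@mean5
    jRetained <- if (side == "3prime") result@junctions@n3 else result@junctions@n5
    jOther <- if (side == "3prime") result@junctions@n5 else result@junctions@n3
    flagged <- result@foldChange >= thresholds@minFoldChange &&
        retained >= thresholds@minRetainedDepth &&
        abs(jRetained - jOther) >= thresholds@minJunctionDelta
    result@flagged <- flagged
    result@recommendation <- if (flagged) "orthogonal_confirmation" else "none"
    methods::validObject(result)
    result
}

#' Run the full imbalance assay for one gene
#'
#' Convenience wrapper: computes stranded per-exon coverage, evaluates each
#' supplied recurrent breakpoint (or determines one automatically from the
#' expression profile), counts spliced reads around each boundary, and
#' applies the flagging rule.
#'
#' @param alignments BAM/SAM path or simulator output.
#' @param gene a [GeneModel-class].
#' @param breakpoints list of [BreakpointSpec-class] for this gene; entries
#'   for other genes are ignored.
#' @param auto if TRUE (or if no breakpoint is supplied), also evaluate an
#'   automatically determined breakpoint ([autoBreakpoint()]); the retained
#'   side is the side with the higher mean depth.
#' @param orientation library orientation, `"RF"` or `"FR"`.
#' @param thresholds an [ImbalanceThresholds-class].
#' @param lengthWeighted passed to [imbalanceStatistic()].
#' @return a list of evaluated [ImbalanceResult-class].
#' @export
runImbalanceAssay <- function(alignments, gene, breakpoints = NULL,
                              auto = FALSE, orientation = "RF",
                              thresholds = imbalanceThresholds(),
                              lengthWeighted = TRUE) {
    cov <- strandedExonCoverage(alignments, gene, orientation)
    if (methods::is(breakpoints, "BreakpointSpec"))
        breakpoints <- list(breakpoints)
    breakpoints <- Filter(function(b) geneId(b) == geneId(gene),
                          as.list(breakpoints))
    if (auto || length(breakpoints) == 0L) {
        ab <- autoBreakpoint(senseDepth(cov), epsilon = thresholds@pseudocount)
        part <- exonPartition(gene, breakpointSpec(geneId(gene),
            ab$boundaryExon, "3prime", source = "automatic", gene = gene))
        m5 <- stats::weighted.mean(senseDepth(cov)[part$fivePrime],
                                   exonWidths(gene)[part$fivePrime])
        m3 <- stats::weighted.mean(senseDepth(cov)[part$threePrime],
                                   exonWidths(gene)[part$threePrime])
        side <- if (m3 >= m5) "3prime" else "5prime"
        breakpoints <- c(breakpoints, list(breakpointSpec(geneId(gene),
            ab$boundaryExon, side, source = "automatic", gene = gene)))
    }
    lapply(breakpoints, function(bp) {
        part <- exonPartition(gene, bp)
        jc <- countSplicedReads(alignments, gene, bp, orientation)
        res <- imbalanceStatistic(cov, part, retainedSide(bp),
            epsilon = thresholds@pseudocount, junctions = jc, bp = bp,
            lengthWeighted = lengthWeighted)
        evaluateImbalance(res, thresholds)
    })
}

#' Tabulate imbalance results
#'
#' @param results a list of [ImbalanceResult-class].
#' @return a data.frame with one row per (gene, breakpoint).
#' @export
imbalanceReport <- function(results) {
    if (methods::is(results, "ImbalanceResult")) results <- list(results)
    do.call(rbind, lapply(results, function(r) data.frame(
        gene_id = r@geneId,
        boundary_exon = r@breakpoint@boundaryExon,
        source = r@breakpoint@source,
        retained_side = r@breakpoint@retainedSide,
        mean5 = r@mean5, mean3 = r@mean3,
        fold_change = r@foldChange,
        n5 = r@junctions@n5, n3 = r@junctions@n3,
        n_spanning = r@junctions@nSpanning,
        flagged = r@flagged,
        recommendation = r@recommendation,
        stringsAsFactors = FALSE)))
}

#' Write the imbalance report as TSV plus a JSON twin
#'
#' @param results list of [ImbalanceResult-class].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the report data.frame, invisibly.
#' @export
writeImbalanceReport <- function(results, prefix) {
    rep <- imbalanceReport(results)
    utils::write.table(rep, paste0(prefix, ".tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    jsonlite::write_json(rep, paste0(prefix, ".json"), auto_unbox = FALSE,
        digits = NA, pretty = TRUE)
    invisible(rep)
}
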