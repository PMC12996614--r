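#' Construct QCMetrics
#'
#' @param sampleId sample identifier.
#' @param tcc tumor cell content, percent (pathologist estimate).
#' @param rnaInput RNA input, ng.
#' @param uniqueReads unique fragments after duplicate collapsing (see
#'   [countUniqueFragments()]).
#' @param medianInsert median insert size, bp (see [medianInsertSize()]).
#' @return a [QCMetrics-class].
#' @export
qcMetrics <- function(sampleId, tcc = NA_real_, rnaInput = NA_real_,
                      uniqueReads = NA_real_, medianInsert = NA_real_) {
    methods::new("QCMetrics", sampleId = as.character(sampleId),
        tcc = as.numeric(tcc), rnaInput = as.numeric(rnaInput),
        uniqueReads = as.numeric(uniqueReads),
        medianInsert = as.numeric(medianInsert))
}

#' Construct QCThresholds
#'
#' @param minTcc minimum tumor cell content, percent (default 40).
#' @param minRnaInput minimum RNA input, ng (default 50).
#' @param minUniqueReads minimum unique fragments (default 50 million).
#' @param minMedianInsert minimum median insert size, bp (default 100).
#' @return a [QCThresholds-class].
#' @export
qcThresholds <- function(minTcc = 40, minRnaInput = 50,
                         minUniqueReads = 5e7, minMedianInsert = 100) {
    methods::new("QCThresholds", minTcc = minTcc, minRnaInput = minRnaInput,
        minUniqueReads = minUniqueReads, minMedianInsert = minMedianInsert)
}

setMethod("show", "QCDecision", function(object) {
    cat("QCDecision ", object@sampleId, ": ",
        if (object@overallPass) "PASS" else "FAIL",
        " -> ", object@routing, "\n", sep = "")
    cat("  tcc_ok=", object@tccOk, " input_ok=", object@inputOk,
        " reads_ok=", object@readsOk, " insert_ok=", object@insertOk,
        "\n", sep = "")
})

# Lower median: sorted value at position ceiling(n/2); always an observed
# integer, and deterministic for even counts.
.lowerMedian <- function(x) {
    x <- sort(x)
    x[ceiling(length(x) / 2)]
}

.insertSizesFromRecords <- function(rec) {
    rec <- .primaryRecords(rec)
    f <- rec$flag
    keep <- bitwAnd(f, .FLAG_PAIRED) > 0L & bitwAnd(f, .FLAG_PROPER) > 0L &
        !is.na(rec$tlen) & rec$tlen > 0L  # leftmost mate: one record per pair
    abs(rec$tlen[keep])
}

#' @describeIn medianInsertSize from a BAM/SAM file.
#' @export
setMethod("medianInsertSize", "character", function(alignments) {
    sizes <- .insertSizesFromRecords(.readRecords(alignments))
    if (length(sizes) == 0L) stop("no paired data")
    .lowerMedian(sizes)
})

#' @describeIn medianInsertSize from an in-memory record table.
#' @export
setMethod("medianInsertSize", "data.frame", function(alignments) {
    sizes <- .insertSizesFromRecords(alignments)
    if (length(sizes) == 0L) stop("no paired data")
    .lowerMedian(sizes)
})

#' @describeIn medianInsertSize from a simulator result list.
#' @export
setMethod("medianInsertSize", "list", function(alignments) {
    medianInsertSize(.recordsFrom(alignments))
})

.fragmentKeysFromRecords <- function(rec) {
    rec <- .primaryRecords(rec)
    f <- rec$flag
    keep <- bitwAnd(f, .FLAG_PAIRED) > 0L & bitwAnd(f, .FLAG_PROPER) > 0L &
        !is.na(rec$tlen) & rec$tlen > 0L
    rec <- rec[keep, , drop = FALSE]
    # fragment orientation: is the leftmost mate first-in-pair?
    fwd <- bitwAnd(rec$flag, .FLAG_READ1) > 0L
    paste(rec$rname, rec$pos, rec$pos + rec$tlen - 1L, fwd, sep = ":")
}

#' @describeIn countUniqueFragments from a BAM/SAM file.
#' @param asReads if TRUE, report 2x the fragment count (read pairs instead
#'   of fragments).
#' @export
setMethod("countUniqueFragments", "character",
    function(alignments, asReads = FALSE) {
        n <- length(unique(.fragmentKeysFromRecords(.readRecords(alignments))))
        if (asReads) 2L * n else n
    })

#' @describeIn countUniqueFragments from an in-memory record table.
#' @export
setMethod("countUniqueFragments", "data.frame",
    function(alignments, asReads = FALSE) {
        n <- length(unique(.fragmentKeysFromRecords(alignments)))
        if (asReads) 2L * n else n
    })

#' @describeIn countUniqueFragments from a simulator result list.
#' @export
setMethod("countUniqueFragments", "list",
    function(alignments, asReads = FALSE) {
        countUniqueFragments(.recordsFrom(alignments), asReads = asReads)
    })

#' Evaluate the four-criterion QC gate
#'
#' Compares the four metrics against their thresholds (all comparisons
#' inclusive, >=) and routes the sample: `WTS` if all four pass,
#' `targeted_panel` (the fallback assay) otherwise. Tumor cell content is
#' mandatory pre-analytics: a missing TCC is an error, never a silent pass,
#' and the same holds for the other metrics.
#'
#' @param metrics a [QCMetrics-class].
#' @param thresholds a [QCThresholds-class].
#' @return a [QCDecision-class].
#' @examples
#' m <- qcMetrics("S1", tcc = 50, rnaInput = 200, uniqueReads = 1e8,
#'                medianInsert = 135)
#' evaluateQC(m)
#' @export
evaluateQC <- function(metrics, thresholds = qcThresholds()) {
    if (is.na(metrics@tcc))
        stop("TCC required for sample ", metrics@sampleId)
    for (nm in c("rnaInput", "uniqueReads", "medianInsert"))
        if (is.na(slot(metrics, nm)))
            stop(nm, " required for sample ", metrics@sampleId)
    tccOk <- metrics@tcc >= thresholds@minTcc
    inputOk <- metrics@rnaInput >= thresholds@minRnaInput
    readsOk <- metrics@uniqueReads >= thresholds@minUniqueReads
    insertOk <- metrics@medianInsert >= thresholds@minMedianInsert
    pass <- tccOk && inputOk && readsOk && insertOk
    methods::new("QCDecision", sampleId = metrics@sampleId,
        tccOk = tccOk, inputOk = inputOk, readsOk = readsOk,
        insertOk = insertOk, overallPass = pass,
        routing = if (pass) "WTS" else "targeted_panel")
}

#' Read per-sample QC metadata
#'
#' TSV with header `sample_id`, `tcc_percent`, `rna_input_ng` and optional
#' precomputed `unique_reads` and `median_insert_bp` columns (allowing
#' ledger-only operation without alignment files).
#'
#' @param path path to the TSV.
#' @return a list of [QCMetrics-class], one per row.
#' @export
readSampleMetadata <- function(path) {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("sample_id", "tcc_percent", "rna_input_ng")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("sample metadata is missing column(s): ",
             paste(miss, collapse = ", "))
    getcol <- function(nm) {
        if (nm %in% names(tab)) tab[[nm]] else rep(NA_real_, nrow(tab))
    }
    ur <- getcol("unique_reads")
    mi <- getcol("median_insert_bp")
    lapply(seq_len(nrow(tab)), function(i) qcMetrics(
        tab$sample_id[i], tcc = tab$tcc_percent[i],
        rnaInput = tab$rna_input_ng[i],
        uniqueReads = ur[i], medianInsert = mi[i]))
}

#' Tabulate QC decisions for a set of samples
#'
#' @param metricsList list of [QCMetrics-class].
#' @param thresholds a [QCThresholds-class].
#' @return a data.frame with per-criterion flags and routing per sample.
#' @export
qcReport <- function(metricsList, thresholds = qcThresholds()) {
    if (methods::is(metricsList, "QCMetrics"))
        metricsList <- list(metricsList)
    do.call(rbind, lapply(metricsList, function(m) {
        d <- evaluateQC(m, thresholds)
        data.frame(sample_id = d@sampleId, tcc_ok = d@tccOk,
            input_ok = d@inputOk, reads_ok = d@readsOk,
            insert_ok = d@insertOk, overall_pass = d@overallPass,
            routing = d@routing, stringsAsFactors = FALSE)
    }))
}

#' Write the QC report as TSV plus a JSON twin
#'
#' @inheritParams qcReport
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the report data.frame, invisibly.
#' @export
writeQcReport <- function(metricsList, prefix, thresholds = qcThresholds()) {
    rep <- qcReport(metricsList, thresholds)
    utils::write.table(rep, paste0(prefix, ".tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    jsonlite::write_json(rep, paste0(prefix, ".json"), auto_unbox = FALSE,
        digits = NA, pretty = TRUE)
    invisible(rep)
}
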