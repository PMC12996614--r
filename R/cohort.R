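# Cohort ledger: one row per sample with QC metrics, expected fusion truth
# and the WTS outcome. Schema (TSV header): sample_id, tcc_percent,
# rna_input_ng, unique_reads, median_insert_bp, truth (gene pair or empty),
# wts_outcome in {detected, missed, negative}, panel_outcome (optional),
# and optionally n_fusions / n_fusions_called for fusion-level tallies when
# samples carry more than one fusion.

# Percentages are rounded half-up (never banker's rounding) so that printed
# clinical-report style values are stable: 98.599 -> 98.6, 91.67 -> 92.
.roundHalfUp <- function(x, digits = 1L) {
    floor(x * 10^digits + 0.5) / 10^digits
}

.pct <- function(num, den, digits = 1L) {
    if (is.na(den) || den == 0) return(NA_real_)
    .roundHalfUp(100 * num / den, digits)
}

#' Read / write a cohort ledger
#'
#' @param path TSV path.
#' @return a ledger data.frame.
#' @export
readCohortLedger <- function(path) {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    .validateLedger(tab)
    tab
}

#' @rdname readCohortLedger
#' @param ledger a ledger data.frame.
#' @export
writeCohortLedger <- function(ledger, path) {
    utils::write.table(ledger, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.validateLedger <- function(ledger) {
    need <- c("sample_id", "tcc_percent", "rna_input_ng", "unique_reads",
              "median_insert_bp", "wts_outcome")
    miss <- setdiff(need, names(ledger))
    if (length(miss))
        stop("ledger is missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(ledger) == 0L) stop("empty ledger")
    if (anyDuplicated(ledger$sample_id))
        stop("duplicate sample_id in ledger")
    if (!all(ledger$wts_outcome %in% c("detected", "missed", "negative")))
        stop("wts_outcome must be detected/missed/negative")
    hasTruth <- .ledgerTruth(ledger)
    bad <- ledger$wts_outcome %in% c("detected", "missed") & !hasTruth
    if (any(bad))
        stop("wts_outcome detected/missed requires a truth entry (sample ",
             ledger$sample_id[which(bad)[1L]], ")")
    invisible(TRUE)
}

.ledgerTruth <- function(ledger) {
    if (!("truth" %in% names(ledger))) return(rep(FALSE, nrow(ledger)))
    !is.na(ledger$truth) & nzchar(as.character(ledger$truth))
}

.ledgerQc <- function(ledger, thresholds) {
    data.frame(
        sample_id = ledger$sample_id,
        tcc_ok = ledger$tcc_percent >= thresholds@minTcc,
        input_ok = ledger$rna_input_ng >= thresholds@minRnaInput,
        reads_ok = ledger$unique_reads >= thresholds@minUniqueReads,
        insert_ok = ledger$median_insert_bp >= thresholds@minMedianInsert,
        stringsAsFactors = FALSE)
}

#' Summarize a cohort ledger
#'
#' Computes the headline statistics of a diagnostic cohort: fusion
#' detection rate, sample-level concordance (detected positives plus
#' confirmed negatives), fusion-level call rate, the per-criterion QC
#' failure breakdown, concordance restricted to QC-passing samples, and the
#' fallback-routing tally. QC evaluation delegates to the same inclusive
#' four-criterion gate as [evaluateQC()].
#'
#' @param ledger a cohort ledger data.frame (see [readCohortLedger()]).
#' @param thresholds a [QCThresholds-class].
#' @param integerPct if TRUE, report the detection rate as an integer
#'   percent (the style used for small evaluation cohorts).
#' @return a [CohortSummary-class].
#' @export
summarizeCohort <- function(ledger, thresholds = qcThresholds(),
                            integerPct = FALSE) {
    .validateLedger(ledger)
    n <- nrow(ledger)
    hasTruth <- .ledgerTruth(ledger)
    nPos <- sum(hasTruth)
    nDet <- sum(ledger$wts_outcome == "detected")
    detRate <- .pct(nDet, nPos, digits = if (integerPct) 0L else 1L)

    concordant <- (hasTruth & ledger$wts_outcome == "detected") |
        (!hasTruth & ledger$wts_outcome == "negative")
    nConc <- sum(concordant)

    nFus <- if ("n_fusions" %in% names(ledger))
        sum(ledger$n_fusions) else nPos
    nFusCalled <- if ("n_fusions_called" %in% names(ledger))
        sum(ledger$n_fusions_called) else nDet

    qc <- .ledgerQc(ledger, thresholds)
    passAll <- qc$tcc_ok & qc$input_ok & qc$reads_ok & qc$insert_ok
    failCounts <- c(tcc = sum(!qc$tcc_ok), input = sum(!qc$input_ok),
                    reads = sum(!qc$reads_ok), insert = sum(!qc$insert_ok))
    nFail <- sum(!passAll)

    concQcPass <- .pct(sum(concordant & passAll), sum(passAll))

    methods::new("CohortSummary",
        nSamples = n, nFusionPositive = as.integer(nPos),
        nDetected = as.integer(nDet), detectionRatePct = detRate,
        nConcordantSamples = as.integer(nConc),
        sampleConcordancePct = .pct(nConc, n),
        nFusionsTotal = as.integer(nFus),
        nFusionsCalled = as.integer(nFusCalled),
        fusionCallRatePct = .pct(nFusCalled, nFus),
        qcFailCounts = as.integer(failCounts) |>
            stats::setNames(names(failCounts)),
        nQcFail = as.integer(nFail), qcFailPct = .pct(nFail, n),
        nQcPass = as.integer(n - nFail), qcPassPct = .pct(n - nFail, n),
        concordanceAmongQcPassPct = concQcPass,
        nRoutedPanel = as.integer(nFail), routedPanelPct = .pct(nFail, n))
}

setMethod("show", "CohortSummary", function(object) {
    cat("CohortSummary over", object@nSamples, "samples\n")
    cat(sprintf("  fusion-positive: %d, detected: %d (%s%%)\n",
        object@nFusionPositive, object@nDetected,
        format(object@detectionRatePct)))
    cat(sprintf("  sample concordance: %d/%d (%s%%)\n",
        object@nConcordantSamples, object@nSamples,
        format(object@sampleConcordancePct)))
    cat(sprintf("  fusions called: %d/%d (%s%%)\n",
        object@nFusionsCalled, object@nFusionsTotal,
        format(object@fusionCallRatePct)))
    cat(sprintf("  QC fail: %d (%s%%) [tcc %d, input %d, reads %d, insert %d]; pass: %d (%s%%)\n",
        object@nQcFail, format(object@qcFailPct),
        object@qcFailCounts[["tcc"]], object@qcFailCounts[["input"]],
        object@qcFailCounts[["reads"]], object@qcFailCounts[["insert"]],
        object@nQcPass, format(object@qcPassPct)))
    cat(sprintf("  concordance among QC-pass: %s%%; routed to panel: %d (%s%%)\n",
        format(object@concordanceAmongQcPassPct), object@nRoutedPanel,
        format(object@routedPanelPct)))
})

#' Per-sample routing table and tallies
#'
#' Applies the QC gate to every ledger row and tallies how many samples are
#' routed to the fallback targeted panel.
#'
#' @inheritParams summarizeCohort
#' @return a list with `table` (per-sample flags and routing),
#'   `nRoutedPanel` and `routedPanelPct`.
#' @export
routeSamples <- function(ledger, thresholds = qcThresholds()) {
    .validateLedger(ledger)
    qc <- .ledgerQc(ledger, thresholds)
    pass <- qc$tcc_ok & qc$input_ok & qc$reads_ok & qc$insert_ok
    qc$overall_pass <- pass
    qc$routing <- ifelse(pass, "WTS", "targeted_panel")
    list(table = qc, nRoutedPanel = sum(!pass),
         routedPanelPct = .pct(sum(!pass), nrow(ledger)))
}

#' Export a cohort summary
#'
#' @param summary a [CohortSummary-class].
#' @param prefix output prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return a one-row data.frame of the summary fields, invisibly.
#' @export
writeCohortSummary <- function(summary, prefix) {
    df <- data.frame(
        n_samples = summary@nSamples,
        n_fusion_positive = summary@nFusionPositive,
        n_detected = summary@nDetected,
        detection_rate_pct = summary@detectionRatePct,
        n_concordant_samples = summary@nConcordantSamples,
        sample_concordance_pct = summary@sampleConcordancePct,
        n_fusions_total = summary@nFusionsTotal,
        n_fusions_called = summary@nFusionsCalled,
        fusion_call_rate_pct = summary@fusionCallRatePct,
        qc_fail_tcc = summary@qcFailCounts[["tcc"]],
        qc_fail_input = summary@qcFailCounts[["input"]],
        qc_fail_reads = summary@qcFailCounts[["reads"]],
        qc_fail_insert = summary@qcFailCounts[["insert"]],
        n_qc_fail = summary@nQcFail, qc_fail_pct = summary@qcFailPct,
        n_qc_pass = summary@nQcPass, qc_pass_pct = summary@qcPassPct,
        concordance_among_qc_pass_pct = summary@concordanceAmongQcPassPct,
        n_routed_panel = summary@nRoutedPanel,
        routed_panel_pct = summary@routedPanelPct)
    utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(as.list(df), paste0(prefix, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(df)
}
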