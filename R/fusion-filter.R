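# Fusion calls are handled as plain data.frames with a fixed column set:
# sample_id, gene5, gene3, contig5, pos5, contig3, pos3, support_reads,
# caller, event_type, status, callers, manual_review. One table serves both
# fusion callers and splicing-event callers (splice variants such as MET
# exon-14 skipping are rows with gene5 == gene3 and
# event_type == "splice_variant"), so a single filter path covers both.

.FUSION_COLS <- c("sample_id", "gene5", "gene3", "contig5", "pos5",
                  "contig3", "pos3", "support_reads", "caller", "event_type",
                  "status", "callers", "manual_review")

.emptyCalls <- function() {
    data.frame(sample_id = character(), gene5 = character(),
        gene3 = character(), contig5 = character(), pos5 = integer(),
        contig3 = character(), pos3 = integer(), support_reads = integer(),
        caller = character(), event_type = character(), status = character(),
        callers = character(), manual_review = character(),
        stringsAsFactors = FALSE)
}

.splitBreakpoint <- function(x) {
    # "chr2:29446394" -> contig, position
    contig <- sub(":[^:]*$", "", x)
    pos <- suppressWarnings(as.integer(sub("^.*:", "", x)))
    list(contig = ifelse(is.na(x) | x == "" | x == ".", NA_character_, contig),
         pos = pos)
}

#' Construct a GeneSet
#'
#' @param genes character vector of gene symbols.
#' @param minSupport minimum supporting read count for a call to pass
#'   (1 for a validated diagnostic set; 10 for an expanded exploratory set).
#' @param name set name.
#' @return a [GeneSet-class].
#' @export
geneSet <- function(genes, minSupport = 1L, name = "gene_set") {
    methods::new("GeneSet", name = name, genes = unique(as.character(genes)),
        minSupport = as.integer(minSupport))
}

#' Read a gene-set file
#'
#' One gene symbol per line; lines starting with `#` are comments.
#'
#' @param path path to the file.
#' @inheritParams geneSet
#' @return a [GeneSet-class].
#' @export
readGeneSet <- function(path, minSupport = 1L, name = basename(path)) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    geneSet(lines, minSupport = minSupport, name = name)
}

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "': ", length(object@genes),
        " genes, min support ", object@minSupport, "\n", sep = "")
})

#' Parse a fusion-caller output table
#'
#' Supports two dialects. `"arriba"` expects the ARRIBA-style columns
#' `gene1`, `gene2`, `split_reads1`, `split_reads2`, `discordant_mates`,
#' `breakpoint1`, `breakpoint2` (a leading `#` on the header is tolerated);
#' supporting reads are the sum of the two split-read counts and the
#' discordant mates. `"generic"` expects `sample_id`, `gene5`, `gene3`,
#' `support_reads`, `event_type` and optional `breakpoint5`, `breakpoint3`
#' — the dialect used for panel outputs and splicing callers.
#'
#' @param path path to the TSV.
#' @param dialect `"arriba"` or `"generic"`.
#' @param sampleId sample identifier to assign (arriba tables carry none).
#' @param caller caller label recorded on each call.
#' @return a data.frame of calls with `status = "raw"`.
#' @export
parseFusionTable <- function(path, dialect = c("arriba", "generic"),
                             sampleId = NA_character_, caller = NULL) {
    dialect <- match.arg(dialect)
    first <- readLines(path, n = 1L)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "")
    names(tab)[1L] <- sub("^#", "", names(tab)[1L])
    if (nrow(tab) == 0L) return(.emptyCalls())
    if (dialect == "arriba") {
        need <- c("gene1", "gene2", "split_reads1", "split_reads2",
                  "discordant_mates", "breakpoint1", "breakpoint2")
        miss <- setdiff(need, names(tab))
        if (length(miss))
            stop("arriba table is missing column(s): ",
                 paste(miss, collapse = ", "))
        b1 <- .splitBreakpoint(tab$breakpoint1)
        b2 <- .splitBreakpoint(tab$breakpoint2)
        out <- data.frame(
            sample_id = rep(as.character(sampleId), nrow(tab)),
            gene5 = tab$gene1, gene3 = tab$gene2,
            contig5 = b1$contig, pos5 = b1$pos,
            contig3 = b2$contig, pos3 = b2$pos,
            support_reads = as.integer(tab$split_reads1 + tab$split_reads2 +
                                       tab$discordant_mates),
            caller = if (is.null(caller)) "arriba" else caller,
            event_type = "fusion", stringsAsFactors = FALSE)
    } else {
        need <- c("sample_id", "gene5", "gene3", "support_reads",
                  "event_type")
        miss <- setdiff(need, names(tab))
        if (length(miss))
            stop("generic fusion table is missing column(s): ",
                 paste(miss, collapse = ", "))
        b1 <- if ("breakpoint5" %in% names(tab))
            .splitBreakpoint(tab$breakpoint5)
        else list(contig = rep(NA_character_, nrow(tab)),
                  pos = rep(NA_integer_, nrow(tab)))
        b2 <- if ("breakpoint3" %in% names(tab))
            .splitBreakpoint(tab$breakpoint3)
        else list(contig = rep(NA_character_, nrow(tab)),
                  pos = rep(NA_integer_, nrow(tab)))
        out <- data.frame(
            sample_id = as.character(tab$sample_id),
            gene5 = tab$gene5, gene3 = tab$gene3,
            contig5 = b1$contig, pos5 = b1$pos,
            contig3 = b2$contig, pos3 = b2$pos,
            support_reads = as.integer(tab$support_reads),
            caller = if (is.null(caller)) "other" else caller,
            event_type = as.character(tab$event_type),
            stringsAsFactors = FALSE)
    }
    if (any(!out$event_type %in% c("fusion", "splice_variant")))
        stop("event_type must be 'fusion' or 'splice_variant'")
    if (any(is.na(out$support_reads)) || any(out$support_reads < 0L))
        stop("support_reads must be non-negative integers")
    out$status <- "raw"
    out$callers <- out$caller
    out$manual_review <- "pending"
    out[, .FUSION_COLS]
}

#' Apply read-support and gene-set filters
#'
#' A call passes iff its supporting reads reach the set's minimum support
#' and at least one partner gene is in the set. Calls are never dropped:
#' failing calls are kept with `status = "filtered_fail"` and row order is
#' preserved, so filtering is idempotent and auditable.
#'
#' @param calls a calls data.frame from [parseFusionTable()].
#' @param gene_set a [GeneSet-class].
#' @return the calls with `status` set to `"filtered_pass"`/`"filtered_fail"`.
#' @export
applyFilters <- function(calls, gene_set) {
    if (nrow(calls) == 0L) return(calls)
    pass <- calls$support_reads >= gene_set@minSupport &
        (calls$gene5 %in% gene_set@genes | calls$gene3 %in% gene_set@genes)
    calls$status <- ifelse(pass, "filtered_pass", "filtered_fail")
    calls
}

.pairKey <- function(g5, g3) {
    paste(pmin(g5, g3), pmax(g5, g3), sep = "::")
}

#' Merge calls from parallel callers
#'
#' Calls agreeing on the unordered gene pair — and, when both report
#' breakpoints, on the positions within `tolerance` bp — are merged into a
#' single record keeping the maximum support and the union of callers. No
#' call is fabricated or lost: the number of distinct gene pairs never
#' increases and merged support never exceeds the maximum input support.
#'
#' @param ... calls data.frames (one per caller), or a single list of them.
#' @param tolerance breakpoint agreement tolerance in bp (default 10).
#' @return a merged calls data.frame.
#' @export
mergeCallers <- function(..., tolerance = 10L) {
    args <- list(...)
    if (length(args) == 1L && is.list(args[[1L]]) &&
        !is.data.frame(args[[1L]]))
        args <- args[[1L]]
    calls <- do.call(rbind, args)
    if (is.null(calls) || nrow(calls) == 0L) return(.emptyCalls())
    merged <- calls[0L, , drop = FALSE]
    canMerge <- function(a, b) {
        if (a$sample_id != b$sample_id) return(FALSE)
        if (.pairKey(a$gene5, a$gene3) != .pairKey(b$gene5, b$gene3))
            return(FALSE)
        if (a$event_type != b$event_type) return(FALSE)
        # orient b to a's gene order before comparing breakpoints
        flipped <- a$gene5 != b$gene5
        bp5 <- if (flipped) b$pos3 else b$pos5
        bc5 <- if (flipped) b$contig3 else b$contig5
        bp3 <- if (flipped) b$pos5 else b$pos3
        bc3 <- if (flipped) b$contig5 else b$contig3
        both5 <- !is.na(a$pos5) && !is.na(bp5)
        both3 <- !is.na(a$pos3) && !is.na(bp3)
        if (both5 && (!identical(a$contig5, bc5) ||
                      abs(a$pos5 - bp5) > tolerance)) return(FALSE)
        if (both3 && (!identical(a$contig3, bc3) ||
                      abs(a$pos3 - bp3) > tolerance)) return(FALSE)
        TRUE
    }
    for (i in seq_len(nrow(calls))) {
        row <- calls[i, , drop = FALSE]
        hit <- 0L
        for (j in seq_len(nrow(merged))) {
            if (canMerge(merged[j, , drop = FALSE], row)) { hit <- j; break }
        }
        if (hit == 0L) {
            merged <- rbind(merged, row)
        } else {
            merged$support_reads[hit] <- max(merged$support_reads[hit],
                                             row$support_reads)
            merged$callers[hit] <- paste(sort(unique(c(
                strsplit(merged$callers[hit], ",")[[1L]],
                strsplit(row$callers, ",")[[1L]]))), collapse = ",")
        }
    }
    rownames(merged) <- NULL
    merged
}

#' Compare observed calls with a panel truth call
#'
#' Matching is on the unordered gene pair (panel reports and WTS callers
#' can disagree on 5'/3' orientation for reciprocal events); splice variants
#' match on gene and event type. Only calls with
#' `status = "filtered_pass"` count as observed.
#'
#' Outcomes: `true_positive` if the expected call is matched;
#' `false_negative` if expected but unmatched; `true_negative` if nothing
#' was expected and nothing passed; `false_positive` otherwise.
#'
#' @param observed filtered calls data.frame for one sample.
#' @param expected a one-row truth data.frame (columns `gene5`, `gene3`,
#'   `event_type`) or NULL for an expected-negative sample.
#' @param sampleId sample identifier for the record.
#' @return a one-row data.frame: `sample_id`, `expected_pair`, `n_observed`,
#'   `outcome`.
#' @export
matchToTruth <- function(observed, expected = NULL, sampleId = NULL) {
    obs <- observed[observed$status == "filtered_pass", , drop = FALSE]
    if (is.null(sampleId))
        sampleId <- if (nrow(observed)) observed$sample_id[1L]
                    else if (!is.null(expected) && "sample_id" %in% names(expected))
                        expected$sample_id[1L]
                    else NA_character_
    if (!is.null(expected) && nrow(expected) > 0L) {
        expKey <- .pairKey(expected$gene5[1L], expected$gene3[1L])
        expType <- expected$event_type[1L]
        matched <- nrow(obs) > 0L &&
            any(.pairKey(obs$gene5, obs$gene3) == expKey &
                obs$event_type == expType)
        outcome <- if (matched) "true_positive" else "false_negative"
        pair <- expKey
    } else {
        outcome <- if (nrow(obs) == 0L) "true_negative" else "false_positive"
        pair <- NA_character_
    }
    data.frame(sample_id = sampleId, expected_pair = pair,
        n_observed = nrow(obs), outcome = outcome, stringsAsFactors = FALSE)
}
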