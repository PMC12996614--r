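#' Construct a SimConfig
#'
#' Defaults describe the assay's canonical situation: a fusion transcript at
#' ~7x coverage in pure tumor expressed only on the retained side of the
#' breakpoint, a 0.03x full-length wild-type background, no antisense
#' contamination, and FFPE-like inserts (log-normal, median 129 bp).
#'
#' @param gene a [GeneModel-class].
#' @param breakpoint a [BreakpointSpec-class] or NULL (wild-type sample).
#' @param tcc tumor cell content, percent; the fusion expression is scaled
#'   by `tcc / 100` (the wild-type background is present in all cells).
#' @param fusionExpression x coverage of the fusion transcript in pure tumor.
#' @param wildtypeExpression x coverage of the full-length transcript.
#' @param antisenseDepth x coverage of unspliced opposite-strand pre-mRNA
#'   contamination (the neighboring-gene confounder).
#' @param antisenseSpan genomic interval of the contamination (default: the
#'   gene's genomic span, introns included, as pre-mRNA would).
#' @param insertMedian,insertSd insert-size distribution, bp.
#' @param readLength read length, bp.
#' @param seed integer RNG seed; identical configs give byte-identical SAM.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(gene, breakpoint = NULL, tcc = 100,
                      fusionExpression = 7, wildtypeExpression = 0.03,
                      antisenseDepth = 0, antisenseSpan = integer(),
                      insertMedian = 129, insertSd = 8, readLength = 50L,
                      seed) {
    methods::new("SimConfig", gene = gene, breakpoint = breakpoint,
        tcc = tcc, fusionExpression = fusionExpression,
        wildtypeExpression = wildtypeExpression,
        antisenseDepth = antisenseDepth,
        antisenseSpan = as.integer(antisenseSpan),
        insertMedian = insertMedian, insertSd = insertSd,
        readLength = as.integer(readLength), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig for", geneId(object@gene),
        if (is.null(object@breakpoint)) "(wild-type)" else
            paste0("(fusion after exon ", object@breakpoint@boundaryExon, ")"),
        "\n")
    cat(sprintf(
        "  tcc %.0f%%, fusion %.2fx, wildtype %.2fx, antisense %.2fx, insert %g+/-%g bp, seed %d\n",
        object@tcc, object@fusionExpression, object@wildtypeExpression,
        object@antisenseDepth, object@insertMedian, object@insertSd,
        object@seed))
})

# ---- transcript geometry -------------------------------------------------

# Blocks of a transcript built from exon indices (transcription order):
# genomic 1-based [gstart, gend] per exon plus cumulative transcript offsets.
.transcriptBlocks <- function(gene, exonIdx) {
    ex <- exonRanges(gene)[exonIdx]
    w <- IRanges::width(ex)
    list(gstart = IRanges::start(ex), gend = IRanges::end(ex), width = w,
         offset = cumsum(c(0L, w[-length(w)])), length = sum(w),
         strand = geneStrand(gene))
}

# Map a read interval [t0, t0 + len) in transcript coordinates (0-based) to
# ascending genomic blocks; returns POS (1-based leftmost) and CIGAR.
.mapReadToGenome <- function(blocks, t0, len) {
    t1 <- t0 + len  # exclusive
    hit <- which(blocks$offset < t1 & blocks$offset + blocks$width > t0)
    gs <- ge <- integer(length(hit))
    for (i in seq_along(hit)) {
        e <- hit[i]
        lo <- max(t0, blocks$offset[e]) - blocks$offset[e]
        hi <- min(t1, blocks$offset[e] + blocks$width[e]) - blocks$offset[e]
        if (blocks$strand == "+") {
            gs[i] <- blocks$gstart[e] + lo
            ge[i] <- blocks$gstart[e] + hi - 1L
        } else {
            gs[i] <- blocks$gend[e] - hi + 1L
            ge[i] <- blocks$gend[e] - lo
        }
    }
    ord <- order(gs)
    gs <- gs[ord]; ge <- ge[ord]
    cig <- character(2L * length(gs) - 1L)
    cig[seq(1L, length(cig), by = 2L)] <- paste0(ge - gs + 1L, "M")
    if (length(gs) > 1L)
        cig[seq(2L, length(cig), by = 2L)] <-
            paste0(gs[-1L] - ge[-length(ge)] - 1L, "N")
    list(pos = gs[1L], cigar = paste(cig, collapse = ""))
}

# ---- insert-size model ---------------------------------------------------

# Fragment lengths are log-normal with meanlog = log(median) (the median of
# a log-normal is exp(meanlog)) and sdlog = insertSd / insertMedian, rounded
# to integers and clamped to [minLen, maxLen].
.drawInsertLengths <- function(n, median, sd, minLen, maxLen) {
    fl <- round(stats::rlnorm(n, meanlog = log(median), sdlog = sd / median))
    pmin(pmax(as.integer(fl), minLen), maxLen)
}

# Exact pmf of the drawn lengths (discretized + clamped log-normal).
.insertPmf <- function(median, sd, minLen, maxLen) {
    if (maxLen <= minLen)
        return(list(len = minLen, p = 1))
    len <- minLen:maxLen
    sdlog <- sd / median
    hi <- stats::plnorm(len + 0.5, log(median), sdlog)
    lo <- stats::plnorm(len - 0.5, log(median), sdlog)
    p <- hi - lo
    p[1L] <- hi[1L]                      # everything rounding below minLen
    p[length(p)] <- 1 - lo[length(lo)]   # everything rounding above maxLen
    list(len = len, p = p)
}

# Expected per-base coverage profile (transcript space) contributed by ONE
# fragment, marginalised over start position and fragment length. Accounts
# for the end effects of placing fragments fully inside the transcript,
# and for mate overlap (each mate counts separately in a read pileup).
.expectedCoverageProfile <- function(L, R, pmf) {
    t <- 0:(L - 1L)
    prof <- numeric(L)
    for (i in seq_along(pmf$len)) {
        fl <- pmf$len[i]
        p <- pmf$p[i]
        if (p <= 0 || fl > L) next
        reff <- min(R, fl)
        nStarts <- L - fl + 1L
        n1 <- pmin(t, L - fl) - pmax(0L, t - reff + 1L) + 1L
        n2 <- pmin(t - fl + reff, L - fl) - pmax(0L, t - fl + 1L) + 1L
        prof <- prof + p * (pmax(n1, 0L) + pmax(n2, 0L)) / nStarts
    }
    prof
}

# ---- sample generation ---------------------------------------------------

.samHeader <- function(chrom, len) {
    c("@HD\tVN:1.6\tSO:coordinate",
      paste0("@SQ\tSN:", chrom, "\tLN:", len))
}

# Generate all records for one transcript class. `blocks` defines the
# transcript; `senseStrand` is its genomic strand; `n` fragments are drawn.
.simulateClass <- function(blocks, senseStrand, n, prefix, chrom, cfg) {
    if (n == 0L) return(.emptyRecords())
    L <- blocks$length
    R <- cfg@readLength
    maxLen <- min(L, as.integer(round(3 * cfg@insertMedian)))
    fl <- .drawInsertLengths(n, cfg@insertMedian, cfg@insertSd, R, maxLen)
    u <- as.integer(floor(stats::runif(n) * (L - fl + 1)))
    u <- pmin(u, L - fl)
    reff <- pmin(R, fl)
    qname <- sprintf("%s%06d", prefix, seq_len(n))
    rec <- vector("list", 2L * n)
    for (i in seq_len(n)) {
        m5 <- .mapReadToGenome(blocks, u[i], reff[i])           # transcript 5' mate
        m3 <- .mapReadToGenome(blocks, u[i] + fl[i] - reff[i], reff[i])
        if (senseStrand == "+") { left <- m5; right <- m3 }
        else { left <- m3; right <- m5 }
        # RF chemistry: second-in-pair aligns on the transcript strand.
        senseIsLeft <- senseStrand == "+"
        leftFlag <- .FLAG_PAIRED + .FLAG_PROPER + .FLAG_MATE_REVERSE +
            if (senseIsLeft) .FLAG_READ2 else .FLAG_READ1
        rightFlag <- .FLAG_PAIRED + .FLAG_PROPER + .FLAG_REVERSE +
            if (senseIsLeft) .FLAG_READ1 else .FLAG_READ2
        rec[[2L * i - 1L]] <- list(qname = qname[i], flag = leftFlag,
            pos = left$pos, cigar = left$cigar, tlen = fl[i],
            pnext = right$pos, seqlen = reff[i])
        rec[[2L * i]] <- list(qname = qname[i], flag = rightFlag,
            pos = right$pos, cigar = right$cigar, tlen = -fl[i],
            pnext = left$pos, seqlen = reff[i])
    }
    data.frame(
        qname = vapply(rec, `[[`, character(1), "qname"),
        flag = as.integer(vapply(rec, `[[`, numeric(1), "flag")),
        rname = chrom,
        pos = as.integer(vapply(rec, `[[`, numeric(1), "pos")),
        mapq = 60L,
        cigar = vapply(rec, `[[`, character(1), "cigar"),
        tlen = as.integer(vapply(rec, `[[`, numeric(1), "tlen")),
        pnext = as.integer(vapply(rec, `[[`, numeric(1), "pnext")),
        seqlen = as.integer(vapply(rec, `[[`, numeric(1), "seqlen")),
        stringsAsFactors = FALSE)
}

#' Simulate one stranded paired-end RNA-seq sample
#'
#' Draws Poisson fragment counts per transcript class (fusion, wild-type,
#' antisense pre-mRNA), places fragments uniformly along each transcript
#' with log-normal insert lengths, and emits splice-consistent gapped
#' alignments on the correct strand under the RF (reverse-stranded) library
#' convention. Fusion fragments are restricted to the retained side of the
#' breakpoint; the fusion partner's sequence is never simulated (the assay
#' does not need it). Template length records the sequenced fragment
#' length. Identical configs (including seed) produce byte-identical SAM.
#'
#' @param config a [SimConfig-class].
#' @param samPath optional path; when given, the SAM text is written there.
#' @return a list with `records` (the alignment record table), `sam`
#'   (SAM text lines), `truth` (a [SimTruth-class]) and `samPath`.
#' @examples
#' gm <- geneModel("ALK", "chr2", "-",
#'                 cbind(seq(1000, 34000, by = 1000),
#'                       seq(1150, 34150, by = 1000)))
#' bp <- breakpointSpec("ALK", 19, "3prime", gene = gm)
#' sim <- simulateSample(simConfig(gm, bp, tcc = 50, seed = 1))
#' truthExpectedDepth(sim$truth)[c(1, 20)]
#' @export
simulateSample <- function(config, samPath = NULL) {
    methods::validObject(config)
    gene <- config@gene
    bp <- config@breakpoint
    R <- config@readLength
    set.seed(config@seed)

    # transcript classes: (blocks, genomic strand, target depth, prefix)
    classes <- list()
    n <- exonCount(gene)
    allBlocks <- .transcriptBlocks(gene, seq_len(n))
    fusionIdx <- integer()
    if (!is.null(bp) && config@fusionExpression > 0 && config@tcc > 0) {
        part <- exonPartition(gene, bp)
        fusionIdx <- if (retainedSide(bp) == "3prime") part$threePrime
                     else part$fivePrime
        classes$fusion <- list(
            blocks = .transcriptBlocks(gene, fusionIdx),
            strand = geneStrand(gene),
            depth = config@fusionExpression * config@tcc / 100,
            prefix = "FUS")
    }
    if (config@wildtypeExpression > 0) {
        classes$wildtype <- list(blocks = allBlocks,
            strand = geneStrand(gene),
            depth = config@wildtypeExpression, prefix = "WT")
    }
    if (config@antisenseDepth > 0) {
        span <- config@antisenseSpan
        if (length(span) == 0L) {
            ex <- exonRanges(gene)
            span <- c(min(IRanges::start(ex)), max(IRanges::end(ex)))
        }
        asStrand <- .flipStrand(geneStrand(gene))
        asBlocks <- list(gstart = span[1L], gend = span[2L],
            width = span[2L] - span[1L] + 1L, offset = 0L,
            length = span[2L] - span[1L] + 1L, strand = asStrand)
        classes$antisense <- list(blocks = asBlocks, strand = asStrand,
            depth = config@antisenseDepth, prefix = "AS")
    }

    counts <- c(fusion = 0L, wildtype = 0L, antisense = 0L)
    recs <- list()
    for (nm in names(classes)) {
        cl <- classes[[nm]]
        L <- cl$blocks$length
        if (L < R)
            stop("infeasible geometry: transcript of class '", nm,
                 "' is shorter (", L, " bp) than the read length")
        nExp <- cl$depth * L / (2 * R)
        nFrag <- stats::rpois(1L, nExp)
        counts[nm] <- nFrag
        recs[[nm]] <- .simulateClass(cl$blocks, cl$strand, nFrag,
                                     cl$prefix, geneChrom(gene), config)
    }
    rec <- do.call(rbind, recs)
    if (is.null(rec) || nrow(rec) == 0L) {
        rec <- .emptyRecords()
        rec$pnext <- integer(); rec$seqlen <- integer()
    }
    rec <- rec[order(rec$pos, rec$qname, rec$flag), , drop = FALSE]
    rownames(rec) <- NULL

    # analytic expectation of the sense per-exon mean depth
    expDepth <- numeric(n)
    for (nm in intersect(c("fusion", "wildtype"), names(classes))) {
        cl <- classes[[nm]]
        L <- cl$blocks$length
        maxLen <- min(L, as.integer(round(3 * config@insertMedian)))
        pmf <- .insertPmf(config@insertMedian, config@insertSd, R, maxLen)
        prof <- .expectedCoverageProfile(L, R, pmf)
        nExp <- cl$depth * L / (2 * R)
        idx <- if (nm == "fusion") fusionIdx else seq_len(n)
        for (j in seq_along(idx)) {
            a <- cl$blocks$offset[j] + 1L
            b <- cl$blocks$offset[j] + cl$blocks$width[j]
            expDepth[idx[j]] <- expDepth[idx[j]] + nExp * mean(prof[a:b])
        }
    }

    ex <- exonRanges(gene)
    contigLen <- max(max(IRanges::end(ex)),
                     if (length(config@antisenseSpan)) config@antisenseSpan[2L]
                     else 0L) + 1000L
    sam <- c(.samHeader(geneChrom(gene), contigLen),
        if (nrow(rec) > 0L) sprintf(
            "%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t*",
            rec$qname, as.integer(rec$flag), rec$rname, as.integer(rec$pos),
            as.integer(rec$mapq), rec$cigar, as.integer(rec$pnext),
            as.integer(rec$tlen),
            strrep("A", as.integer(rec$seqlen))))
    if (!is.null(samPath)) writeLines(sam, samPath)

    truth <- methods::new("SimTruth", config = config,
        nFusionFragments = counts[["fusion"]],
        nWildtypeFragments = counts[["wildtype"]],
        nAntisenseFragments = counts[["antisense"]],
        boundaryExon = if (is.null(bp)) NA_integer_ else boundaryExon(bp),
        expectedSenseDepth = expDepth)
    list(records = rec[, c("qname", "flag", "rname", "pos", "mapq",
                           "cigar", "tlen")],
         sam = sam, truth = truth, samPath = samPath)
}

#' @describeIn simulateSample analytic expected sense mean depth per exon.
#' @param x a `SimTruth`.
#' @export
truthExpectedDepth <- function(x) x@expectedSenseDepth

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", object@nFusionFragments, "fusion,",
        object@nWildtypeFragments, "wild-type,",
        object@nAntisenseFragments, "antisense fragments; boundary exon",
        object@boundaryExon, "\n")
})

#' Simulate a cohort with known truth
#'
#' Draws per-sample tumor cell content, RNA input and fusion status, runs
#' the simulator and the imbalance assay on each sample, and assembles a
#' cohort ledger compatible with [summarizeCohort()] and [routeSamples()].
#' The unique-fragment count and median insert size in the ledger are
#' computed from the generated alignments, not echoed from the config.
#'
#' @param nSamples number of samples (>= 1).
#' @param gene a [GeneModel-class].
#' @param breakpoint a [BreakpointSpec-class] used for fusion-positive
#'   samples and as the assay's recurrent breakpoint.
#' @param prevalence probability that a sample carries the fusion.
#' @param tccSampler function(n) returning n TCC percentages.
#' @param rnaInputSampler function(n) returning n RNA inputs (ng).
#' @param fusionExpression,wildtypeExpression,antisenseDepth,insertMedian,insertSd,readLength
#'   passed to [simConfig()].
#' @param thresholds an [ImbalanceThresholds-class] for the assay.
#' @param seed cohort seed; per-sample seeds are derived from it.
#' @param dir optional output directory; when given, per-sample SAM and
#'   truth JSON files are written there and their paths recorded.
#' @return the cohort ledger data.frame (columns `sample_id`,
#'   `tcc_percent`, `rna_input_ng`, `unique_reads`, `median_insert_bp`,
#'   `truth`, `wts_outcome`, `panel_outcome`, plus file paths when `dir` is
#'   given).
#' @export
simulateCohort <- function(nSamples, gene, breakpoint, prevalence = 0.5,
                           tccSampler = function(n) stats::runif(n, 10, 90),
                           rnaInputSampler = function(n) stats::runif(n, 50, 200),
                           fusionExpression = 7, wildtypeExpression = 0.03,
                           antisenseDepth = 0, insertMedian = 129,
                           insertSd = 8, readLength = 50L,
                           thresholds = imbalanceThresholds(), seed,
                           dir = NULL) {
    stopifnot(nSamples >= 1L)
    set.seed(as.integer(seed))
    tcc <- round(tccSampler(nSamples))
    rna <- round(rnaInputSampler(nSamples), 1)
    hasFusion <- stats::rbinom(nSamples, 1L, prevalence) == 1L
    seeds <- sample.int(.Machine$integer.max - 1L, nSamples)
    rows <- vector("list", nSamples)
    for (i in seq_len(nSamples)) {
        cfg <- simConfig(gene,
            breakpoint = if (hasFusion[i]) breakpoint else NULL,
            tcc = tcc[i], fusionExpression = fusionExpression,
            wildtypeExpression = wildtypeExpression,
            antisenseDepth = antisenseDepth, insertMedian = insertMedian,
            insertSd = insertSd, readLength = readLength, seed = seeds[i])
        sid <- sprintf("SIM%04d", i)
        samPath <- if (!is.null(dir)) file.path(dir, paste0(sid, ".sam"))
        sim <- simulateSample(cfg, samPath = samPath)
        uniq <- countUniqueFragments(sim$records)
        mins <- tryCatch(medianInsertSize(sim$records),
                         error = function(e) NA_integer_)
        res <- runImbalanceAssay(sim, gene, breakpoint,
                                 thresholds = thresholds)[[1L]]
        outcome <- if (hasFusion[i]) {
            if (isFlagged(res)) "detected" else "missed"
        } else "negative"
        if (!is.null(dir)) {
            jsonlite::write_json(list(sample_id = sid, tcc = tcc[i],
                fusion = hasFusion[i],
                boundary_exon = sim$truth@boundaryExon,
                n_fusion_fragments = sim$truth@nFusionFragments,
                n_wildtype_fragments = sim$truth@nWildtypeFragments,
                expected_sense_depth = sim$truth@expectedSenseDepth),
                file.path(dir, paste0(sid, ".truth.json")),
                auto_unbox = TRUE, digits = NA)
        }
        rows[[i]] <- data.frame(sample_id = sid, tcc_percent = tcc[i],
            rna_input_ng = rna[i], unique_reads = uniq,
            median_insert_bp = mins,
            truth = if (hasFusion[i]) paste0(geneId(gene), "::partner")
                    else NA_character_,
            wts_outcome = outcome, panel_outcome = NA_character_,
            sam_path = if (is.null(dir)) NA_character_ else samPath,
            stringsAsFactors = FALSE)
    }
    ledger <- do.call(rbind, rows)
    if (!is.null(dir)) {
        utils::write.table(ledger, file.path(dir, "ledger.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
    }
    ledger
}
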