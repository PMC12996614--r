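# Fixtures and independent oracles shared across the test files.
# Everything is generated in code; nothing is read from disk except files
# the tests themselves write to tempdir().

# ---- gene fixtures -------------------------------------------------------

# ALK-like target: minus strand, 34 exons of 150 bp spaced 1 kb apart, so
# exon 1 (transcription order) is the genomically rightmost exon.
alkLikeModel <- function(nExons = 34L, exonLen = 150L, spacing = 1000L) {
    st <- seq(1000L, by = spacing, length.out = nExons)
    geneModel("ALK", "chr2", "-", cbind(st, st + exonLen - 1L))
}

plusGene <- function(nExons = 6L, exonLen = 200L, spacing = 1000L,
                     id = "GPLUS") {
    st <- seq(1000L, by = spacing, length.out = nExons)
    geneModel(id, "chr1", "+", cbind(st, st + exonLen - 1L))
}

# ---- hand-built alignment records ---------------------------------------

samRec <- function(pos, cigar, flag = 16L, qname = "r", rname = "chr1",
                   mapq = 60L, tlen = 0L) {
    data.frame(qname = qname, flag = as.integer(flag), rname = rname,
               pos = as.integer(pos), mapq = as.integer(mapq),
               cigar = cigar, tlen = as.integer(tlen),
               stringsAsFactors = FALSE)
}

# A single-end read assigned to the given transcript strand under RF:
# single-end records align opposite to the transcript strand.
senseRead <- function(pos, cigar, geneStrand, rname = "chr1",
                      qname = "r") {
    flag <- if (geneStrand == "+") 16L else 0L
    samRec(pos, cigar, flag = flag, qname = qname, rname = rname)
}

antisenseRead <- function(pos, cigar, geneStrand, rname = "chr1",
                          qname = "a") {
    flag <- if (geneStrand == "+") 0L else 16L
    samRec(pos, cigar, flag = flag, qname = qname, rname = rname)
}

bindRecs <- function(...) do.call(rbind, list(...))

# ---- brute-force pileup oracle ------------------------------------------

# Reference bases covered by one CIGAR, computed by walking the string.
bfCoveredBases <- function(pos, cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
    len <- as.integer(sub(".$", "", ops))
    op <- substring(ops, nchar(ops))
    cur <- pos
    cov <- integer(0)
    for (i in seq_along(op)) {
        if (op[i] %in% c("M", "=", "X")) {
            cov <- c(cov, cur:(cur + len[i] - 1L))
            cur <- cur + len[i]
        } else if (op[i] %in% c("D", "N")) {
            cur <- cur + len[i]
        }
    }
    cov
}

# Independent re-derivation of the RF strand rule.
bfTranscriptStrand <- function(flag) {
    aligned <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    paired <- bitwAnd(flag, 1L) > 0L
    read2 <- bitwAnd(flag, 128L) > 0L
    if (paired && read2) aligned
    else if (aligned == "+") "-" else "+"
}

# Per-exon mean depth restricted to reads on `strand`, by per-base counting.
bfExonMeans <- function(rec, gene, strand) {
    keep <- vapply(seq_len(nrow(rec)), function(i) {
        f <- rec$flag[i]
        if (bitwAnd(f, 4L) > 0L || bitwAnd(f, 256L) > 0L ||
            bitwAnd(f, 2048L) > 0L || bitwAnd(f, 1024L) > 0L ||
            (!is.na(rec$mapq[i]) && rec$mapq[i] < 1L) ||
            (bitwAnd(f, 1L) > 0L && bitwAnd(f, 8L) > 0L)) return(FALSE)
        rec$rname[i] == geneChrom(gene) &&
            bfTranscriptStrand(f) == strand
    }, logical(1))
    rec <- rec[keep, , drop = FALSE]
    ex <- exonRanges(gene)
    maxEnd <- max(IRanges::end(ex))
    depth <- integer(maxEnd)
    for (i in seq_len(nrow(rec))) {
        b <- bfCoveredBases(rec$pos[i], rec$cigar[i])
        b <- b[b <= maxEnd]
        depth[b] <- depth[b] + 1L
    }
    vapply(seq_along(ex), function(j) {
        mean(depth[IRanges::start(ex)[j]:IRanges::end(ex)[j]])
    }, numeric(1))
}

# ---- brute-force changepoint oracle -------------------------------------

# Naive exhaustive two-mean step fit on log2(depth + eps); no shared code
# with the implementation's cumulative-sum shortcut.
bfStepFit <- function(means, eps = 0.05) {
    y <- log2(means + eps)
    n <- length(y)
    rss <- vapply(seq_len(n - 1L), function(k) {
        left <- y[1:k]; right <- y[(k + 1L):n]
        sum((left - mean(left))^2) + sum((right - mean(right))^2)
    }, numeric(1))
    list(k = which.min(rss), rss = rss,
         gain = sum((y - mean(y))^2) - min(rss))
}

# ---- reference-count cohort ledgers ---------------------------------------

# Evaluation-cohort shape: 64 samples, 48 fusion-positive with 4 misses
# (TCC 50/30/30/10), 16 negative.
ecShapedLedger <- function() {
    n <- 64L
    led <- data.frame(sample_id = sprintf("EC%02d", 1:n),
        tcc_percent = 60, rna_input_ng = 150, unique_reads = 96e6,
        median_insert_bp = 129, truth = NA_character_,
        wts_outcome = "negative", stringsAsFactors = FALSE)
    led$truth[1:48] <- "FUSION"
    led$wts_outcome[1:48] <- "detected"
    led$wts_outcome[45:48] <- "missed"
    led$tcc_percent[45:48] <- c(50, 30, 30, 10)
    led$rna_input_ng[45:48] <- c(200, 150, 50, 50)
    led$unique_reads[45:48] <- c(70e6, 85e6, 90e6, 100e6)
    led$median_insert_bp[45:48] <- c(133, 135, 136, 138)
    led
}

# Validation-cohort shape: 357 samples, 74 fusions with 5 misses (all at
# TCC 20-30 %), per-criterion failures 131 TCC / 4 input / 21 reads
# (12 of the read failures also TCC failures), 144 failing overall.
vcShapedLedger <- function() {
    n <- 357L
    led <- data.frame(sample_id = sprintf("VC%03d", 1:n),
        tcc_percent = 60, rna_input_ng = 150, unique_reads = 96e6,
        median_insert_bp = 129, truth = NA_character_,
        wts_outcome = "negative", stringsAsFactors = FALSE)
    led$tcc_percent[1:131] <- 30          # TCC failures
    led$tcc_percent[1:5] <- c(20, 30, 30, 20, 30)
    led$truth[1:5] <- "FUSION"
    led$wts_outcome[1:5] <- "missed"      # all misses below the TCC gate
    led$unique_reads[6:17] <- 40e6        # read failures overlapping TCC
    led$unique_reads[132:140] <- 40e6     # read failures alone
    led$rna_input_ng[141:144] <- 30       # input failures alone
    led$truth[145:213] <- "FUSION"        # 69 detected fusions, QC-passing
    led$wts_outcome[145:213] <- "detected"
    led
}

# Clinical-practice shape: 1235 samples, 423 failing the gate on TCC.
clinicalShapedLedger <- function() {
    n <- 1235L
    led <- data.frame(sample_id = sprintf("CL%04d", 1:n),
        tcc_percent = 60, rna_input_ng = 150, unique_reads = 96e6,
        median_insert_bp = 129, truth = NA_character_,
        wts_outcome = "negative", stringsAsFactors = FALSE)
    led$tcc_percent[1:423] <- 30
    led
}
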