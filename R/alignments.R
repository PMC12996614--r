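# Internal alignment-record funnel.
#
# All alignment-consuming operations (coverage, junction counting, insert
# size, duplicate collapsing) run on one canonical in-memory representation:
# a data.frame with columns qname, flag, rname, pos (1-based), mapq, cigar,
# tlen. Both entry points — a BAM/SAM file on disk and the simulator's
# native output — funnel into it, so file-based and in-memory analyses are
# guaranteed to agree.

.FLAG_PAIRED <- 0x1L
.FLAG_PROPER <- 0x2L
.FLAG_UNMAPPED <- 0x4L
.FLAG_MATE_UNMAPPED <- 0x8L
.FLAG_REVERSE <- 0x10L
.FLAG_MATE_REVERSE <- 0x20L
.FLAG_READ1 <- 0x40L
.FLAG_READ2 <- 0x80L
.FLAG_SECONDARY <- 0x100L
.FLAG_DUP <- 0x400L
.FLAG_SUPPLEMENTARY <- 0x800L

.emptyRecords <- function() {
    data.frame(qname = character(), flag = integer(), rname = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               tlen = integer(), stringsAsFactors = FALSE)
}

# Resolve a path: SAM files are converted to sorted+indexed BAM in tempdir;
# BAM files must be indexed (or an index is built beside them if writable).
.asBamPath <- function(path) {
    stopifnot(length(path) == 1L, file.exists(path))
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile()
        return(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                indexDestination = TRUE))
    }
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path))) {
        idx <- try(Rsamtools::indexBam(path), silent = TRUE)
        if (inherits(idx, "try-error"))
            stop("BAM file is not indexed and an index could not be built: ",
                 path)
    }
    path
}

# Read records overlapping a region (or the whole file) into the canonical
# record table.
.readRecords <- function(path, chrom = NULL, start = NULL, end = NULL) {
    bam <- .asBamPath(path)
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "isize")
    if (!is.null(chrom)) {
        if (!(chrom %in% names(hdr)))
            stop("contig '", chrom, "' absent from alignment header")
        which <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(max(1L, start), end))
        param <- Rsamtools::ScanBamParam(what = what, which = which)
        res <- Rsamtools::scanBam(bam, param = param)[[1L]]
    } else {
        param <- Rsamtools::ScanBamParam(what = what)
        res <- Rsamtools::scanBam(bam, param = param)[[1L]]
    }
    data.frame(qname = as.character(res$qname), flag = as.integer(res$flag),
               rname = as.character(res$rname), pos = as.integer(res$pos),
               mapq = as.integer(res$mapq), cigar = as.character(res$cigar),
               tlen = as.integer(res$isize), stringsAsFactors = FALSE)
}

# Standard pileup hygiene: drop unmapped records and mates, secondary,
# supplementary and duplicate-flagged alignments, and MAPQ < minMapq.
.primaryRecords <- function(rec, minMapq = 1L) {
    if (nrow(rec) == 0L) return(rec)
    f <- rec$flag
    drop <- bitwAnd(f, .FLAG_UNMAPPED) > 0L |
        bitwAnd(f, .FLAG_SECONDARY) > 0L |
        bitwAnd(f, .FLAG_SUPPLEMENTARY) > 0L |
        bitwAnd(f, .FLAG_DUP) > 0L |
        (bitwAnd(f, .FLAG_PAIRED) > 0L & bitwAnd(f, .FLAG_MATE_UNMAPPED) > 0L) |
        (!is.na(rec$mapq) & rec$mapq < minMapq)
    rec[!drop, , drop = FALSE]
}

# Transcript-strand assignment under a stranded protocol. RF (reverse-
# stranded, TruSeq convention): the second-in-pair mate aligns on the
# transcript strand, the first-in-pair on the opposite; single-end records
# align opposite to the transcript. FR is the mirror image.
.transcriptStrand <- function(flag, orientation = c("RF", "FR")) {
    orientation <- match.arg(orientation)
    aligned <- ifelse(bitwAnd(flag, .FLAG_REVERSE) > 0L, "-", "+")
    paired <- bitwAnd(flag, .FLAG_PAIRED) > 0L
    read2 <- bitwAnd(flag, .FLAG_READ2) > 0L
    same <- if (orientation == "RF") (paired & read2) else (!paired | !read2)
    ifelse(same, aligned, ifelse(aligned == "+", "-", "+"))
}

.flipStrand <- function(s) ifelse(s == "+", "-", "+")

# Aligned reference blocks (M/=/X) per record, as an IRangesList.
.alignedBlocks <- function(rec) {
    GenomicAlignments::cigarRangesAlongReferenceSpace(
        rec$cigar, pos = rec$pos, ops = c("M", "=", "X"),
        reduce.ranges = TRUE)
}

# Intron gaps (N) per record, as an IRangesList.
.junctionRanges <- function(rec) {
    GenomicAlignments::cigarRangesAlongReferenceSpace(
        rec$cigar, pos = rec$pos, ops = "N")
}

# Records from a simulator output or any list carrying $records.
.recordsFrom <- function(alignments) {
    if (is.data.frame(alignments)) return(alignments)
    if (is.list(alignments) && is.data.frame(alignments$records))
        return(alignments$records)
    stop("cannot interpret 'alignments' as an alignment record table")
}
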