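#' Construct a GeneModel
#'
#' Exon intervals may be given in any order; they are union-merged
#' ([IRanges::reduce]) and stored in transcription order (exon 1 = 5'-most
#' exon), i.e. ascending genomic start for `strand = "+"` and descending for
#' `strand = "-"`.
#'
#' @param geneId gene identifier.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons an [IRanges::IRanges] of exon intervals (1-based closed
#'   genomic coordinates), or a two-column matrix/data.frame of start/end.
#' @param geneName gene symbol; defaults to `geneId`.
#' @return a [GeneModel-class].
#' @examples
#' gm <- geneModel("ALK", "chr2", "-",
#'                 cbind(start = seq(1000, 34000, by = 1000),
#'                       end   = seq(1150, 34150, by = 1000)))
#' exonCount(gm)
#' @export
geneModel <- function(geneId, chrom, strand, exons, geneName = geneId) {
    if (!methods::is(exons, "IRanges")) {
        exons <- as.matrix(exons)
        exons <- IRanges::IRanges(start = as.integer(exons[, 1L]),
                                  end   = as.integer(exons[, 2L]))
    }
    exons <- IRanges::reduce(exons)
    ord <- order(IRanges::start(exons), decreasing = (strand == "-"))
    methods::new("GeneModel", geneId = as.character(geneId),
        geneName = as.character(geneName), chrom = as.character(chrom),
        strand = strand, exons = exons[ord])
}

#' @describeIn geneModel gene identifier.
#' @param x a `GeneModel`.
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @describeIn geneModel gene symbol.
#' @export
setMethod("geneName", "GeneModel", function(x) x@geneName)

#' @describeIn geneModel contig name.
#' @export
setMethod("geneChrom", "GeneModel", function(x) x@chrom)

#' @describeIn geneModel strand, `"+"` or `"-"`.
#' @export
setMethod("geneStrand", "GeneModel", function(x) x@strand)

#' @describeIn geneModel exon intervals (transcription order).
#' @export
setMethod("exonRanges", "GeneModel", function(x) x@exons)

#' @describeIn geneModel number of exons.
#' @export
setMethod("exonCount", "GeneModel", function(x) length(x@exons))

#' @describeIn geneModel exon widths in bp (transcription order).
#' @export
setMethod("exonWidths", "GeneModel", function(x) IRanges::width(x@exons))

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel ", object@geneName, " (", object@geneId, ") ",
        object@chrom, ":", min(IRanges::start(object@exons)), "-",
        max(IRanges::end(object@exons)), " (", object@strand, "), ",
        length(object@exons), " exons\n", sep = "")
})

#' Construct a BreakpointSpec
#'
#' @param geneId gene identifier.
#' @param boundaryExon integer k: the partition lies between exon k and exon
#'   k+1 in transcription order.
#' @param retainedSide side expected overexpressed when a fusion is present:
#'   `"3prime"` (e.g. a retained kinase domain) or `"5prime"`.
#' @param genomicPos optional genomic coordinate of the boundary.
#' @param source `"recurrent"` or `"automatic"`.
#' @param gene optional [GeneModel-class]; when supplied, `boundaryExon` is
#'   validated against the exon count and `genomicPos` is filled in.
#' @return a [BreakpointSpec-class].
#' @export
breakpointSpec <- function(geneId, boundaryExon,
                           retainedSide = c("3prime", "5prime"),
                           genomicPos = NA_real_,
                           source = c("recurrent", "automatic"),
                           gene = NULL) {
    retainedSide <- match.arg(retainedSide)
    source <- match.arg(source)
    boundaryExon <- as.integer(boundaryExon)
    if (!is.null(gene)) {
        if (geneId(gene) != geneId)
            stop("gene model is for ", geneId(gene), ", not ", geneId)
        n <- exonCount(gene)
        if (is.na(boundaryExon) || boundaryExon < 1L || boundaryExon >= n)
            stop("invalid boundary exon for gene ", geneId,
                 ": need 1 <= k < ", n, ", got ", boundaryExon)
        if (is.na(genomicPos))
            genomicPos <- breakpointGenomicPos(gene, boundaryExon)
    }
    methods::new("BreakpointSpec", geneId = as.character(geneId),
        boundaryExon = boundaryExon, genomicPos = as.numeric(genomicPos),
        retainedSide = retainedSide, source = source)
}

#' @describeIn breakpointSpec boundary exon index k.
#' @param x a `BreakpointSpec`.
#' @export
setMethod("boundaryExon", "BreakpointSpec", function(x) x@boundaryExon)

#' @describeIn breakpointSpec retained (expected overexpressed) side.
#' @export
setMethod("retainedSide", "BreakpointSpec", function(x) x@retainedSide)

#' @describeIn breakpointSpec gene identifier.
#' @export
setMethod("geneId", "BreakpointSpec", function(x) x@geneId)

setMethod("show", "BreakpointSpec", function(object) {
    cat("BreakpointSpec ", object@geneId, ": exons 1-", object@boundaryExon,
        " | ", object@boundaryExon + 1L, "-..., retained ",
        object@retainedSide, " (", object@source, ")\n", sep = "")
})

#' Genomic coordinate of a breakpoint boundary
#'
#' The midpoint of the intron between exon k and exon k+1 (transcription
#' order). Junctions are classified against this coordinate, so the
#' canonical wild-type junction across the boundary always counts as
#' spanning.
#'
#' @param gene a [GeneModel-class].
#' @param k boundary exon index (1 <= k < exon count).
#' @return a genomic coordinate (possibly half-integer).
#' @export
breakpointGenomicPos <- function(gene, k) {
    k <- as.integer(k)
    n <- exonCount(gene)
    if (k < 1L || k >= n) stop("boundary exon out of range")
    ex <- exonRanges(gene)
    if (geneStrand(gene) == "+") {
        (IRanges::end(ex)[k] + IRanges::start(ex)[k + 1L]) / 2
    } else {
        (IRanges::start(ex)[k] + IRanges::end(ex)[k + 1L]) / 2
    }
}

#' Partition a gene's exons at a breakpoint
#'
#' Splits exon indices (transcription order) into the 5' part (exons 1..k)
#' and the 3' part (exons k+1..n); the two index sets are disjoint and
#' jointly exhaustive.
#'
#' @param gene a [GeneModel-class].
#' @param bp a [BreakpointSpec-class] for the same gene.
#' @return a list with integer vectors `fivePrime` and `threePrime`.
#' @examples
#' gm <- geneModel("G", "chr1", "+", cbind(c(1, 201, 401), c(100, 300, 500)))
#' bp <- breakpointSpec("G", 2, "3prime", gene = gm)
#' exonPartition(gm, bp)
#' @export
exonPartition <- function(gene, bp) {
    if (geneId(gene) != geneId(bp))
        stop("breakpoint is for gene ", geneId(bp), ", model is for ",
             geneId(gene))
    n <- exonCount(gene)
    k <- boundaryExon(bp)
    if (k < 1L || k >= n)
        stop("boundary exon ", k, " out of range for ", geneId(gene),
             " (", n, " exons)")
    list(fivePrime = seq_len(k), threePrime = seq.int(k + 1L, n))
}

# Light pre-validation so malformed GTF input fails with a line number;
# rtracklayer then does the actual parsing.
.checkGtfLines <- function(lines) {
    body <- !startsWith(lines, "#") & nzchar(lines)
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    bad <- vapply(fields, function(f) {
        length(f) < 9L || is.na(suppressWarnings(as.integer(f[4L]))) ||
            is.na(suppressWarnings(as.integer(f[5L])))
    }, logical(1))
    if (any(bad))
        stop("malformed GTF line ", which(body)[which(bad)[1L]],
             ": expected 9 tab-separated fields with numeric start/end")
}

#' Parse gene annotation into GeneModels
#'
#' Reads exon features from a GTF file, union-merges the exons of all
#' transcripts of each requested gene, and assigns exon indices in
#' transcription order. Genes are matched by `gene_id` or `gene_name`.
#'
#' @param path path to a GTF file (or a character vector of GTF lines).
#' @param geneFilter character vector of gene identifiers/symbols to load.
#'   An empty filter yields an empty list.
#' @return a named list of [GeneModel-class]; requested genes absent from
#'   the annotation are recorded in the `"missing"` attribute (with a
#'   warning), not treated as fatal.
#' @export
parseGeneAnnotation <- function(path, geneFilter) {
    geneFilter <- as.character(geneFilter)
    if (length(geneFilter) == 0L) {
        out <- list()
        attr(out, "missing") <- character()
        return(out)
    }
    if (length(path) == 1L && file.exists(path)) {
        lines <- readLines(path)
    } else {
        lines <- path
        path <- tempfile(fileext = ".gtf")
        writeLines(lines, path)
        on.exit(unlink(path))
    }
    .checkGtfLines(lines)
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    ids <- as.character(gr$gene_id)
    nms <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else ids
    out <- list()
    for (g in geneFilter) {
        hit <- which(ids == g | nms == g)
        if (length(hit) == 0L) next
        sub <- gr[hit]
        strand <- unique(as.character(GenomicRanges::strand(sub)))
        chrom <- unique(as.character(GenomicRanges::seqnames(sub)))
        if (length(strand) != 1L || length(chrom) != 1L)
            stop("gene ", g, " has exons on multiple strands/contigs")
        out[[g]] <- geneModel(ids[hit[1L]], chrom, strand,
            IRanges::ranges(sub), geneName = nms[hit[1L]])
    }
    missing <- setdiff(geneFilter, names(out))
    if (length(missing))
        warning("genes absent from annotation: ",
                paste(missing, collapse = ", "))
    attr(out, "missing") <- missing
    out
}

#' Write GeneModels back to GTF
#'
#' Emits one exon feature per (merged) exon, numbered in transcription
#' order. Re-parsing the output with [parseGeneAnnotation()] reproduces the
#' models.
#'
#' @param genes a [GeneModel-class] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneModelGTF <- function(genes, path) {
    if (methods::is(genes, "GeneModel")) genes <- list(genes)
    lines <- unlist(lapply(genes, function(g) {
        ex <- exonRanges(g)
        sprintf(
            "%s\tfusimba\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; transcript_id \"%s.t1\"; exon_number \"%d\";",
            geneChrom(g), IRanges::start(ex), IRanges::end(ex),
            geneStrand(g), geneId(g), geneName(g), geneId(g),
            seq_along(ex))
    }))
    writeLines(lines, path)
    invisible(path)
}

#' Load a recurrent-breakpoint table
#'
#' Reads a TSV with header columns `gene_id`, `boundary_exon`,
#' `retained_side` (comment lines starting with `#` are ignored) into
#' [BreakpointSpec-class] objects with `source = "recurrent"`. The genes and
#' boundary exons of the table are site configuration: the package ships
#' only a small illustrative example table
#' (`system.file("extdata", "example_breakpoints.tsv", package = "fusimba")`).
#'
#' @param path path to the TSV.
#' @param genes optional named list of [GeneModel-class] (as returned by
#'   [parseGeneAnnotation()]); when supplied, each boundary exon is
#'   validated against the gene's exon count and the genomic boundary
#'   position is filled in.
#' @return a named list of [BreakpointSpec-class].
#' @export
loadBreakpointTable <- function(path, genes = NULL) {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "boundary_exon", "retained_side")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("breakpoint table is missing column(s): ",
             paste(miss, collapse = ", "))
    out <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
        gid <- tab$gene_id[i]
        side <- as.character(tab$retained_side[i])
        if (!side %in% c("5prime", "3prime"))
            stop("invalid retained_side for gene ", gid, ": ", side)
        k <- suppressWarnings(as.integer(tab$boundary_exon[i]))
        if (is.na(k) || k < 1L)
            stop("invalid boundary_exon for gene ", gid, ": ",
                 tab$boundary_exon[i])
        gene <- if (!is.null(genes)) genes[[gid]] else NULL
        out[[i]] <- breakpointSpec(gid, k, side, source = "recurrent",
                                   gene = gene)
    }
    names(out) <- tab$gene_id
    out
}
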