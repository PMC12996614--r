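# Strand-aware coverage, junction counting and the imbalance statistic.

test_that("sense pileup is exact on a fully covered exon", {
    gm <- geneModel("G", "chr1", "+", cbind(1001L, 1100L))
    rec <- do.call(rbind, lapply(1:10, function(i)
        senseRead(1001L, "100M", "+", qname = paste0("s", i))))
    cov <- strandedExonCoverage(rec, gm)
    expect_equal(senseDepth(cov), 10)
    expect_equal(antisenseDepth(cov), 0)
})

test_that("antisense unspliced reads land in the antisense track only", {
    gm <- geneModel("G", "chr1", "+", cbind(1001L, 1100L))
    rec <- bindRecs(
        do.call(rbind, lapply(1:10, function(i)
            senseRead(1001L, "100M", "+", qname = paste0("s", i)))),
        do.call(rbind, lapply(1:7, function(i)
            antisenseRead(1001L, "100M", "+", qname = paste0("a", i)))))
    cov <- strandedExonCoverage(rec, gm)
    expect_equal(senseDepth(cov), 10)
    expect_equal(antisenseDepth(cov), 7)
})

test_that("coverage equals a brute-force per-base pileup on random fixtures", {
    set.seed(11)
    gm <- plusGene(nExons = 4L, exonLen = 120L, spacing = 400L)
    recs <- lapply(1:60, function(i) {
        pos <- sample(900:2400, 1)
        cigar <- sample(c("80M", "40M200N40M", "100M"), 1)
        flag <- sample(c(0L, 16L), 1)
        samRec(pos, cigar, flag = flag, qname = paste0("r", i))
    })
    rec <- do.call(rbind, recs)
    cov <- strandedExonCoverage(rec, gm)
    expect_equal(senseDepth(cov), bfExonMeans(rec, gm, "+"))
    expect_equal(antisenseDepth(cov), bfExonMeans(rec, gm, "-"))

    # coverage conservation: depth x width sums to all aligned bases in exons
    total <- sum((senseDepth(cov) + antisenseDepth(cov)) * exonWidths(gm))
    ex <- exonRanges(gm)
    inExon <- function(b) any(b >= IRanges::start(ex) & b <= IRanges::end(ex))
    oracle <- sum(vapply(seq_len(nrow(rec)), function(i) {
        sum(vapply(bfCoveredBases(rec$pos[i], rec$cigar[i]), inExon,
                   logical(1)))
    }, numeric(1)))
    expect_equal(total, oracle)
})

test_that("secondary, duplicate, low-MAPQ and mate-unmapped records are excluded", {
    gm <- geneModel("G", "chr1", "+", cbind(1001L, 1100L))
    rec <- bindRecs(
        senseRead(1001L, "100M", "+", qname = "keep"),
        samRec(1001L, "100M", flag = 16L + 256L, qname = "sec"),
        samRec(1001L, "100M", flag = 16L + 1024L, qname = "dup"),
        samRec(1001L, "100M", flag = 16L + 2048L, qname = "supp"),
        samRec(1001L, "100M", flag = 16L, mapq = 0L, qname = "mapq0"),
        samRec(1001L, "100M", flag = 16L + 1L + 8L, qname = "mateunmapped"))
    cov <- strandedExonCoverage(rec, gm)
    expect_equal(senseDepth(cov), 1)
})

test_that("spliced reads are assigned to 5', 3' or spanning", {
    # plus-strand gene, 3 exons, boundary after exon 2
    gm <- plusGene(nExons = 3L, exonLen = 100L, spacing = 500L) # 1000,1500,2000
    bp <- breakpointSpec("GPLUS", 2, "3prime", gene = gm)

    # 84 spliced reads joining exons 2->3 would cross the boundary; instead
    # place them 3' of it: there is only one junction 3' of exon 2 in a
    # 3-exon gene, so use a 4-exon gene for a clean 3'-only junction.
    gm4 <- plusGene(nExons = 4L, exonLen = 100L, spacing = 500L)
    bp4 <- breakpointSpec("GPLUS", 1, "3prime", gene = gm4)
    rec <- do.call(rbind, lapply(1:84, function(i)
        senseRead(2050L, "50M400N50M", "+", qname = paste0("j", i))))
    jc <- countSplicedReads(rec, gm4, bp4)
    expect_equal(c(jc@n5, jc@n3, jc@nSpanning), c(0L, 84L, 0L))

    # unspliced reads only
    rec2 <- senseRead(1001L, "100M", "+")
    jc2 <- countSplicedReads(rec2, gm, bp)
    expect_equal(c(jc2@n5, jc2@n3, jc2@nSpanning), c(0L, 0L, 0L))

    # a read splicing across the boundary (exon 2 -> exon 3) spans
    rec3 <- senseRead(1550L, "50M400N50M", "+")
    jc3 <- countSplicedReads(rec3, gm, bp)
    expect_equal(c(jc3@n5, jc3@n3, jc3@nSpanning), c(0L, 0L, 1L))

    # antisense spliced reads are not counted on this gene
    rec4 <- antisenseRead(1550L, "50M400N50M", "+")
    jc4 <- countSplicedReads(rec4, gm, bp)
    expect_equal(c(jc4@n5, jc4@n3, jc4@nSpanning), c(0L, 0L, 0L))
})

test_that("junction sides respect transcription order on the minus strand", {
    gm <- geneModel("G", "chr1", "-",
                    cbind(c(1001L, 1501L, 2001L), c(1100L, 1600L, 2100L)))
    bp <- breakpointSpec("G", 1, "3prime", gene = gm)  # exon 1 = (2001,2100)
    # a junction between the two genomically leftmost exons is 3' in
    # transcription order
    rec <- senseRead(1050L, "50M400N50M", "-")
    jc <- countSplicedReads(rec, gm, bp)
    expect_equal(c(jc@n5, jc@n3, jc@nSpanning), c(0L, 1L, 0L))
})

test_that("the fold change follows the pseudocount formula", {
    widths <- rep(150L, 34L)
    cov <- strandedCoverage("ALK", c(rep(0.03, 19), rep(7.37, 15)),
                            widths = widths)
    part <- list(fivePrime = 1:19, threePrime = 20:34)
    res <- imbalanceStatistic(cov, part, "3prime", epsilon = 0.05)
    expect_equal(res@mean5, 0.03)
    expect_equal(res@mean3, 7.37)
    expect_equal(foldChange(res), (7.37 + 0.05) / (0.03 + 0.05))  # 92.75
    expect_equal(foldChange(res), 92.75)

    # symmetric means give fold change 1 for any epsilon
    for (eps in c(0.01, 0.05, 1)) {
        covEq <- strandedCoverage("G", rep(3.3, 6), widths = rep(100L, 6))
        r <- imbalanceStatistic(covEq, list(fivePrime = 1:3, threePrime = 4:6),
                                "3prime", epsilon = eps)
        expect_equal(foldChange(r), 1)
    }

    # zero on the other side is bounded by the pseudocount
    covZ <- strandedCoverage("G", c(0, 0, 5, 5), widths = rep(100L, 4))
    rz <- imbalanceStatistic(covZ, list(fivePrime = 1:2, threePrime = 3:4),
                             "3prime", epsilon = 0.05)
    expect_equal(foldChange(rz), (5 + 0.05) / 0.05)  # 101
})

test_that("mean5/mean3 are length-weighted across exons", {
    cov <- strandedCoverage("G", c(10, 1, 2, 2), widths = c(300L, 100L, 50L, 50L))
    res <- imbalanceStatistic(cov, list(fivePrime = 1:2, threePrime = 3:4),
                              "3prime")
    expect_equal(res@mean5, (10 * 300 + 1 * 100) / 400)
    resPlain <- imbalanceStatistic(cov, list(fivePrime = 1:2, threePrime = 3:4),
                                   "3prime", lengthWeighted = FALSE)
    expect_equal(resPlain@mean5, mean(c(10, 1)))
})

test_that("fold change is monotone in the two means and shrinks with epsilon", {
    base <- c(0.5, 0.5, 4, 4)
    part <- list(fivePrime = 1:2, threePrime = 3:4)
    fc <- function(m5, m3, eps = 0.05) {
        cov <- strandedCoverage("G", c(m5, m5, m3, m3), widths = rep(100L, 4))
        foldChange(imbalanceStatistic(cov, part, "3prime", epsilon = eps))
    }
    retained <- seq(1, 20, by = 2)
    expect_true(all(diff(vapply(retained, function(m) fc(0.5, m), numeric(1))) > 0))
    other <- seq(0.1, 3, by = 0.3)
    expect_true(all(diff(vapply(other, function(m) fc(m, 10), numeric(1))) < 0))
    # pseudocount limit: fold change -> 1 as epsilon grows
    eps <- c(0.05, 1, 10, 1e3, 1e6)
    fcs <- vapply(eps, function(e) fc(0.5, 10, e), numeric(1))
    expect_true(all(diff(fcs) < 0))
    expect_equal(fcs[length(fcs)], 1, tolerance = 1e-4)
})

test_that("the flagging rule is a strict conjunction", {
    jc <- junctionCounts(0L, 84L, 0L)
    part <- list(fivePrime = 1:19, threePrime = 20:34)
    covAlk <- strandedCoverage("ALK", c(rep(0.03, 19), rep(7.37, 15)),
                               widths = rep(150L, 34))
    res <- evaluateImbalance(imbalanceStatistic(covAlk, part, "3prime",
                                                junctions = jc))
    expect_true(isFlagged(res))
    expect_equal(res@recommendation, "orthogonal_confirmation")

    # balanced gene: fold change 1 -> not flagged
    covEq <- strandedCoverage("G", rep(5, 6), widths = rep(100L, 6))
    rEq <- evaluateImbalance(imbalanceStatistic(covEq,
        list(fivePrime = 1:3, threePrime = 4:6), "3prime",
        junctions = junctionCounts(10L, 10L, 0L)))
    expect_false(isFlagged(rEq))
    expect_equal(rEq@recommendation, "none")

    # high fold change but retained depth below the floor -> not flagged
    covLow <- strandedCoverage("G", c(0, 0, 0.5, 0.5), widths = rep(100L, 4))
    rLow <- evaluateImbalance(imbalanceStatistic(covLow,
        list(fivePrime = 1:2, threePrime = 3:4), "3prime",
        junctions = junctionCounts(0L, 50L, 0L)))
    expect_gt(foldChange(rLow), 10)
    expect_false(isFlagged(rLow))

    # junction evidence below the delta -> not flagged
    rJ <- evaluateImbalance(imbalanceStatistic(covAlk, part, "3prime",
        junctions = junctionCounts(0L, 3L, 0L)))
    expect_false(isFlagged(rJ))
})

test_that("imbalance report tabulates and round-trips through files", {
    covAlk <- strandedCoverage("ALK", c(rep(0.03, 19), rep(7.37, 15)),
                               widths = rep(150L, 34))
    res <- evaluateImbalance(imbalanceStatistic(covAlk,
        list(fivePrime = 1:19, threePrime = 20:34), "3prime",
        junctions = junctionCounts(0L, 84L, 0L)))
    prefix <- tempfile()
    rep <- writeImbalanceReport(list(res), prefix)
    expect_true(file.exists(paste0(prefix, ".tsv")))
    expect_true(file.exists(paste0(prefix, ".json")))
    back <- read.delim(paste0(prefix, ".tsv"))
    expect_equal(back$fold_change, 92.75)
    expect_true(back$flagged)
})
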