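# Fusion-caller table parsing, filtering, harmonization and truth matching.

writeArriba <- function(rows) {
    path <- tempfile(fileext = ".tsv")
    writeLines(c(paste0("#gene1\tgene2\tsplit_reads1\tsplit_reads2\t",
                        "discordant_mates\tbreakpoint1\tbreakpoint2"), rows),
               path)
    path
}

writeGeneric <- function(rows, extra = character()) {
    path <- tempfile(fileext = ".tsv")
    writeLines(c(paste(c("sample_id\tgene5\tgene3\tsupport_reads\tevent_type",
                         extra), collapse = "\t"), rows), path)
    path
}

test_that("arriba rows sum split and discordant support", {
    path <- writeArriba("EML4\tALK\t5\t4\t3\tchr2:42492091\tchr2:29446394")
    calls <- parseFusionTable(path, "arriba", sampleId = "S1")
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$support_reads, 12L)
    expect_equal(calls$gene5, "EML4")
    expect_equal(calls$gene3, "ALK")
    expect_equal(calls$status, "raw")
    expect_equal(calls$pos5, 42492091L)
})

test_that("empty tables, bad dialects and missing columns are handled", {
    path <- writeArriba(character())
    expect_equal(nrow(parseFusionTable(path, "arriba")), 0L)
    expect_error(parseFusionTable(path, "bogus"))
    bad <- tempfile()
    writeLines(c("gene1\tgene2\tsplit_reads1", "A\tB\t1"), bad)
    expect_error(parseFusionTable(bad, "arriba"), "discordant_mates")
})

test_that("splice variants with identical partner genes are accepted", {
    path <- writeGeneric("N3\tMET\tMET\t7\tsplice_variant")
    calls <- parseFusionTable(path, "generic", caller = "ctat_splicing")
    expect_equal(calls$event_type, "splice_variant")
    expect_equal(calls$gene5, calls$gene3)
})

test_that("filters combine read support and gene-set membership", {
    validated <- geneSet(c("ALK", "RET", "ROS1", "MET"), minSupport = 1L)
    expanded <- geneSet(c("PTEN", "MALAT1", "CDK12"), minSupport = 10L)
    calls <- data.frame(sample_id = "S", gene5 = c("EML4", "X", "Y"),
        gene3 = c("ALK", "PTEN", "Z"),
        contig5 = NA, pos5 = NA_integer_, contig3 = NA, pos3 = NA_integer_,
        support_reads = c(1L, 9L, 100L), caller = "arriba",
        event_type = "fusion", status = "raw", callers = "arriba",
        manual_review = "pending", stringsAsFactors = FALSE)
    f1 <- applyFilters(calls, validated)
    expect_equal(f1$status,
                 c("filtered_pass", "filtered_fail", "filtered_fail"))
    f2 <- applyFilters(calls, expanded)
    # support 9 < 10 fails the stricter exploratory threshold
    expect_equal(f2$status[2], "filtered_fail")
    # a call with 100 reads but no gene in the set still fails
    expect_equal(f2$status[3], "filtered_fail")
    # filtering is idempotent and order-preserving
    expect_identical(applyFilters(f1, validated), f1)
    expect_identical(f1$gene5, calls$gene5)
})

test_that("caller merging respects the breakpoint tolerance", {
    mk <- function(caller, p5, p3, support, g5 = "EML4", g3 = "ALK") {
        data.frame(sample_id = "S", gene5 = g5, gene3 = g3,
            contig5 = "chr2", pos5 = p5, contig3 = "chr2", pos3 = p3,
            support_reads = support, caller = caller, event_type = "fusion",
            status = "raw", callers = caller, manual_review = "pending",
            stringsAsFactors = FALSE)
    }
    # identical call from two callers -> one record, max support
    m <- mergeCallers(mk("arriba", 100L, 900L, 12L),
                      mk("dragen", 100L, 900L, 8L))
    expect_equal(nrow(m), 1L)
    expect_equal(m$support_reads, 12L)
    expect_equal(m$callers, "arriba,dragen")

    # breakpoints 25 bp apart stay separate (tolerance 10)
    m2 <- mergeCallers(mk("arriba", 100L, 900L, 12L),
                       mk("dragen", 125L, 900L, 8L))
    expect_equal(nrow(m2), 2L)

    # reversed gene order still merges (unordered pair)
    m3 <- mergeCallers(mk("arriba", 100L, 900L, 12L),
                       mk("dragen", 900L, 100L, 9L, g5 = "ALK", g3 = "EML4"))
    expect_equal(nrow(m3), 1L)

    # disjoint calls concatenate; nothing fabricated
    m4 <- mergeCallers(mk("arriba", 100L, 900L, 12L),
                       mk("dragen", 100L, 900L, 8L, g5 = "KIF5B", g3 = "RET"))
    expect_equal(nrow(m4), 2L)
    expect_true(max(m4$support_reads) <= 12L)
})

test_that("truth matching is unordered, typed and exhaustive", {
    obs <- data.frame(sample_id = "S", gene5 = "ALK", gene3 = "EML4",
        contig5 = NA, pos5 = NA_integer_, contig3 = NA, pos3 = NA_integer_,
        support_reads = 12L, caller = "arriba", event_type = "fusion",
        status = "filtered_pass", callers = "arriba",
        manual_review = "pending", stringsAsFactors = FALSE)
    truth <- data.frame(gene5 = "EML4", gene3 = "ALK",
                        event_type = "fusion")
    expect_equal(matchToTruth(obs, truth)$outcome, "true_positive")
    # expected event not observed
    expect_equal(matchToTruth(obs[0, ], truth, sampleId = "S")$outcome,
                 "false_negative")
    # expected-negative sample with no pass calls
    expect_equal(matchToTruth(obs[0, ], NULL, sampleId = "S")$outcome,
                 "true_negative")
    # unexpected pass call
    expect_equal(matchToTruth(obs, NULL)$outcome, "false_positive")
    # splice variants match on gene + event type, not on a partner pair
    metObs <- transform(obs, gene5 = "MET", gene3 = "MET",
                        event_type = "splice_variant")
    metTruth <- data.frame(gene5 = "MET", gene3 = "MET",
                           event_type = "splice_variant")
    expect_equal(matchToTruth(metObs, metTruth)$outcome, "true_positive")
    # a fusion call does not satisfy a splice-variant expectation
    expect_equal(matchToTruth(obs, metTruth)$outcome, "false_negative")
    # deterministic under repetition
    expect_identical(matchToTruth(obs, truth), matchToTruth(obs, truth))
})

test_that("gene-set files read symbols and skip comments", {
    path <- tempfile()
    writeLines(c("# validated set", "ALK", "RET", "", "ROS1"), path)
    gs <- readGeneSet(path, minSupport = 1L)
    expect_equal(sort(gs@genes), c("ALK", "RET", "ROS1"))
    expect_error(geneSet(character()), "non-empty")
    expect_error(geneSet("ALK", minSupport = 0L), "minSupport")
})
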