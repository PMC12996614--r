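# The stranded read simulator: determinism, strand correctness, analytic
# expectation, insert-size fidelity, cohort generation.

test_that("identical configs give byte-identical SAM", {
    gm <- alkLikeModel()
    bp <- breakpointSpec("ALK", 19, "3prime", gene = gm)
    cfg <- simConfig(gm, bp, tcc = 60, antisenseDepth = 1, seed = 123)
    s1 <- simulateSample(cfg)
    s2 <- simulateSample(cfg)
    expect_identical(s1$sam, s2$sam)
    expect_identical(s1$records, s2$records)
    s3 <- simulateSample(simConfig(gm, bp, tcc = 60, antisenseDepth = 1,
                                   seed = 124))
    expect_false(identical(s1$sam, s3$sam))
})

test_that("zero expression on the gene strand yields zero gene-strand reads", {
    gm <- plusGene()
    cfg <- simConfig(gm, NULL, tcc = 0, fusionExpression = 5,
                     wildtypeExpression = 0, seed = 5)
    sim <- simulateSample(cfg)
    expect_equal(nrow(sim$records), 0L)
})

test_that("antisense contamination stays off the sense strand", {
    gm <- plusGene(nExons = 3L, exonLen = 500L, spacing = 1000L)
    bp <- breakpointSpec("GPLUS", 1, "3prime", gene = gm)
    cfg <- simConfig(gm, NULL, tcc = 100, fusionExpression = 0,
                     wildtypeExpression = 0, antisenseDepth = 5, seed = 9)
    sim <- simulateSample(cfg)
    expect_gt(nrow(sim$records), 0L)
    cov <- strandedExonCoverage(sim, gm)
    expect_equal(senseDepth(cov), rep(0, 3))
    expect_gt(mean(antisenseDepth(cov)), 3)
    jc <- countSplicedReads(sim, gm, bp)
    expect_equal(c(jc@n5, jc@n3, jc@nSpanning), c(0L, 0L, 0L))
})

test_that("fusion reads cover only the retained side and splice correctly", {
    gm <- alkLikeModel()
    bp <- breakpointSpec("ALK", 19, "3prime", gene = gm)
    cfg <- simConfig(gm, bp, tcc = 100, fusionExpression = 7.37,
                     wildtypeExpression = 0, seed = 77)
    sim <- simulateSample(cfg)
    cov <- strandedExonCoverage(sim, gm)
    expect_equal(senseDepth(cov)[1:19], rep(0, 19))
    expect_gt(mean(senseDepth(cov)[20:34]), 5)
    jc <- countSplicedReads(sim, gm, bp)
    expect_equal(jc@n5, 0L)
    expect_gt(jc@n3, 10L)
    expect_equal(jc@nSpanning, 0L)
})

test_that("simulated depth matches the analytic expectation", {
    gm <- plusGene(nExons = 6L, exonLen = 200L, spacing = 800L)
    bp <- breakpointSpec("GPLUS", 3, "3prime", gene = gm)
    nRep <- 100L
    obs <- matrix(0, nRep, 6L)
    expDepth <- NULL
    for (r in seq_len(nRep)) {
        cfg <- simConfig(gm, bp, tcc = 80, fusionExpression = 6,
                         wildtypeExpression = 0.5, seed = 1000L + r)
        sim <- simulateSample(cfg)
        obs[r, ] <- senseDepth(strandedExonCoverage(sim, gm))
        expDepth <- truthExpectedDepth(sim$truth)
    }
    se <- apply(obs, 2L, stats::sd) / sqrt(nRep)
    expect_true(all(abs(colMeans(obs) - expDepth) <= 3 * se + 1e-9))
})

test_that("the realized insert-size median tracks the configured median", {
    # single long exon => genomic span equals the insert length by design
    gm <- geneModel("LONG", "chr3", "+", cbind(1001L, 11000L))
    cfg <- simConfig(gm, NULL, fusionExpression = 0,
                     wildtypeExpression = 25, insertMedian = 129,
                     insertSd = 8, seed = 404)
    sim <- simulateSample(cfg)
    expect_gte(sim$truth@nWildtypeFragments, 2000L)
    expect_lte(abs(medianInsertSize(sim$records) - 129), 5)
})

test_that("SAM output is valid input for the file-based metrics", {
    gm <- alkLikeModel()
    bp <- breakpointSpec("ALK", 19, "3prime", gene = gm)
    cfg <- simConfig(gm, bp, tcc = 100, wildtypeExpression = 0.5, seed = 31)
    path <- tempfile(fileext = ".sam")
    sim <- simulateSample(cfg, samPath = path)
    expect_true(file.exists(path))
    expect_equal(medianInsertSize(path), medianInsertSize(sim$records))
    expect_equal(countUniqueFragments(path),
                 countUniqueFragments(sim$records))
    covFile <- strandedExonCoverage(path, gm)
    covMem <- strandedExonCoverage(sim, gm)
    expect_equal(senseDepth(covFile), senseDepth(covMem))
    expect_equal(antisenseDepth(covFile), antisenseDepth(covMem))
})

test_that("infeasible geometry is rejected", {
    tiny <- geneModel("TINY", "chr1", "+", cbind(1001L, 1030L))
    cfg <- simConfig(tiny, NULL, fusionExpression = 0,
                     wildtypeExpression = 5, insertMedian = 60,
                     readLength = 50L, seed = 2)
    expect_error(simulateSample(cfg), "infeasible")
})

test_that("cohort simulation is reproducible and ledger-complete", {
    gm <- plusGene(nExons = 8L, exonLen = 150L, spacing = 600L)
    bp <- breakpointSpec("GPLUS", 4, "3prime", gene = gm)
    led <- simulateCohort(20L, gm, bp, prevalence = 0.5,
        tccSampler = function(n) rep(50, n), seed = 1L)
    expect_equal(nrow(led), 20L)
    # seeded binomial oracle for the fusion-positive count
    set.seed(1L)
    round(rep(50, 20)); round(stats::runif(20, 50, 200), 1)
    expected <- sum(stats::rbinom(20L, 1L, 0.5) == 1L)
    expect_equal(sum(!is.na(led$truth)), expected)
    expect_true(all(led$wts_outcome %in% c("detected", "missed", "negative")))
    expect_true(all(led$unique_reads >= 0))
    # single-sample cohort
    led1 <- simulateCohort(1L, gm, bp, seed = 3L)
    expect_equal(nrow(led1), 1L)
    # degenerate low TCC routes everything to the fallback panel
    ledLow <- simulateCohort(5L, gm, bp,
        tccSampler = function(n) rep(20, n), seed = 4L)
    route <- routeSamples(ledLow,
        qcThresholds(minUniqueReads = 0, minMedianInsert = 0,
                     minRnaInput = 0))
    expect_equal(route$nRoutedPanel, 5L)
    expect_true(all(route$table$routing == "targeted_panel"))
})

test_that("cohort files are written when a directory is given", {
    gm <- plusGene(nExons = 6L, exonLen = 150L, spacing = 600L)
    bp <- breakpointSpec("GPLUS", 3, "3prime", gene = gm)
    dir <- tempfile()
    dir.create(dir)
    led <- simulateCohort(2L, gm, bp, seed = 11L, dir = dir)
    expect_true(all(file.exists(led$sam_path)))
    expect_true(file.exists(file.path(dir, "ledger.tsv")))
    expect_true(file.exists(file.path(dir, "SIM0001.truth.json")))
    back <- readCohortLedger(file.path(dir, "ledger.tsv"))
    expect_equal(back$sample_id, led$sample_id)
})
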