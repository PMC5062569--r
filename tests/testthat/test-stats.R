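test_that("a single usable population collapses to the plain Pearson correlation", {
    set.seed(1)
    g <- matrix(0L, 10, 1, dimnames = list(sprintf("S%02d", 1:10),
                                           "chr1:1:A:T"))
    theta <- runif(10)
    y <- rnorm(10)
    ## second population too small to pool: only P1 is usable
    cohort <- AdmixedCohort(
        data.frame(individual_id = rownames(g),
                   population = c(rep("P1", 8), "P2", "P2"),
                   africanAncestry = theta),
        g)
    res <- pooledAncestryCorrelation(cohort, y)
    expect_equal(pooledR(res), cor(theta[1:8], y[1:8]), tolerance = 1e-12)
    expect_equal(res@excludedPopulations$reason, "n<4")
})

test_that("populations with identical within-correlation pool to that value", {
    ## two strata engineered to the same r: pooling is a fixed point
    set.seed(2)
    x1 <- runif(20); e1 <- rnorm(20)
    y1 <- as.numeric(0.5 * scale(x1) +
                     sqrt(0.75) * scale(resid(lm(e1 ~ x1))))
    cohort <- makeCohortFixture(
        matrix(0L, 40, 1, dimnames = list(NULL, "chr1:1:A:T")),
        rep(c("P1", "P2"), each = 20), c(x1, x1))
    res <- pooledAncestryCorrelation(cohort, c(y1, y1))
    r1 <- cor(x1, y1)
    expect_equal(pooledR(res), r1, tolerance = 1e-12)
})

test_that("pooling matches an independently coded Fisher-z oracle to 1e-12", {
    set.seed(3)
    for (i in 1:25) {
        nPop <- sample(2:6, 1)
        n <- sample(4:30, nPop, replace = TRUE)
        pop <- rep(sprintf("P%d", seq_len(nPop)), n)
        theta <- runif(sum(n))
        y <- rnorm(sum(n)) + theta * rnorm(1, 0, 2)
        cohort <- makeCohortFixture(
            matrix(0L, sum(n), 1, dimnames = list(NULL, "chr1:1:A:T")),
            pop, theta)
        expect_equal(pooledR(pooledAncestryCorrelation(cohort, y)),
                     poolOracle(theta, y, pop), tolerance = 1e-12)
    }
})

test_that("pooling is invariant to population relabeling and row order", {
    set.seed(4)
    n <- 60
    pop <- rep(c("P1", "P2", "P3"), each = 20)
    theta <- runif(n); y <- rnorm(n) + theta
    mk <- function(pop, theta) makeCohortFixture(
        matrix(0L, length(theta), 1, dimnames = list(NULL, "chr1:1:A:T")),
        pop, theta)
    r0 <- pooledR(pooledAncestryCorrelation(mk(pop, theta), y))
    relab <- c(P1 = "zebra", P2 = "alpha", P3 = "mid")[pop]
    expect_equal(pooledR(pooledAncestryCorrelation(mk(relab, theta), y)), r0)
    o <- sample(n)
    expect_equal(pooledR(pooledAncestryCorrelation(mk(pop[o], theta[o]),
                                                   y[o])), r0)
})

test_that("degenerate strata are excluded and fully degenerate input errors", {
    g <- matrix(0L, 8, 1, dimnames = list(NULL, "chr1:1:A:T"))
    cohort <- makeCohortFixture(g, rep(c("P1", "P2"), each = 4),
                                rep(0.5, 8))   # zero ancestry variance
    expect_error(pooledAncestryCorrelation(cohort, rnorm(8)),
                 "no usable strata")
    cohort2 <- makeCohortFixture(g, rep(c("P1", "P2"), each = 4),
                                 runif(8))
    expect_error(pooledAncestryCorrelation(cohort2, rep(1, 8)),
                 "no usable strata")
})

test_that("the multi-column pooled correlation agrees with the scalar route", {
    set.seed(5)
    cfg <- tinySimConfig(seed = 12L)
    sim <- simulateCohort(cfg)
    g <- genotypes(sim$cohort)
    Y <- cbind(rowSums(g >= 1L, na.rm = TRUE),
               rnorm(nrow(g)),
               rowSums(g[, 1:50] >= 1L, na.rm = TRUE))
    multi <- AncestryBias:::.pooledRMatrix(sim$cohort, Y)
    for (j in 1:3)
        expect_equal(multi[j],
                     pooledR(pooledAncestryCorrelation(sim$cohort, Y[, j])),
                     tolerance = 1e-12)
})

test_that("BH adjustment reproduces hand-computed q-values and rejects bad input", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhFDR(0.2), 0.2)
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
    q <- bhFDR(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= 0))
    expect_error(bhFDR(c(0.1, 1.2)), "0, 1")
    expect_error(bhFDR(c(0.1, NA)), "0, 1")
})

test_that("BH q-value thresholding equals the classical step-up rejected set", {
    set.seed(6)
    for (i in 1:50) {
        m <- sample(1:40, 1)
        p <- runif(m)^sample(1:3, 1)
        alpha <- runif(1, 0.01, 0.2)
        expect_identical(which(bhFDR(p) <= alpha), bhStepUpRejected(p, alpha))
    }
})

test_that("the chi-square independence statistic matches hand-computed values", {
    even <- AncestryBias:::.chisqIndependence(rbind(c(10, 10), c(10, 10)))
    expect_equal(even$chi2, 0)
    expect_equal(even$p.value, 1)
    ## expected cells all 12.5; chi2 = 4 * 7.5^2 / 12.5 = 18
    skew <- AncestryBias:::.chisqIndependence(rbind(c(20, 5), c(5, 20)))
    expect_equal(skew$chi2, 18)
    expect_equal(skew$df, 1)
    expect_false(skew$exact)
    ## sparse table falls back to the exact test with a warning
    expect_warning(sparse <- AncestryBias:::.chisqIndependence(
        rbind(c(1, 0), c(0, 1))), "exact")
    expect_true(sparse$exact)
    expect_true(sparse$p.value > 0 && sparse$p.value <= 1)
})

test_that("database-trained predictors are over-represented in deleterious PAV calls under the planted model", {
    cfg <- SimConfig(seed = 5L, nVariants = 2000L,
                     dbTrainedAssertBoost = 0.25,
                     depositNBiased = 0L, depositNNeutral = 0L)
    sim <- simulateCohort(cfg)
    ann <- simulateAnnotations(sim, cfg)
    cl <- classifyVariants(ann)
    it <- predictorIndependenceTest(cl, ann)
    expect_lt(it$p.value, 0.01)
    ## over-representation direction: database-trained share higher in PAVs
    sh <- it$table["database_trained", ] / colSums(it$table)
    expect_gt(sh["PAV"], sh["NAV"])
    ## per-predictor table has 11 rows and the same call totals
    itp <- predictorIndependenceTest(cl, ann, perPredictor = TRUE)
    expect_equal(dim(itp$table), c(11L, 2L))
    expect_equal(sum(itp$table), sum(it$table))
})

test_that("the gene scan recovers a planted biased gene and skips degenerate genes", {
    set.seed(7)
    nInd <- 120
    pop <- rep(sprintf("P%d", 1:4), each = 30)
    theta <- runif(nInd, 0.1, 0.9)
    ## gene GBIAS: carriage decreases with ancestry; GFLAT: independent;
    ## GMONO: monomorphic
    gBias <- as.integer(runif(nInd) < 0.6 * (1 - theta))
    gFlat <- as.integer(runif(nInd) < 0.3)
    g <- cbind(gBias, gFlat, 0L)
    colnames(g) <- c("chr1:100:A:T", "chr1:200:G:C", "chr1:300:T:A")
    cohort <- makeCohortFixture(g, pop, theta)
    ann <- makeAnn(n = 3, gene = c("GBIAS", "GFLAT", "GMONO"),
                   clinvar = "pathogenic", nDel = 3L)
    ## variant ids must match the genotype columns
    ann@variants$variant_id <- colnames(g)
    ann@variants$pos <- c(100L, 200L, 300L)
    rownames(ann@popFreqs) <- colnames(g)
    rownames(ann@predictorCalls) <- colnames(g)
    rownames(ann@assertions) <- colnames(g)
    scan <- geneLevelScan(cohort, ann)
    expect_setequal(scan$gene, c("GBIAS", "GFLAT"))
    expect_equal(attr(scan, "untested")$gene, "GMONO")
    expect_lt(scan$pooled_r[scan$gene == "GBIAS"], 0)
    expect_equal(scan$gene[which.min(scan$pooled_r)], "GBIAS")
    expect_true(all(scan$q_value >= scan$p_value))
})

test_that("identical per-gene count vectors give identical scan rows", {
    set.seed(8)
    nInd <- 80
    pop <- rep(c("P1", "P2"), each = 40)
    theta <- runif(nInd)
    carrier <- as.integer(runif(nInd) < 0.4)
    g <- cbind(carrier, carrier)
    colnames(g) <- c("chr1:100:A:T", "chr2:100:A:T")
    cohort <- makeCohortFixture(g, pop, theta)
    ann <- makeAnn(n = 2, gene = c("GA", "GB"), clinvar = "pathogenic",
                   nDel = 2L)
    ann@variants$variant_id <- colnames(g)
    ann@variants$chrom <- c("chr1", "chr2")
    rownames(ann@popFreqs) <- colnames(g)
    rownames(ann@predictorCalls) <- colnames(g)
    rownames(ann@assertions) <- colnames(g)
    scan <- geneLevelScan(cohort, ann)
    expect_equal(scan$pooled_r[1], scan$pooled_r[2])
    expect_equal(scan$p_value[1], scan$p_value[2])
})

test_that("gene-set enrichment handles boundary cases and stays calibrated under the null", {
    expect_error(geneSetEnrichment("a", character(), "a"), "empty universe")
    universe <- sprintf("G%03d", 1:200)
    reference <- universe[1:40]
    ## empty hits: conventional zero odds ratio, p = 1
    empty <- geneSetEnrichment(character(), universe, reference)
    expect_equal(empty$odds_ratio, 0)
    expect_equal(empty$p_value, 1)
    ## hits identical to a proper-subset reference: infinite odds ratio
    ident <- geneSetEnrichment(reference, universe, reference)
    expect_equal(ident$odds_ratio, Inf)
    expect_lt(ident$p_value, 1e-10)
    ## null calibration: uniform hits are not enriched too often
    set.seed(9)
    ps <- replicate(300, geneSetEnrichment(sample(universe, 25), universe,
                                           reference)$p_value)
    expect_gt(mean(ps < 0.05), 0.005)
    expect_lt(mean(ps < 0.05), 0.12)
})
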