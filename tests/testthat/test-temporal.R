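## Shared small planted scenario for the temporal tests.
tempFixture <- function(seed = 21L) {
    cfg <- SimConfig(seed = seed, nPopulations = 8L, nPerPopulation = 30L,
                     ancestryMeans = seq(0.2, 0.85, length.out = 8),
                     nGenes = 60L, nVariants = 4000L, nReleases = 10L,
                     depositRelease = 7L, depositNBiased = 20L,
                     depositNNeutral = 100L, nReferenceAfricans = 5L)
    sim <- simulateCohort(cfg)
    ann <- simulateAnnotations(sim, cfg)
    rs <- simulateReleaseSeries(sim, ann, cfg)
    list(cfg = cfg, sim = sim, ann = ann, rs = rs)
}

test_that("overriding ClinVar swaps in the release assertions and nothing else", {
    fx <- tempFixture()
    rel <- releases(fx$rs$series)[[3]]
    ann2 <- overrideClinVar(fx$ann, rel)
    a <- assertions(ann2)
    relPath <- names(assertions(rel))[assertions(rel) == "pathogenic"]
    expect_setequal(rownames(a)[a[, "ClinVar"] == "pathogenic"],
                    intersect(relPath, variantIds(fx$ann)))
    expect_identical(a[, "OMIM"], assertions(fx$ann)[, "OMIM"])
    expect_identical(a[, "HGMD"], assertions(fx$ann)[, "HGMD"])
})

test_that("the trajectory is deterministic, dated, and tracks database size", {
    fx <- tempFixture()
    traj <- correlationTrajectory(fx$rs$series, fx$sim$cohort, fx$ann)
    expect_equal(nrow(traj), 10L)
    expect_identical(traj$date, releaseDates(fx$rs$series))
    ## db size equals the assertion-map pathogenic cardinality, and grows
    sizes <- vapply(releases(fx$rs$series),
                    function(r) sum(assertions(r) == "pathogenic"), 0)
    expect_equal(traj$n_pathogenic_in_db, sizes)
    expect_true(all(diff(traj$n_pathogenic_in_db) >= 0))
    ## identical releases give identical points
    twice <- ReleaseSeries(list(releases(fx$rs$series)[[2]],
                                DatabaseRelease(
                                    releaseDates(fx$rs$series)[2] + 1,
                                    assertions(releases(fx$rs$series)[[2]]))))
    t2 <- correlationTrajectory(twice, fx$sim$cohort, fx$ann)
    expect_equal(t2$pooled_r[1], t2$pooled_r[2])
    ## recomputation is idempotent
    expect_equal(correlationTrajectory(fx$rs$series, fx$sim$cohort, fx$ann),
                 traj)
})

test_that("a release with no usable assertions is flagged, not an error", {
    fx <- tempFixture()
    empty <- DatabaseRelease("2011-01-01", character())
    s <- ReleaseSeries(list(empty, releases(fx$rs$series)[[1]]))
    traj <- correlationTrajectory(s, fx$sim$cohort, fx$ann)
    expect_true(traj$degenerate[1])
    expect_true(is.na(traj$pooled_r[1]))
    expect_false(traj$degenerate[2])
})

test_that("flip detection requires opposite signs with both points significant", {
    traj <- data.frame(date = as.Date("2014-01-01") + 0:2 * 30,
                       n_pathogenic_in_db = c(10, 20, 30),
                       pooled_r = c(0.7, 0.6, -0.65),
                       p_value = c(0.001, 0.002, 0.003),
                       degenerate = FALSE, filtered = FALSE)
    fl <- detectFlips(traj, alpha = 0.05)
    expect_equal(nrow(fl), 1L)
    expect_equal(fl$date_A, traj$date[2])
    expect_equal(fl$date_B, traj$date[3])
    ## an insignificant second point gates the flip out
    traj$p_value[3] <- 0.4
    expect_equal(nrow(detectFlips(traj, 0.05)), 0L)
    ## NA rows are skipped
    traj$p_value[3] <- 0.003; traj$pooled_r[2] <- NA
    expect_equal(nrow(detectFlips(traj, 0.05)), 0L)
})

test_that("the planted deposit produces exactly one sign flip at the deposit release", {
    fx <- tempFixture()
    traj <- correlationTrajectory(fx$rs$series, fx$sim$cohort, fx$ann)
    fl <- detectFlips(traj)
    expect_equal(nrow(fl), 1L)
    expect_equal(fl$date_B,
                 releaseDates(fx$rs$series)[fx$cfg@depositRelease])
    expect_gt(fl$r_A, 0)
    expect_lt(fl$r_B, 0)
})

test_that("driver attribution: sole candidate, zero-effect monomorphic candidate, exact reversion", {
    fx <- tempFixture()
    ids <- variantIds(fx$ann)
    carried <- ids[colSums(genotypes(fx$sim$cohort) >= 1L, na.rm = TRUE) > 5]
    base <- structure(rep("pathogenic", 30), names = carried[1:30])
    relA <- DatabaseRelease("2014-03-01", base)
    relB <- DatabaseRelease("2014-04-01", c(base,
                structure("pathogenic", names = carried[31])))
    rep1 <- attributeDrivers(relA, relB, fx$sim$cohort, fx$ann)
    expect_equal(nrow(drivers(rep1)), 1L)
    expect_equal(drivers(rep1)$variant_id, carried[31])
    expect_equal(drivers(rep1)$change_type, "added")
    expect_equal(rep1@selectedSetSize, 1L)
    expect_equal(rep1@achievedCoverage, 1, tolerance = 1e-12)

    ## a cohort-monomorphic candidate has exactly zero marginal effect
    mono <- ids[colSums(genotypes(fx$sim$cohort) >= 1L, na.rm = TRUE) == 0][1]
    skip_if(is.na(mono))
    relB2 <- DatabaseRelease("2014-04-01",
                             c(base, structure(rep("pathogenic", 2),
                                               names = c(carried[31], mono))))
    rep2 <- attributeDrivers(relA, relB2, fx$sim$cohort, fx$ann)
    d <- drivers(rep2)
    expect_equal(d$marginal_delta_r[d$variant_id == mono], 0)

    ## reverting every difference reproduces r(A) exactly: the full-rank
    ## selection reaches coverage 1 on any pair from the series
    rel <- releases(fx$rs$series)
    rep3 <- attributeDrivers(rel[[6]], rel[[7]], fx$sim$cohort, fx$ann,
                             coverage = 1)
    expect_gte(rep3@achievedCoverage, 1 - 1e-9)
})

test_that("inconsistent release pairs and misordered dates are rejected", {
    fx <- tempFixture()
    rel <- releases(fx$rs$series)
    expect_error(attributeDrivers(rel[[7]], rel[[6]], fx$sim$cohort, fx$ann),
                 "precede")
    ## same assertions, different dates: no differences and no change; the
    ## degenerate zero-candidate case reports coverage 1
    same <- DatabaseRelease(releaseDates(fx$rs$series)[6] + 1,
                            assertions(rel[[6]]))
    rep0 <- attributeDrivers(rel[[6]], same, fx$sim$cohort, fx$ann)
    expect_equal(nrow(drivers(rep0)), 0L)
    expect_equal(rep0@selectedSetSize, 0L)
})

test_that("planted deposit drivers are recovered ahead of the balanced entries", {
    fx <- tempFixture(seed = 31L)
    rel <- releases(fx$rs$series)
    k <- fx$cfg@depositRelease
    rep_ <- attributeDrivers(rel[[k - 1L]], rel[[k]], fx$sim$cohort, fx$ann,
                             coverage = 0.9)
    d <- drivers(rep_)
    truthBiased <- fx$rs$deposit$variant_id[fx$rs$deposit$role == "biased"]
    firstNeutral <- which(!d$variant_id %in% truthBiased)[1]
    expect_gte(sum(d$variant_id[seq_len(firstNeutral - 1L)] %in% truthBiased),
               ceiling(0.9 * length(truthBiased)))
    expect_gte(rep_@achievedCoverage, 0.9)
    ## the selected set is within the planted ground truth
    expect_true(all(d$variant_id[d$selected] %in%
                    fx$rs$deposit$variant_id))
})
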