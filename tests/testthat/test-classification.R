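cfgDefault <- FilterConfig()

test_that("pathogenic annotation requires an exact assertion in a protein-coding gene", {
    expect_true(isPathogenicAnnotated(makeAnn(clinvar = "pathogenic",
                                              coding = TRUE)))
    expect_false(isPathogenicAnnotated(makeAnn(clinvar = "pathogenic",
                                               coding = FALSE)))
    expect_false(isPathogenicAnnotated(makeAnn()))
    expect_false(isPathogenicAnnotated(makeAnn(clinvar = "non_pathogenic")))
    ## only configured databases count
    cfgHgmd <- FilterConfig(pathogenicDatabases = "HGMD")
    expect_false(isPathogenicAnnotated(makeAnn(clinvar = "pathogenic"),
                                       cfgHgmd))
    expect_true(isPathogenicAnnotated(makeAnn(hgmd = "pathogenic"), cfgHgmd))
})

test_that("deleteriousness needs >= 2 of 11 votes; nonsense/splice auto-qualify; missing votes do not count", {
    expect_true(isDeleterious(makeAnn(nDel = 2L)))
    expect_false(isDeleterious(makeAnn(nDel = 1L)))
    expect_true(isDeleterious(makeAnn(consequence = "nonsense", nDel = 0L)))
    expect_true(isDeleterious(makeAnn(consequence = "splice", nDel = 0L)))
    ## exception off: predictors alone decide
    cfgNoExc <- FilterConfig(applyStopSpliceException = FALSE)
    expect_false(isDeleterious(makeAnn(consequence = "nonsense", nDel = 0L),
                               cfgNoExc))
    ## a missing call is a non-deleterious vote
    expect_false(isDeleterious(makeAnn(nDel = 1L, nMissing = 10L)))
    expect_true(isDeleterious(makeAnn(nDel = 2L, nMissing = 9L)))
})

test_that("the MAF gate folds to minor-allele frequency and is branch-specific", {
    ## PAV with max panel MAF 6% is removed; 3% passes the PAV gate only
    expect_false(passesMaf(makeAnn(freqAFR = 0.06), isPav = TRUE))
    expect_true(passesMaf(makeAnn(freqAFR = 0.03), isPav = TRUE))
    expect_false(passesMaf(makeAnn(freqAFR = 0.03), isPav = FALSE))
    ## exceeding in ANY panel fails
    expect_false(passesMaf(makeAnn(freqAFR = 0.001, freqEUR = 0.06),
                           isPav = TRUE))
    ## frequency folding: f = 0.97 is MAF 0.03
    expect_true(passesMaf(makeAnn(freqAFR = 0.97), isPav = TRUE))
    expect_false(passesMaf(makeAnn(freqAFR = 0.97), isPav = FALSE))
    ## unobserved in every panel = rare
    expect_true(passesMaf(makeAnn(freqAFR = NA, freqEUR = NA), isPav = FALSE))
    ## switch off
    cfgNoMaf <- FilterConfig(applyMafFilter = FALSE)
    expect_true(passesMaf(makeAnn(freqAFR = 0.4), isPav = TRUE, cfgNoMaf))
})

test_that("classification assigns the documented classes and exclusion reasons", {
    cl <- classifyVariants(makeAnn(clinvar = "pathogenic", freqAFR = 0.01,
                                   nDel = 3L))
    expect_equal(cl$class, "DEL_PAV")
    cl <- classifyVariants(makeAnn(clinvar = "pathogenic", freqAFR = 0.01,
                                   nDel = 1L))
    expect_equal(cl$class, "NONDEL_PAV")
    cl <- classifyVariants(makeAnn(nDel = 2L, freqAFR = 0.01))
    expect_equal(cl$class, "DEL_NAV")
    cl <- classifyVariants(makeAnn(nDel = 0L, freqAFR = 0.01))
    expect_equal(cl$class, "NONDEL_NAV")
    ## non-protein-altering NAV is excluded
    cl <- classifyVariants(makeAnn(consequence = "synonymous", nDel = 2L))
    expect_equal(cl$class, "EXCLUDED")
    expect_equal(cl$exclusion_reason, "non_protein_altering")
    cl <- classifyVariants(makeAnn(consequence = "other", coding = FALSE,
                                   gene = ""))
    expect_equal(cl$exclusion_reason, "non_coding")
    ## common pathogenic-annotated entries are removed entirely, not demoted
    cl <- classifyVariants(makeAnn(clinvar = "pathogenic", freqAFR = 0.2,
                                   nDel = 3L))
    expect_equal(cl$class, "EXCLUDED")
    expect_equal(cl$exclusion_reason, "common_maf")
    ## class label and exclusion reason are mutually consistent
    expect_true(all((cl$class == "EXCLUDED") ==
                    (cl$exclusion_reason != "none")))
})

test_that("disabling the deleterious filter merges the split under DEL_* labels", {
    cfg <- FilterConfig(applyDeleteriousFilter = FALSE)
    cl <- classifyVariants(makeAnn(clinvar = "pathogenic", nDel = 0L), cfg)
    expect_equal(cl$class, "DEL_PAV")
    expect_true(attr(cl, "merged"))
    cl <- classifyVariants(makeAnn(nDel = 0L), cfg)
    expect_equal(cl$class, "DEL_NAV")
})

test_that("every variant lands in exactly one bin (partition) and output is deterministic", {
    cfg <- tinySimConfig(seed = 8L)
    sim <- simulateCohort(cfg)
    ann <- simulateAnnotations(sim, cfg)
    set.seed(19)
    for (i in 1:20) {
        fc <- FilterConfig(pavMafCutoff = runif(1, 0.01, 1),
                           navMafCutoff = runif(1, 0.01, 1),
                           minDeleteriousCalls = sample(0:11, 1),
                           applyMafFilter = sample(c(TRUE, FALSE), 1),
                           applyDeleteriousFilter = sample(c(TRUE, FALSE), 1),
                           applyStopSpliceException = sample(c(TRUE, FALSE), 1),
                           pathogenicDatabases = sample(c("OMIM", "HGMD",
                                                          "ClinVar"),
                                                        sample(1:3, 1)))
        cl <- classifyVariants(ann, fc)
        expect_equal(nrow(cl), cfg@nVariants)
        expect_true(all(cl$class %in% c("DEL_PAV", "NONDEL_PAV", "DEL_NAV",
                                        "NONDEL_NAV", "EXCLUDED")))
        expect_identical(cl, classifyVariants(ann, fc))
    }
})

test_that("disabling the MAF filter never shrinks any per-individual class count", {
    cfg <- tinySimConfig(seed = 9L)
    sim <- simulateCohort(cfg)
    ann <- simulateAnnotations(sim, cfg)
    on_ <- perIndividualCounts(sim$cohort, classifyVariants(ann))
    off <- perIndividualCounts(sim$cohort,
                               classifyVariants(ann,
                                   FilterConfig(applyMafFilter = FALSE)))
    expect_true(all(off >= on_))
})

test_that("with the exception on, no nonsense or splice variant is non-deleterious", {
    cfg <- tinySimConfig(seed = 10L)
    sim <- simulateCohort(cfg)
    ann <- simulateAnnotations(sim, cfg)
    cl <- classifyVariants(ann)
    csq <- variants(ann)$consequence
    expect_false(any(cl$class %in% c("NONDEL_PAV", "NONDEL_NAV") &
                     csq %in% c("nonsense", "splice")))
})

test_that("per-individual counts match a brute-force loop in both modes", {
    g <- rbind(c(1L, 2L, 0L, NA, 1L),
               c(0L, 1L, 1L, 2L, 0L),
               c(2L, 0L, NA, 1L, 1L))
    colnames(g) <- sprintf("chr1:%d:A:T", 1:5 * 100L)
    cohort <- makeCohortFixture(g, c("P1", "P1", "P2"), c(0.2, 0.5, 0.8))
    classified <- data.frame(
        variant_id = colnames(g),
        class = c("DEL_PAV", "DEL_NAV", "DEL_NAV", "EXCLUDED", "NONDEL_NAV"),
        exclusion_reason = c("none", "none", "none", "common_maf", "none"))
    for (mode in c("carrier", "allele_dosage")) {
        cnt <- perIndividualCounts(cohort, classified, mode)
        brute <- matrix(0, nrow(g), 4,
                        dimnames = list(rownames(cnt),
                                        c("DEL_PAV", "NONDEL_PAV", "DEL_NAV",
                                          "NONDEL_NAV")))
        for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
            k <- classified$class[j]
            if (k == "EXCLUDED" || is.na(g[i, j])) next
            brute[i, k] <- brute[i, k] +
                if (mode == "carrier") as.numeric(g[i, j] >= 1) else g[i, j]
        }
        expect_equal(cnt, brute)
    }
    ## carrier vs dosage on a homozygous carried variant
    expect_equal(perIndividualCounts(cohort, classified,
                                     "carrier")["S003", "DEL_PAV"], 1)
    expect_equal(perIndividualCounts(cohort, classified,
                                     "allele_dosage")["S003", "DEL_PAV"], 2)
})

test_that("per-individual counts on a simulated cohort equal the exhaustive oracle", {
    cfg <- tinySimConfig(seed = 11L)
    sim <- simulateCohort(cfg)
    ann <- simulateAnnotations(sim, cfg)
    cl <- classifyVariants(ann)
    cnt <- perIndividualCounts(sim$cohort, cl)
    g <- genotypes(sim$cohort)
    clv <- structure(cl$class, names = cl$variant_id)
    for (i in sample(nrow(g), 5)) {
        for (k in colnames(cnt)) {
            ids <- names(clv)[clv == k]
            expect_equal(cnt[i, k],
                         sum(g[i, ids] >= 1L, na.rm = TRUE))
        }
        ## row sum equals the individual's total surviving variant count
        surv <- names(clv)[clv != "EXCLUDED"]
        expect_equal(sum(cnt[i, ]), sum(g[i, surv] >= 1L, na.rm = TRUE))
    }
})

test_that("an all-missing individual yields zero counts and a warning", {
    g <- rbind(c(NA_integer_, NA_integer_), c(1L, 0L), c(0L, 2L), c(1L, 1L))
    colnames(g) <- c("chr1:100:A:T", "chr1:200:G:C")
    cohort <- makeCohortFixture(g, rep("P1", 4), c(0.1, 0.2, 0.3, 0.4))
    classified <- data.frame(variant_id = colnames(g),
                             class = c("DEL_NAV", "DEL_NAV"),
                             exclusion_reason = "none")
    expect_warning(cnt <- perIndividualCounts(cohort, classified),
                   "all-missing")
    expect_equal(unname(cnt[1, ]), rep(0, 4))
})
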