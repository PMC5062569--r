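## Seeded synthetic admixed-cohort generator.
##
## The generator emulates the study conditions of a whole-genome audit of
## ancestry bias in variant prioritization: 16 population samples of an
## admixed African-descent cohort (Beta-distributed African-ancestry
## proportions theta), ancestry-stratified allele frequencies (African
## variation excess on neutral sites, ancestry-independent frequencies on
## truly deleterious sites), clinical databases whose pathogenic assertions
## over-sample variants common outside Africa (Euro-centric skew), in-silico
## predictors whose database-trained subset is more sensitive on asserted
## variants, and a monthly-release series containing one bulk deposit that
## flips the sign of the ancestry-pathogenicity correlation.
##
## Genotypes are Binomial(2, theta * f_afr + (1 - theta) * f_other): the
## analysis consumes only marginal per-individual counts, so no LD or
## local-ancestry tracts are modelled.

.DEFAULT_PREDICTORS <- c("SIFT", "PolyPhen2_HDIV", "PolyPhen2_HVAR", "LRT",
                         "MutationTaster", "MutationAssessor", "FATHMM",
                         "GERP", "PhyloP", "SiPhy", "CADD")
.DEFAULT_PREDICTOR_CATEGORIES <- c(
    SIFT = "agnostic", PolyPhen2_HDIV = "database_trained",
    PolyPhen2_HVAR = "database_trained", LRT = "agnostic",
    MutationTaster = "database_trained", MutationAssessor = "agnostic",
    FATHMM = "database_trained", GERP = "agnostic", PhyloP = "agnostic",
    SiPhy = "agnostic", CADD = "database_trained")

#' Configuration of the synthetic-data generator
#'
#' Slots define the cohort structure, the per-variant frequency model, the
#' assertion bias, the predictor model and the release series. Defaults are
#' the package's standard study conditions; see the methods vignette for the
#' rationale behind each value.
#'
#' @slot seed integer seed from which all generator streams derive.
#' @slot nPopulations,nPerPopulation cohort block structure (16 x 40).
#' @slot ancestryBetaParams nPopulations x 2 matrix of Beta(a, b) parameters
#'   for the per-population African-ancestry distribution.
#' @slot nGenes,nVariants genome scale of the simulation.
#' @slot consequenceProbs named probabilities over
#'   missense/nonsense/splice/synonymous/other.
#' @slot deleteriousTruthProbs per-consequence probability that a variant is
#'   truly deleterious (frequency then ancestry-independent).
#' @slot rareAfrPrivateWeight,rareSharedWeight mixture weights of the rare
#'   neutral variant sharing patterns: African-private (f_other = 0), shared
#'   (f_afr = f_other), other-private (f_afr = 0, weight = remainder).
#'   Cohort-ascertained site lists from African-descent samples are dominated
#'   by African-enriched rare variation, hence the asymmetry.
#' @slot rareFreqBeta Beta parameters of the non-zero rare-variant frequency.
#' @slot commonFraction,commonAfrBeta,commonOtherBeta mixture weight and Beta
#'   parameters of the common neutral variant component (these are the
#'   misidentified common database entries the MAF filter removes).
#' @slot deleteriousBeta Beta parameters of the shared frequency of truly
#'   deleterious variants.
#' @slot constantFrequency when not NA, every variant gets
#'   f_afr = f_other = this value (a no-ancestry-signal control).
#' @slot ancestryFrequencyEffect set FALSE to copy f_other onto f_afr
#'   (removes the ancestry signal while keeping frequency heterogeneity).
#' @slot assertDelRates,assertNeutralBase per-database pathogenic-assertion
#'   probabilities for truly deleterious / neutral variants.
#' @slot euroSkew multiplier on the neutral assertion probability when the
#'   variant is more common outside Africa (1 = unbiased databases).
#' @slot nonPathogenicRate probability a neutral, unasserted variant carries a
#'   ClinVar non-pathogenic (benign-style) entry.
#' @slot predictorNames,predictorCategories the 11 predictors and their
#'   database_trained/agnostic labels.
#' @slot predictorSensitivity,predictorFalsePositive per-predictor call
#'   probabilities on truly deleterious / neutral variants.
#' @slot dbTrainedAssertBoost additive call-probability boost for
#'   database-trained predictors on pathogenic-asserted variants.
#' @slot predictorMissingRate probability a predictor score is missing.
#' @slot genotypeMissingRate probability a genotype call is missing.
#' @slot nReleases,startDate,releaseIntervalDays,initialFraction release
#'   series shape: linear growth from initialFraction of the assertion pool
#'   to the full pool.
#' @slot depositRelease,depositNBiased,depositNNeutral,depositDirection,
#'   depositBiasedMajorRange,depositBiasedMinorRange,depositNeutralRange
#'   the planted bulk deposit: at release \code{depositRelease},
#'   \code{depositNBiased} strongly ancestry-skewed variants (major-allele
#'   frequency drawn on the \code{depositDirection} side) and
#'   \code{depositNNeutral} ancestry-balanced variants enter the database.
#' @slot nReferenceAfricans,referenceLabel reference-panel rows appended to
#'   the Q-matrix so the >99\%-membership cluster rule is exercisable.
#' @export
setClass("SimConfig",
    representation(seed = "integer", nPopulations = "integer",
                   nPerPopulation = "integer", ancestryBetaParams = "matrix",
                   nGenes = "integer", nVariants = "integer",
                   consequenceProbs = "numeric",
                   deleteriousTruthProbs = "numeric",
                   rareAfrPrivateWeight = "numeric",
                   rareSharedWeight = "numeric", rareFreqBeta = "numeric",
                   commonFraction = "numeric", commonAfrBeta = "numeric",
                   commonOtherBeta = "numeric", deleteriousBeta = "numeric",
                   constantFrequency = "numeric",
                   ancestryFrequencyEffect = "logical",
                   assertDelRates = "numeric", assertNeutralBase = "numeric",
                   euroSkew = "numeric", nonPathogenicRate = "numeric",
                   predictorNames = "character",
                   predictorCategories = "character",
                   predictorSensitivity = "numeric",
                   predictorFalsePositive = "numeric",
                   dbTrainedAssertBoost = "numeric",
                   predictorMissingRate = "numeric",
                   genotypeMissingRate = "numeric",
                   nReleases = "integer", startDate = "Date",
                   releaseIntervalDays = "integer",
                   initialFraction = "numeric", depositRelease = "integer",
                   depositNBiased = "integer", depositNNeutral = "integer",
                   depositDirection = "character",
                   depositBiasedMajorRange = "numeric",
                   depositBiasedMinorRange = "numeric",
                   depositNeutralRange = "numeric",
                   nReferenceAfricans = "integer",
                   referenceLabel = "character"))

setValidity("SimConfig", function(object) {
    msgs <- character()
    probs <- c(object@consequenceProbs, object@deleteriousTruthProbs,
               object@assertDelRates, object@assertNeutralBase,
               object@nonPathogenicRate, object@predictorSensitivity,
               object@predictorFalsePositive, object@dbTrainedAssertBoost,
               object@predictorMissingRate, object@genotypeMissingRate,
               object@commonFraction, object@initialFraction)
    if (any(probs < 0 | probs > 1))
        msgs <- c(msgs, "all probabilities must lie in [0, 1]")
    if (abs(sum(object@consequenceProbs) - 1) > 1e-8)
        msgs <- c(msgs, "consequenceProbs must sum to 1")
    if (nrow(object@ancestryBetaParams) != object@nPopulations)
        msgs <- c(msgs, "one (a, b) pair per population is required")
    if (any(object@ancestryBetaParams <= 0))
        msgs <- c(msgs, "ancestry Beta parameters must be positive")
    if (length(object@predictorNames) != 11L)
        msgs <- c(msgs, "exactly 11 predictors are required")
    if (object@depositRelease < 1L || object@depositRelease > object@nReleases)
        msgs <- c(msgs, "deposit release must lie within the series")
    if (!object@depositDirection %in% c("euro", "afr"))
        msgs <- c(msgs, "depositDirection must be 'euro' or 'afr'")
    if (object@euroSkew < 0)
        msgs <- c(msgs, "euroSkew must be >= 0")
    if (object@rareAfrPrivateWeight + object@rareSharedWeight > 1 ||
        object@rareAfrPrivateWeight < 0 || object@rareSharedWeight < 0)
        msgs <- c(msgs, "rare sharing-pattern weights must be a sub-simplex")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SimConfig
#'
#' All arguments default to the package's standard study conditions.
#'
#' @param seed integer master seed.
#' @param nPopulations,nPerPopulation cohort block structure.
#' @param ancestryMeans per-population mean African-ancestry proportions
#'   (used with \code{ancestryConcentration} to build the Beta parameters
#'   unless \code{ancestryBetaParams} is supplied).
#' @param ancestryConcentration Beta concentration a + b.
#' @param ancestryBetaParams explicit nPopulations x 2 Beta parameter matrix.
#' @param nGenes,nVariants genome scale.
#' @param ... remaining slots by name (see \linkS4class{SimConfig}).
#' @return A \linkS4class{SimConfig}.
#' @export
SimConfig <- function(seed = 1L, nPopulations = 16L, nPerPopulation = 40L,
                      ancestryMeans = seq(0.15, 0.9,
                                          length.out = nPopulations),
                      ancestryConcentration = 8,
                      ancestryBetaParams = cbind(
                          ancestryMeans * ancestryConcentration,
                          (1 - ancestryMeans) * ancestryConcentration),
                      nGenes = 300L, nVariants = 20000L, ...) {
    dots <- list(...)
    defaults <- list(
        consequenceProbs = c(missense = 0.50, nonsense = 0.05, splice = 0.05,
                             synonymous = 0.22, other = 0.18),
        deleteriousTruthProbs = c(missense = 0.15, nonsense = 0.60,
                                  splice = 0.60, synonymous = 0.01,
                                  other = 0.02),
        rareAfrPrivateWeight = 0.55, rareSharedWeight = 0.30,
        rareFreqBeta = c(0.6, 60),
        commonFraction = 0.15, commonAfrBeta = c(2, 10),
        commonOtherBeta = c(2, 25), deleteriousBeta = c(0.5, 150),
        constantFrequency = NA_real_, ancestryFrequencyEffect = TRUE,
        assertDelRates = c(OMIM = 0.12, HGMD = 0.30, ClinVar = 0.25),
        assertNeutralBase = c(OMIM = 0.0075, HGMD = 0.06, ClinVar = 0.045),
        euroSkew = 1.5, nonPathogenicRate = 0.01,
        predictorNames = .DEFAULT_PREDICTORS,
        predictorCategories = .DEFAULT_PREDICTOR_CATEGORIES,
        predictorSensitivity = 0.5, predictorFalsePositive = 0.07,
        dbTrainedAssertBoost = 0.06, predictorMissingRate = 0.05,
        genotypeMissingRate = 0.002,
        nReleases = 30L, startDate = as.Date("2012-06-16"),
        releaseIntervalDays = 34L, initialFraction = 0.45,
        depositRelease = 20L, depositNBiased = 50L, depositNNeutral = 500L,
        depositDirection = "euro",
        depositBiasedMajorRange = c(0.30, 0.50),
        depositBiasedMinorRange = c(0, 0.01),
        depositNeutralRange = c(0.005, 0.04),
        nReferenceAfricans = 20L, referenceLabel = "ref_AFR")
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown))
        stop("unknown SimConfig parameter(s): ", paste(unknown, collapse = ", "))
    slots <- utils::modifyList(defaults, dots)
    intSlots <- c("nReleases", "depositRelease", "depositNBiased",
                  "depositNNeutral", "nReferenceAfricans",
                  "releaseIntervalDays")
    for (s in intSlots) slots[[s]] <- as.integer(slots[[s]])
    slots$startDate <- as.Date(slots$startDate)
    do.call(new, c(list("SimConfig", seed = as.integer(seed),
                        nPopulations = as.integer(nPopulations),
                        nPerPopulation = as.integer(nPerPopulation),
                        ancestryBetaParams = ancestryBetaParams,
                        nGenes = as.integer(nGenes),
                        nVariants = as.integer(nVariants)),
                   slots))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nPopulations, "populations x",
        object@nPerPopulation, "individuals,", object@nVariants, "variants,",
        object@nGenes, "genes,", object@nReleases,
        "releases (deposit at", paste0(object@depositRelease, ","),
        object@depositDirection, "direction), seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## cohort + variants
## ---------------------------------------------------------------------------

#' Simulate an admixed cohort and its variant sites
#'
#' Draws per-individual African-ancestry proportions theta from the
#' per-population Beta distributions, per-variant ancestry-stratified allele
#' frequencies (f_afr, f_other), and genotypes Binomial(2, theta f_afr +
#' (1 - theta) f_other). Ground truth (truly-deleterious status, generating
#' frequencies, deposit roles) is returned alongside.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{cohort} (\linkS4class{AdmixedCohort}),
#'   \code{variants} (data.frame) and \code{truth} (data.frame with
#'   \code{variant_id}, \code{trulyDeleterious}, \code{fAfr}, \code{fOther},
#'   \code{depositRole}).
#' @export
simulateCohort <- function(cfg = SimConfig()) {
    set.seed(.streamSeed(cfg@seed, "cohort"))
    nPop <- cfg@nPopulations; nPer <- cfg@nPerPopulation
    popNames <- sprintf("POP%02d", seq_len(nPop))
    theta <- numeric(0)
    for (p in seq_len(nPop))
        theta <- c(theta, stats::rbeta(nPer, cfg@ancestryBetaParams[p, 1],
                                       cfg@ancestryBetaParams[p, 2]))
    nInd <- nPop * nPer
    ind <- data.frame(individual_id = sprintf("IND%04d", seq_len(nInd)),
                      population = rep(popNames, each = nPer),
                      africanAncestry = theta, stringsAsFactors = FALSE)

    n <- cfg@nVariants
    chromNum <- sample.int(22L, n, replace = TRUE)
    pos <- sample.int(240000000L, n)           # globally unique positions
    refIdx <- sample.int(4L, n, replace = TRUE)
    altIdx <- 1L + (refIdx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L
    bases <- c("A", "C", "G", "T")
    csq <- sample(names(cfg@consequenceProbs), n, replace = TRUE,
                  prob = cfg@consequenceProbs)
    genePool <- sprintf("G%04d", seq_len(cfg@nGenes))
    gene <- ifelse(csq == "other", "", sample(genePool, n, replace = TRUE))
    trulyDel <- stats::rbinom(n, 1L, cfg@deleteriousTruthProbs[csq]) == 1L

    ## frequency model
    if (!is.na(cfg@constantFrequency)) {
        fAfr <- rep(cfg@constantFrequency, n)
        fOther <- fAfr
        depositRole <- rep("none", n)
    } else {
        common <- stats::rbinom(n, 1L, cfg@commonFraction) == 1L
        fAfr <- fOther <- numeric(n)
        iN <- which(!trulyDel & !common)
        wS <- cfg@rareSharedWeight; wA <- cfg@rareAfrPrivateWeight
        pattern <- sample(c("afr_private", "shared", "other_private"),
                          length(iN), replace = TRUE,
                          prob = c(wA, wS, 1 - wA - wS))
        fr <- stats::rbeta(length(iN), cfg@rareFreqBeta[1],
                           cfg@rareFreqBeta[2])
        fAfr[iN] <- ifelse(pattern == "other_private", 0, fr)
        fOther[iN] <- ifelse(pattern == "afr_private", 0, fr)
        iC <- !trulyDel & common
        fAfr[iC] <- stats::rbeta(sum(iC), cfg@commonAfrBeta[1],
                                 cfg@commonAfrBeta[2])
        fOther[iC] <- stats::rbeta(sum(iC), cfg@commonOtherBeta[1],
                                   cfg@commonOtherBeta[2])
        fDel <- stats::rbeta(sum(trulyDel), cfg@deleteriousBeta[1],
                             cfg@deleteriousBeta[2])
        fAfr[trulyDel] <- fDel
        fOther[trulyDel] <- fDel
        if (!cfg@ancestryFrequencyEffect) fAfr <- fOther

        ## planted database deposit: strongly skewed + balanced variants
        ## The deposit emulates one bulk database submission: a coding,
        ## strongly ancestry-skewed slice (the planted drivers) plus a larger
        ## ancestry-balanced slice of entries that fail the coding filters,
        ## so the filtered analysis is nearly insensitive to the deposit.
        depositRole <- rep("none", n)
        nDep <- cfg@depositNBiased + cfg@depositNNeutral
        if (nDep > 0L) {
            eligCoding <- which(!trulyDel & !common & csq == "missense")
            eligNonCoding <- which(!trulyDel & !common & csq == "other")
            if (length(eligCoding) < cfg@depositNBiased ||
                length(eligNonCoding) < cfg@depositNNeutral)
                stop("not enough eligible variants to plant the deposit")
            biased <- sample(eligCoding, cfg@depositNBiased)
            balanced <- sample(eligNonCoding, cfg@depositNNeutral)
            depositRole[biased] <- "biased"
            depositRole[balanced] <- "neutral"
            major <- stats::runif(length(biased),
                                  cfg@depositBiasedMajorRange[1],
                                  cfg@depositBiasedMajorRange[2])
            minor <- stats::runif(length(biased),
                                  cfg@depositBiasedMinorRange[1],
                                  cfg@depositBiasedMinorRange[2])
            if (cfg@depositDirection == "euro") {
                fOther[biased] <- major; fAfr[biased] <- minor
            } else {
                fAfr[biased] <- major; fOther[biased] <- minor
            }
            fb <- stats::runif(length(balanced), cfg@depositNeutralRange[1],
                               cfg@depositNeutralRange[2])
            fAfr[balanced] <- fb
            fOther[balanced] <- fb
        }
    }

    ord <- order(chromNum, pos)
    chrom <- paste0("chr", chromNum)
    v <- data.frame(variant_id = .variantId(chrom, pos, bases[refIdx],
                                            bases[altIdx]),
                    chrom = chrom, pos = pos, ref = bases[refIdx],
                    alt = bases[altIdx], gene = gene, consequence = csq,
                    inProteinCodingGene = csq != "other",
                    proteinAltering = csq %in% c("missense", "nonsense",
                                                 "splice"),
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
    rownames(v) <- NULL
    truth <- data.frame(variant_id = v$variant_id,
                        trulyDeleterious = trulyDel[ord],
                        fAfr = fAfr[ord], fOther = fOther[ord],
                        depositRole = depositRole[ord],
                        stringsAsFactors = FALSE)

    ## genotypes in variant blocks to bound memory
    G <- matrix(0L, nInd, n)
    block <- 4000L
    for (s in seq(1L, n, by = block)) {
        e <- min(s + block - 1L, n)
        q <- outer(theta, truth$fAfr[s:e]) +
             outer(1 - theta, truth$fOther[s:e])
        G[, s:e] <- stats::rbinom(length(q), 2L, q)
    }
    if (cfg@genotypeMissingRate > 0) {
        nm <- stats::rbinom(1L, length(G), cfg@genotypeMissingRate)
        if (nm > 0L) G[sample.int(length(G), nm)] <- NA_integer_
    }
    colnames(G) <- truth$variant_id
    list(cohort = AdmixedCohort(ind, G), variants = v, truth = truth)
}

## ---------------------------------------------------------------------------
## annotations
## ---------------------------------------------------------------------------

#' Simulate the per-variant annotation table
#'
#' Population-panel frequencies come from the generating frequencies;
#' pathogenic assertions are drawn per database, with neutral variants that
#' are more common outside Africa asserted \code{euroSkew} times more often
#' (the planted Euro-centric database bias); predictor calls use
#' category-dependent sensitivities, database-trained predictors receiving an
#' extra call-probability boost on asserted variants.
#'
#' @param sim output of \code{\link{simulateCohort}}.
#' @param cfg the same \linkS4class{SimConfig}.
#' @return A \linkS4class{VariantAnnotations}.
#' @export
simulateAnnotations <- function(sim, cfg = SimConfig()) {
    set.seed(.streamSeed(cfg@seed, "annotations"))
    v <- sim$variants; tr <- sim$truth
    n <- nrow(v)
    popFreqs <- cbind(AFR = tr$fAfr, EUR = tr$fOther,
                      AMR = 0.5 * tr$fAfr + 0.5 * tr$fOther)
    rownames(popFreqs) <- v$variant_id

    euroCommon <- tr$fOther > tr$fAfr
    isDeposit <- tr$depositRole != "none"
    assertions <- matrix("absent", n, 3,
                         dimnames = list(v$variant_id, CORE_DATABASES))
    for (db in CORE_DATABASES) {
        p <- ifelse(tr$trulyDeleterious, cfg@assertDelRates[[db]],
                    pmin(cfg@assertNeutralBase[[db]] *
                         ifelse(euroCommon, cfg@euroSkew, 1), 1))
        hit <- stats::rbinom(n, 1L, p) == 1L
        if (db == "ClinVar") hit[isDeposit] <- TRUE
        else hit[isDeposit] <- FALSE
        assertions[hit, db] <- "pathogenic"
    }
    ## benign-style entries: found in the database, not disease-causing
    benign <- assertions[, "ClinVar"] == "absent" & !tr$trulyDeleterious &
        stats::rbinom(n, 1L, cfg@nonPathogenicRate) == 1L
    assertions[benign, "ClinVar"] <- "non_pathogenic"

    assertedAny <- rowSums(assertions == "pathogenic") > 0L
    calls <- matrix("benign", n, 11L,
                    dimnames = list(v$variant_id, cfg@predictorNames))
    cats <- cfg@predictorCategories[cfg@predictorNames]
    for (j in seq_len(11L)) {
        p <- ifelse(tr$trulyDeleterious, cfg@predictorSensitivity,
                    cfg@predictorFalsePositive)
        if (cats[j] == "database_trained")
            p <- pmin(p + cfg@dbTrainedAssertBoost * assertedAny, 0.98)
        del <- stats::rbinom(n, 1L, p) == 1L
        calls[del, j] <- "deleterious"
        miss <- stats::rbinom(n, 1L, cfg@predictorMissingRate) == 1L
        calls[miss, j] <- "missing"
    }
    VariantAnnotations(v, popFreqs, calls, cats, assertions)
}

## ---------------------------------------------------------------------------
## release series
## ---------------------------------------------------------------------------

#' Simulate a versioned release series with a planted deposit
#'
#' The ClinVar-asserted set of the annotation table (minus the deposit) grows
#' linearly from \code{initialFraction} of the pool at the first release to
#' the full pool at the last, in a seeded random order. At
#' \code{depositRelease} the planted deposit (ancestry-skewed plus balanced
#' variants) enters in one step and persists; that release receives no
#' regular additions, so the between-release difference at the deposit is
#' exactly the deposit. Database size is monotone non-decreasing.
#'
#' @param sim output of \code{\link{simulateCohort}}.
#' @param ann output of \code{\link{simulateAnnotations}}.
#' @param cfg the same \linkS4class{SimConfig}.
#' @return list with \code{series} (\linkS4class{ReleaseSeries}) and
#'   \code{deposit} (ground-truth data.frame: \code{variant_id}, \code{role}).
#' @export
simulateReleaseSeries <- function(sim, ann, cfg = SimConfig()) {
    set.seed(.streamSeed(cfg@seed, "releases"))
    a <- assertions(ann)[, "ClinVar"]
    depositIds <- sim$truth$variant_id[sim$truth$depositRole != "none"]
    pool <- setdiff(names(a)[a == "pathogenic"], depositIds)
    if (!length(pool)) stop("no ClinVar-asserted variants to build a series")
    nonPath <- names(a)[a == "non_pathogenic"]
    perm <- sample(pool)
    R <- cfg@nReleases
    sizes <- round(seq(cfg@initialFraction * length(perm), length(perm),
                       length.out = R))
    k <- cfg@depositRelease
    if (k > 1L) sizes[k] <- sizes[k - 1L]
    sizes <- cummax(sizes)
    dates <- cfg@startDate + (seq_len(R) - 1L) * cfg@releaseIntervalDays
    rel <- vector("list", R)
    for (r in seq_len(R)) {
        ids <- perm[seq_len(sizes[r])]
        if (r >= k) ids <- c(ids, depositIds)
        asr <- c(structure(rep("pathogenic", length(ids)), names = ids),
                 structure(rep("non_pathogenic", length(nonPath)),
                           names = nonPath))
        rel[[r]] <- DatabaseRelease(dates[r], asr)
    }
    deposit <- sim$truth[sim$truth$depositRole != "none",
                         c("variant_id", "depositRole")]
    names(deposit) <- c("variant_id", "role")
    rownames(deposit) <- NULL
    list(series = ReleaseSeries(rel), deposit = deposit)
}

## ---------------------------------------------------------------------------
## full bundle on disk
## ---------------------------------------------------------------------------

#' Generate and write a complete synthetic input bundle
#'
#' Writes cohort.vcf, annotations.tsv, qmatrix.Q, pops.tsv, releases/ (one
#' TSV per dated release), panel_genes.txt, mendelian_genes.txt,
#' gwas_genes.txt and truth/ sidecars (deposit and truly-deleterious ground
#' truth, generator parameters) under \code{dir}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (\code{cohort},
#'   \code{variants}, \code{truth}, \code{ann}, \code{series},
#'   \code{deposit}, \code{panelGenes}) and the written \code{files}.
#' @export
simulateBundle <- function(cfg = SimConfig(), dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "releases"), showWarnings = FALSE)
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    sim <- simulateCohort(cfg)
    ann <- simulateAnnotations(sim, cfg)
    rs <- simulateReleaseSeries(sim, ann, cfg)

    files <- character()
    f <- file.path(dir, "cohort.vcf")
    writeCohortVCF(sim$cohort, sim$variants, f); files <- c(files, f)
    f <- file.path(dir, "annotations.tsv")
    writeAnnotationTable(ann, f); files <- c(files, f)
    files <- c(files, writeReleaseSeries(rs$series, file.path(dir, "releases")))

    ## Q-matrix with appended reference-African rows
    set.seed(.streamSeed(cfg@seed, "qmatrix"))
    theta <- individuals(sim$cohort)$africanAncestry
    refTheta <- stats::runif(cfg@nReferenceAfricans, 0.992, 0.999)
    allTheta <- c(theta, refTheta)
    K <- 4L
    othersRaw <- matrix(stats::rgamma(length(allTheta) * (K - 1L), 1), ncol = K - 1L)
    others <- othersRaw / rowSums(othersRaw) * (1 - allTheta)
    afrCol <- sample.int(K, 1L)
    Q <- matrix(0, length(allTheta), K)
    Q[, afrCol] <- allTheta
    Q[, setdiff(seq_len(K), afrCol)] <- others
    f <- file.path(dir, "qmatrix.Q")
    utils::write.table(format(Q, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       f, sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, f)

    pops <- rbind(individuals(sim$cohort)[, c("individual_id", "population")],
                  data.frame(individual_id = sprintf("REF%03d",
                                 seq_len(cfg@nReferenceAfricans)),
                             population = cfg@referenceLabel))
    f <- file.path(dir, "pops.tsv")
    utils::write.table(pops, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)

    ## gene lists
    set.seed(.streamSeed(cfg@seed, "panel"))
    genePool <- sprintf("G%04d", seq_len(cfg@nGenes))
    panel <- sort(sample(genePool, min(200L, cfg@nGenes)))
    mendelian <- sort(sample(genePool, min(60L, cfg@nGenes)))
    gwas <- sort(sample(genePool, min(100L, cfg@nGenes)))
    writeLines(panel, file.path(dir, "panel_genes.txt"))
    writeLines(mendelian, file.path(dir, "mendelian_genes.txt"))
    writeLines(gwas, file.path(dir, "gwas_genes.txt"))
    files <- c(files, file.path(dir, c("panel_genes.txt",
                                       "mendelian_genes.txt",
                                       "gwas_genes.txt")))

    ## ground-truth sidecars
    f <- file.path(dir, "truth", "deposit.tsv")
    utils::write.table(rs$deposit, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "truth", "generating_frequencies.tsv")
    utils::write.table(sim$truth, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)

    invisible(list(cohort = sim$cohort, variants = sim$variants,
                   truth = sim$truth, ann = ann, series = rs$series,
                   deposit = rs$deposit, panelGenes = panel,
                   mendelianGenes = mendelian, gwasGenes = gwas,
                   files = files))
}

## ---------------------------------------------------------------------------
## analytic generator target
## ---------------------------------------------------------------------------

#' Analytic within-population correlation implied by the generator
#'
#' For one population with theta ~ Beta(a, b) and carrier counts over the
#' supplied variant frequencies, computes the model-implied Pearson
#' correlation between theta and the total carrier count by quadrature over
#' the theta distribution: the carrier probability of a variant is
#' h(theta) = 1 - (1 - q)^2 with q = theta f_afr + (1 - theta) f_other, the
#' count signal variance is Var(sum h), the Binomial noise is E[sum h(1-h)].
#'
#' @param fAfr,fOther generating allele frequencies.
#' @param a,b Beta parameters of the population's ancestry distribution.
#' @param gridSize quadrature size (equal-probability theta quantiles).
#' @return the analytic correlation (numeric scalar).
#' @export
analyticWithinPopCorrelation <- function(fAfr, fOther, a, b,
                                         gridSize = 512L) {
    tq <- stats::qbeta((seq_len(gridSize) - 0.5) / gridSize, a, b)
    q <- outer(tq, fAfr) + outer(1 - tq, fOther)   # grid x variants
    h <- 1 - (1 - q)^2
    S <- rowSums(h)
    noise <- mean(rowSums(h * (1 - h)))
    covTS <- mean(tq * S) - mean(tq) * mean(S)
    varS <- mean(S^2) - mean(S)^2
    sdT <- sqrt(mean(tq^2) - mean(tq)^2)
    covTS / (sdT * sqrt(varS + noise))
}
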