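## Central S4 containers for the bias audit.

#' @import methods
NULL

## controlled vocabularies used across the package
VARIANT_CLASSES    <- c("DEL_PAV", "NONDEL_PAV", "DEL_NAV", "NONDEL_NAV", "EXCLUDED")
COUNTED_CLASSES    <- c("DEL_PAV", "NONDEL_PAV", "DEL_NAV", "NONDEL_NAV")
EXCLUSION_REASONS  <- c("common_maf", "non_coding", "non_protein_altering", "none")
CORE_DATABASES     <- c("OMIM", "HGMD", "ClinVar")
ASSERTION_LEVELS   <- c("pathogenic", "non_pathogenic", "absent")
PREDICTOR_LEVELS   <- c("deleterious", "benign", "missing")
PREDICTOR_CATEGORIES <- c("database_trained", "agnostic")
CONSEQUENCE_LEVELS <- c("missense", "nonsense", "splice", "synonymous", "other")

.checkVariantTable <- function(v) {
    msgs <- character()
    need <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
              "consequence", "inProteinCodingGene", "proteinAltering")
    miss <- setdiff(need, names(v))
    if (length(miss))
        return(paste("variant table lacks column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(v$variant_id))
        msgs <- c(msgs, "variant_id values must be unique")
    if (any(v$pos < 1))
        msgs <- c(msgs, "positions must be 1-based (pos >= 1)")
    if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L))
        msgs <- c(msgs, "only single-nucleotide ref/alt alleles are supported")
    if (any(v$ref == v$alt))
        msgs <- c(msgs, "ref and alt alleles must differ")
    if (!all(v$consequence %in% CONSEQUENCE_LEVELS))
        msgs <- c(msgs, paste("consequence must be one of:",
                              paste(CONSEQUENCE_LEVELS, collapse = ", ")))
    msgs
}

## ---------------------------------------------------------------------------
## AdmixedCohort
## ---------------------------------------------------------------------------

#' Admixed cohort with ancestry proportions and genotypes
#'
#' Holds the study individuals (one population label and one African-ancestry
#' proportion each) together with an individuals-by-variants matrix of
#' alternate-allele counts (0, 1, 2; \code{NA} marks a missing genotype call).
#'
#' @slot individuals data.frame with columns \code{individual_id},
#'   \code{population}, \code{africanAncestry}.
#' @slot genotypes integer matrix, rows named by individual, columns by
#'   \code{variant_id}.
#' @export
setClass("AdmixedCohort",
    representation(individuals = "data.frame", genotypes = "matrix"))

setValidity("AdmixedCohort", function(object) {
    ind <- object@individuals
    msgs <- character()
    need <- c("individual_id", "population", "africanAncestry")
    if (!all(need %in% names(ind)))
        return(paste("individuals needs columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(ind$individual_id))
        msgs <- c(msgs, "individual_id values must be unique")
    th <- ind$africanAncestry
    if (any(is.na(th)) || any(th < 0 | th > 1))
        msgs <- c(msgs, "africanAncestry proportions must lie in [0, 1]")
    g <- object@genotypes
    if (nrow(g) != nrow(ind) || !identical(rownames(g), ind$individual_id))
        msgs <- c(msgs, "genotype rows must match individuals (same ids, same order)")
    if (is.null(colnames(g)))
        msgs <- c(msgs, "genotype columns must be named by variant_id")
    vals <- g[!is.na(g)]
    if (length(vals) && (any(vals < 0L) || any(vals > 2L)))
        msgs <- c(msgs, "allele counts must be 0, 1 or 2 (NA = missing)")
    if (length(msgs)) msgs else TRUE
})

#' Construct an AdmixedCohort
#'
#' @param individuals data.frame with \code{individual_id}, \code{population},
#'   \code{africanAncestry} columns.
#' @param genotypes integer matrix of alternate-allele counts, rows in the same
#'   order as \code{individuals}, columns named by variant id.
#' @return An \linkS4class{AdmixedCohort}.
#' @export
AdmixedCohort <- function(individuals, genotypes) {
    individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    rownames(genotypes) <- individuals$individual_id
    new("AdmixedCohort", individuals = individuals, genotypes = genotypes)
}

## ---------------------------------------------------------------------------
## VariantAnnotations
## ---------------------------------------------------------------------------

#' Per-variant annotation: frequencies, predictor calls, database assertions
#'
#' Row order is shared across all slots and matches
#' \code{variants(x)$variant_id}.
#'
#' @slot variants data.frame with \code{variant_id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{gene}, \code{consequence},
#'   \code{inProteinCodingGene}, \code{proteinAltering}.
#' @slot popFreqs numeric matrix of alternate-allele frequencies per
#'   population panel (values in [0, 1], NA = unobserved).
#' @slot predictorCalls character matrix with exactly 11 columns (one per
#'   in-silico predictor), values \code{deleterious}, \code{benign} or
#'   \code{missing}.
#' @slot predictorCategories named character vector mapping each predictor to
#'   \code{database_trained} or \code{agnostic}.
#' @slot assertions character matrix with one column per clinical database
#'   (at least OMIM, HGMD, ClinVar), values \code{pathogenic},
#'   \code{non_pathogenic} or \code{absent}.
#' @export
setClass("VariantAnnotations",
    representation(variants = "data.frame", popFreqs = "matrix",
                   predictorCalls = "matrix", predictorCategories = "character",
                   assertions = "matrix"))

setValidity("VariantAnnotations", function(object) {
    msgs <- .checkVariantTable(object@variants)
    n <- nrow(object@variants)
    if (nrow(object@popFreqs) != n || nrow(object@predictorCalls) != n ||
        nrow(object@assertions) != n)
        msgs <- c(msgs, "all annotation matrices must have one row per variant")
    fr <- object@popFreqs[!is.na(object@popFreqs)]
    if (length(fr) && (any(fr < 0) || any(fr > 1)))
        msgs <- c(msgs, "population frequencies must lie in [0, 1]")
    if (ncol(object@predictorCalls) != 11L)
        msgs <- c(msgs, "exactly 11 predictor call columns are required")
    if (!all(object@predictorCalls %in% PREDICTOR_LEVELS))
        msgs <- c(msgs, "predictor calls must be deleterious/benign/missing")
    pc <- object@predictorCategories
    if (!identical(sort(names(pc)), sort(colnames(object@predictorCalls))))
        msgs <- c(msgs, "predictorCategories must be named by the 11 predictors")
    if (!all(pc %in% PREDICTOR_CATEGORIES))
        msgs <- c(msgs, "predictor categories must be database_trained/agnostic")
    if (!all(CORE_DATABASES %in% colnames(object@assertions)))
        msgs <- c(msgs, "assertions must cover OMIM, HGMD and ClinVar")
    if (!all(object@assertions %in% ASSERTION_LEVELS))
        msgs <- c(msgs, "assertions must be pathogenic/non_pathogenic/absent")
    if (length(msgs)) msgs else TRUE
})

#' Construct a VariantAnnotations object
#'
#' @param variants variant data.frame (see \linkS4class{VariantAnnotations}).
#' @param popFreqs numeric matrix of per-panel alternate-allele frequencies.
#' @param predictorCalls character matrix of 11 predictor calls.
#' @param predictorCategories named character vector
#'   (\code{database_trained}/\code{agnostic}) for the 11 predictors.
#' @param assertions character matrix of per-database assertions.
#' @return A \linkS4class{VariantAnnotations}.
#' @export
VariantAnnotations <- function(variants, popFreqs, predictorCalls,
                               predictorCategories, assertions) {
    variants <- as.data.frame(variants, stringsAsFactors = FALSE)
    rn <- variants$variant_id
    popFreqs <- as.matrix(popFreqs); rownames(popFreqs) <- rn
    predictorCalls <- as.matrix(predictorCalls); rownames(predictorCalls) <- rn
    assertions <- as.matrix(assertions); rownames(assertions) <- rn
    new("VariantAnnotations", variants = variants, popFreqs = popFreqs,
        predictorCalls = predictorCalls,
        predictorCategories = predictorCategories, assertions = assertions)
}

## ---------------------------------------------------------------------------
## DatabaseRelease / ReleaseSeries
## ---------------------------------------------------------------------------

#' One dated snapshot of pathogenic assertions
#'
#' @slot date release date (\code{Date}).
#' @slot assertions named character vector, names are variant ids, values
#'   \code{pathogenic} or \code{non_pathogenic}; absence from the vector means
#'   the variant is absent from the release.
#' @export
setClass("DatabaseRelease",
    representation(date = "Date", assertions = "character"))

setValidity("DatabaseRelease", function(object) {
    msgs <- character()
    if (length(object@date) != 1L || is.na(object@date))
        msgs <- c(msgs, "a single non-missing release date is required")
    a <- object@assertions
    if (length(a)) {
        if (is.null(names(a)) || anyDuplicated(names(a)))
            msgs <- c(msgs, "assertions must be uniquely named by variant_id")
        if (!all(a %in% c("pathogenic", "non_pathogenic")))
            msgs <- c(msgs, "release assertions must be pathogenic/non_pathogenic")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a DatabaseRelease
#' @param date release date (coerced with \code{as.Date}).
#' @param assertions named character vector of assertions.
#' @return A \linkS4class{DatabaseRelease}.
#' @export
DatabaseRelease <- function(date, assertions = character()) {
    new("DatabaseRelease", date = as.Date(date), assertions = assertions)
}

#' An ordered series of database releases
#'
#' @slot releases list of \linkS4class{DatabaseRelease}, strictly increasing
#'   in date.
#' @export
setClass("ReleaseSeries", representation(releases = "list"))

setValidity("ReleaseSeries", function(object) {
    rel <- object@releases
    if (!length(rel)) return("a release series must contain >= 1 release")
    if (!all(vapply(rel, is, logical(1), class2 = "DatabaseRelease")))
        return("all elements must be DatabaseRelease objects")
    d <- as.Date(vapply(rel, function(r) as.character(r@date), character(1)))
    if (is.unsorted(d, strictly = TRUE))
        return("release dates must be strictly increasing")
    TRUE
})

#' Construct a ReleaseSeries (releases are sorted by date)
#' @param releases list of \linkS4class{DatabaseRelease} objects.
#' @return A \linkS4class{ReleaseSeries}.
#' @export
ReleaseSeries <- function(releases) {
    d <- as.Date(vapply(releases, function(r) as.character(r@date), character(1)))
    new("ReleaseSeries", releases = releases[order(d)])
}

## ---------------------------------------------------------------------------
## BiasResult
## ---------------------------------------------------------------------------

#' Pooled within-population correlation result
#'
#' @slot pooledR pooled correlation estimate in [-1, 1].
#' @slot z pooled Fisher-z value.
#' @slot pValue two-sided p-value from the normal statistic
#'   \code{z * sqrt(sum(n - 3))}.
#' @slot nEffective sum of the (n - 3) pooling weights.
#' @slot perPopulation data.frame of the usable strata: \code{population},
#'   \code{n}, \code{r}.
#' @slot excludedPopulations data.frame of strata excluded from pooling:
#'   \code{population}, \code{n}, \code{reason}.
#' @export
setClass("BiasResult",
    representation(pooledR = "numeric", z = "numeric", pValue = "numeric",
                   nEffective = "numeric", perPopulation = "data.frame",
                   excludedPopulations = "data.frame"))

## ---------------------------------------------------------------------------
## DriverReport
## ---------------------------------------------------------------------------

#' Driver attribution for a between-release correlation change
#'
#' @slot dateA,dateB the two release dates compared.
#' @slot rA,rB pooled correlations under release A and B.
#' @slot drivers data.frame ranked by absolute marginal effect:
#'   \code{variant_id}, \code{change_type} (added/removed/reclassified),
#'   \code{marginal_delta_r}, \code{selected}.
#' @slot selectedSetSize number of top-ranked variants whose joint reversion
#'   moves the correlation at least \code{coverage} of the way back to rA.
#' @slot coverage requested coverage fraction.
#' @slot achievedCoverage coverage actually achieved by the selected set.
#' @export
setClass("DriverReport",
    representation(dateA = "Date", dateB = "Date", rA = "numeric",
                   rB = "numeric", drivers = "data.frame",
                   selectedSetSize = "integer", coverage = "numeric",
                   achievedCoverage = "numeric"))

## ---------------------------------------------------------------------------
## FilterConfig
## ---------------------------------------------------------------------------

#' Configuration of the variant classification filters
#'
#' Defaults mirror the standard prioritization pipeline: pathogenic-annotated
#' variants (PAVs) keep a 5\% MAF gate, non-annotated variants (NAVs) a 2\%
#' gate, deleteriousness requires at least 2 of the 11 in-silico predictors,
#' and nonsense/splice variants are deleterious irrespective of predictors.
#'
#' @slot pavMafCutoff MAF cutoff for the PAV branch (default 0.05).
#' @slot navMafCutoff MAF cutoff for the NAV branch (default 0.02).
#' @slot minDeleteriousCalls predictor votes needed for deleteriousness
#'   (default 2).
#' @slot applyMafFilter,applyDeleteriousFilter,applyStopSpliceException
#'   switches for the three filters.
#' @slot pathogenicDatabases databases whose pathogenic assertion defines a
#'   PAV (subset of OMIM, HGMD, ClinVar).
#' @export
setClass("FilterConfig",
    representation(pavMafCutoff = "numeric", navMafCutoff = "numeric",
                   minDeleteriousCalls = "integer", applyMafFilter = "logical",
                   applyDeleteriousFilter = "logical",
                   applyStopSpliceException = "logical",
                   pathogenicDatabases = "character"))

setValidity("FilterConfig", function(object) {
    msgs <- character()
    if (object@pavMafCutoff <= 0 || object@pavMafCutoff > 1 ||
        object@navMafCutoff <= 0 || object@navMafCutoff > 1)
        msgs <- c(msgs, "MAF cutoffs must lie in (0, 1]")
    if (object@minDeleteriousCalls < 0L || object@minDeleteriousCalls > 11L)
        msgs <- c(msgs, "minDeleteriousCalls must lie in [0, 11]")
    if (!length(object@pathogenicDatabases) ||
        !all(object@pathogenicDatabases %in% CORE_DATABASES))
        msgs <- c(msgs, "pathogenicDatabases must be a non-empty subset of OMIM/HGMD/ClinVar")
    if (length(msgs)) msgs else TRUE
})

#' Construct a FilterConfig
#' @param pavMafCutoff,navMafCutoff MAF cutoffs for the PAV / NAV branches.
#' @param minDeleteriousCalls predictor votes needed for deleteriousness.
#' @param applyMafFilter,applyDeleteriousFilter,applyStopSpliceException
#'   filter switches.
#' @param pathogenicDatabases databases defining pathogenic annotation.
#' @return A \linkS4class{FilterConfig}.
#' @export
FilterConfig <- function(pavMafCutoff = 0.05, navMafCutoff = 0.02,
                         minDeleteriousCalls = 2L, applyMafFilter = TRUE,
                         applyDeleteriousFilter = TRUE,
                         applyStopSpliceException = TRUE,
                         pathogenicDatabases = CORE_DATABASES) {
    new("FilterConfig", pavMafCutoff = pavMafCutoff,
        navMafCutoff = navMafCutoff,
        minDeleteriousCalls = as.integer(minDeleteriousCalls),
        applyMafFilter = applyMafFilter,
        applyDeleteriousFilter = applyDeleteriousFilter,
        applyStopSpliceException = applyStopSpliceException,
        pathogenicDatabases = pathogenicDatabases)
}

## ---------------------------------------------------------------------------
## CostConfig
## ---------------------------------------------------------------------------

#' Configuration of the confirmation-cost model
#'
#' @slot costPerConfirmation unit cost of orthogonal (Sanger) confirmation,
#'   in currency units (default 500).
#' @slot panelFraction fraction of the genome covered by the candidate panel
#'   (default 0.01, roughly 200 genes); ignored when an explicit gene list is
#'   supplied to the counting functions.
#' @slot prioritizedClasses classes whose carried variants require follow-up
#'   (default: both PAV classes plus deleterious NAVs).
#' @export
setClass("CostConfig",
    representation(costPerConfirmation = "numeric", panelFraction = "numeric",
                   prioritizedClasses = "character"))

setValidity("CostConfig", function(object) {
    msgs <- character()
    if (object@costPerConfirmation < 0)
        msgs <- c(msgs, "costPerConfirmation must be >= 0")
    if (object@panelFraction <= 0 || object@panelFraction > 1)
        msgs <- c(msgs, "panelFraction must lie in (0, 1]")
    if (!all(object@prioritizedClasses %in% COUNTED_CLASSES))
        msgs <- c(msgs, "prioritizedClasses must be a subset of the four classes")
    if (length(msgs)) msgs else TRUE
})

#' Construct a CostConfig
#' @param costPerConfirmation per-variant confirmation cost.
#' @param panelFraction fraction of the genome in the candidate panel.
#' @param prioritizedClasses classes requiring follow-up confirmation.
#' @return A \linkS4class{CostConfig}.
#' @export
CostConfig <- function(costPerConfirmation = 500, panelFraction = 0.01,
                       prioritizedClasses = c("DEL_PAV", "NONDEL_PAV",
                                              "DEL_NAV")) {
    new("CostConfig", costPerConfirmation = costPerConfirmation,
        panelFraction = panelFraction, prioritizedClasses = prioritizedClasses)
}
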