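## Generics and accessors.

#' Individuals table of a cohort
#' @param x an \linkS4class{AdmixedCohort}.
#' @return data.frame with individual_id, population, africanAncestry.
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname individuals
#' @export
setMethod("individuals", "AdmixedCohort", function(x) x@individuals)

#' Genotype matrix (alternate-allele counts) of a cohort
#' @param x an \linkS4class{AdmixedCohort}.
#' @return integer matrix, individuals x variants, NA = missing call.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname genotypes
#' @export
setMethod("genotypes", "AdmixedCohort", function(x) x@genotypes)

#' Population labels of a cohort
#' @param x an \linkS4class{AdmixedCohort}.
#' @return character vector named by individual id.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname populations
#' @export
setMethod("populations", "AdmixedCohort", function(x)
    structure(x@individuals$population, names = x@individuals$individual_id))

#' African-ancestry proportions of a cohort
#' @param x an \linkS4class{AdmixedCohort}.
#' @return numeric vector in [0, 1] named by individual id.
#' @export
setGeneric("africanAncestry", function(x) standardGeneric("africanAncestry"))

#' @rdname africanAncestry
#' @export
setMethod("africanAncestry", "AdmixedCohort", function(x)
    structure(x@individuals$africanAncestry,
              names = x@individuals$individual_id))

#' Variant table of an annotation set
#' @param x a \linkS4class{VariantAnnotations}.
#' @return data.frame of variant-level fields.
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname variants
#' @export
setMethod("variants", "VariantAnnotations", function(x) x@variants)

#' Variant identifiers
#' @param x a \linkS4class{VariantAnnotations} or \linkS4class{AdmixedCohort}.
#' @return character vector of canonical "chrom:pos:ref:alt" ids.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname variantIds
#' @export
setMethod("variantIds", "VariantAnnotations", function(x) x@variants$variant_id)

#' @rdname variantIds
#' @export
setMethod("variantIds", "AdmixedCohort", function(x) colnames(x@genotypes))

#' Population-panel allele frequencies
#' @param x a \linkS4class{VariantAnnotations}.
#' @return numeric matrix, variants x panels.
#' @export
setGeneric("popFreqs", function(x) standardGeneric("popFreqs"))

#' @rdname popFreqs
#' @export
setMethod("popFreqs", "VariantAnnotations", function(x) x@popFreqs)

#' In-silico predictor calls
#' @param x a \linkS4class{VariantAnnotations}.
#' @return character matrix, variants x 11 predictors.
#' @export
setGeneric("predictorCalls", function(x) standardGeneric("predictorCalls"))

#' @rdname predictorCalls
#' @export
setMethod("predictorCalls", "VariantAnnotations", function(x) x@predictorCalls)

#' Predictor category labels
#' @param x a \linkS4class{VariantAnnotations}.
#' @return named character vector (database_trained / agnostic).
#' @export
setGeneric("predictorCategories",
           function(x) standardGeneric("predictorCategories"))

#' @rdname predictorCategories
#' @export
setMethod("predictorCategories", "VariantAnnotations",
          function(x) x@predictorCategories)

#' Clinical-database assertions
#' @param x a \linkS4class{VariantAnnotations} or
#'   \linkS4class{DatabaseRelease}.
#' @return for annotations, a character matrix variants x databases; for a
#'   release, the named assertion vector.
#' @export
setGeneric("assertions", function(x) standardGeneric("assertions"))

#' @rdname assertions
#' @export
setMethod("assertions", "VariantAnnotations", function(x) x@assertions)

#' @rdname assertions
#' @export
setMethod("assertions", "DatabaseRelease", function(x) x@assertions)

#' Release date(s)
#' @param x a \linkS4class{DatabaseRelease} or \linkS4class{ReleaseSeries}.
#' @return Date vector.
#' @export
setGeneric("releaseDates", function(x) standardGeneric("releaseDates"))

#' @rdname releaseDates
#' @export
setMethod("releaseDates", "DatabaseRelease", function(x) x@date)

#' @rdname releaseDates
#' @export
setMethod("releaseDates", "ReleaseSeries", function(x)
    as.Date(vapply(x@releases, function(r) as.character(r@date), character(1))))

#' Releases of a series
#' @param x a \linkS4class{ReleaseSeries}.
#' @return list of \linkS4class{DatabaseRelease}.
#' @export
setGeneric("releases", function(x) standardGeneric("releases"))

#' @rdname releases
#' @export
setMethod("releases", "ReleaseSeries", function(x) x@releases)

#' Pooled correlation estimate
#' @param x a \linkS4class{BiasResult}.
#' @return numeric pooled correlation.
#' @export
setGeneric("pooledR", function(x) standardGeneric("pooledR"))

#' @rdname pooledR
#' @export
setMethod("pooledR", "BiasResult", function(x) x@pooledR)

#' P-value of a result
#' @param x a \linkS4class{BiasResult}.
#' @return numeric p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "BiasResult", function(x) x@pValue)

#' Per-population correlation components
#' @param x a \linkS4class{BiasResult}.
#' @return data.frame with population, n, r for the usable strata.
#' @export
setGeneric("perPopulation", function(x) standardGeneric("perPopulation"))

#' @rdname perPopulation
#' @export
setMethod("perPopulation", "BiasResult", function(x) x@perPopulation)

#' Ranked driver table of a DriverReport
#' @param x a \linkS4class{DriverReport}.
#' @return data.frame of candidates ranked by absolute marginal effect.
#' @export
setGeneric("drivers", function(x) standardGeneric("drivers"))

#' @rdname drivers
#' @export
setMethod("drivers", "DriverReport", function(x) x@drivers)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "AdmixedCohort", function(object) {
    ind <- object@individuals
    cat("AdmixedCohort:", nrow(ind), "individuals,",
        ncol(object@genotypes), "variants,",
        length(unique(ind$population)), "populations\n")
    cat("  African ancestry range:",
        sprintf("%.3f-%.3f", min(ind$africanAncestry),
                max(ind$africanAncestry)), "\n")
})

setMethod("show", "VariantAnnotations", function(object) {
    cat("VariantAnnotations:", nrow(object@variants), "variants,",
        ncol(object@popFreqs), "population panels,",
        ncol(object@predictorCalls), "predictors,",
        ncol(object@assertions), "databases\n")
    np <- colSums(object@assertions == "pathogenic")
    cat("  pathogenic assertions:",
        paste(sprintf("%s=%d", names(np), np), collapse = ", "), "\n")
})

setMethod("show", "DatabaseRelease", function(object) {
    cat("DatabaseRelease", as.character(object@date), "-",
        sum(object@assertions == "pathogenic"), "pathogenic /",
        length(object@assertions), "total assertions\n")
})

setMethod("show", "ReleaseSeries", function(object) {
    d <- releaseDates(object)
    cat("ReleaseSeries:", length(d), "releases,",
        as.character(min(d)), "to", as.character(max(d)), "\n")
})

setMethod("show", "BiasResult", function(object) {
    cat(sprintf("BiasResult: pooled r = %.4f (p = %.3g), %d usable strata, n_eff = %g\n",
                object@pooledR, object@pValue, nrow(object@perPopulation),
                object@nEffective))
    if (nrow(object@excludedPopulations))
        cat("  excluded strata:", nrow(object@excludedPopulations), "\n")
})

setMethod("show", "DriverReport", function(object) {
    cat(sprintf("DriverReport %s -> %s: r %.3f -> %.3f\n",
                as.character(object@dateA), as.character(object@dateB),
                object@rA, object@rB))
    cat(sprintf("  %d candidates, selected set of %d covers %.1f%% of the change (target %.0f%%)\n",
                nrow(object@drivers), object@selectedSetSize,
                100 * object@achievedCoverage, 100 * object@coverage))
})
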