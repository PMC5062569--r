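## Variant classification: PAV/NAV x deleterious/non-deleterious.
##
## Pipeline per variant:
##   1. pathogenic annotation (exact variant match in a configured clinical
##      database, restricted to protein-coding genes) splits PAV vs NAV;
##   2. a MAF gate (5% for PAVs, 2% for NAVs, exceeded in ANY population
##      panel) drops common variants to EXCLUDED(common_maf);
##   3. NAVs must be protein-altering;
##   4. the deleterious filter (>= 2 of 11 predictor votes, nonsense/splice
##      auto-qualify) splits each branch into DEL_* / NONDEL_*.

#' Is a variant pathogenic-annotated?
#'
#' TRUE when any configured clinical database asserts this exact variant
#' pathogenic and the variant lies in a protein-coding gene.
#'
#' @param ann a \linkS4class{VariantAnnotations}.
#' @param cfg a \linkS4class{FilterConfig}.
#' @return logical vector, one entry per variant.
#' @export
isPathogenicAnnotated <- function(ann, cfg = FilterConfig()) {
    a <- assertions(ann)[, cfg@pathogenicDatabases, drop = FALSE]
    rowSums(a == "pathogenic") > 0L & variants(ann)$inProteinCodingGene
}

#' Is a variant deleterious?
#'
#' TRUE when at least \code{minDeleteriousCalls} of the 11 predictors call
#' the variant deleterious, or (with the exception enabled) when the
#' consequence is nonsense or splice. A missing predictor call counts as a
#' non-deleterious vote.
#'
#' @inheritParams isPathogenicAnnotated
#' @return logical vector, one entry per variant.
#' @export
isDeleterious <- function(ann, cfg = FilterConfig()) {
    nDel <- rowSums(predictorCalls(ann) == "deleterious")
    del <- nDel >= cfg@minDeleteriousCalls
    if (cfg@applyStopSpliceException)
        del <- del | variants(ann)$consequence %in% c("nonsense", "splice")
    del
}

#' Does a variant pass the branch-specific MAF gate?
#'
#' The minor-allele frequency min(f, 1 - f) must not exceed the applicable
#' cutoff in any population panel. Variants unobserved in every panel are
#' treated as rare and pass.
#'
#' @inheritParams isPathogenicAnnotated
#' @param isPav logical vector (or scalar): use the PAV cutoff (5\%) where
#'   TRUE, the NAV cutoff (2\%) where FALSE.
#' @return logical vector, one entry per variant.
#' @export
passesMaf <- function(ann, isPav, cfg = FilterConfig()) {
    if (!cfg@applyMafFilter) return(rep(TRUE, nrow(variants(ann))))
    f <- popFreqs(ann)
    maxMaf <- .rowMaxNA(pmin(f, 1 - f))
    maxMaf[is.na(maxMaf)] <- 0
    cutoff <- ifelse(rep_len(isPav, length(maxMaf)),
                     cfg@pavMafCutoff, cfg@navMafCutoff)
    maxMaf <= cutoff
}

#' Classify every variant into a clinical-priority class
#'
#' Assigns each variant exactly one of DEL_PAV, NONDEL_PAV, DEL_NAV,
#' NONDEL_NAV or EXCLUDED (with an exclusion reason). With
#' \code{applyDeleteriousFilter = FALSE} the PAV/NAV branches are not split;
#' surviving variants are reported under the DEL_* labels and the result
#' carries \code{attr(, "merged") = TRUE}.
#'
#' @inheritParams isPathogenicAnnotated
#' @return data.frame with \code{variant_id}, \code{class},
#'   \code{exclusion_reason}; attribute \code{merged} records whether the
#'   deleterious split was applied.
#' @export
classifyVariants <- function(ann, cfg = FilterConfig()) {
    v <- variants(ann)
    n <- nrow(v)
    pav <- isPathogenicAnnotated(ann, cfg)
    del <- isDeleterious(ann, cfg)
    mafPav <- passesMaf(ann, TRUE, cfg)
    mafNav <- passesMaf(ann, FALSE, cfg)

    class <- rep("EXCLUDED", n)
    reason <- rep("none", n)

    ## PAV branch: pathogenic-annotated entries failing the MAF gate are
    ## treated as misidentified common entries and removed outright.
    idx <- pav & !mafPav
    reason[idx] <- "common_maf"
    idx <- pav & mafPav
    class[idx] <- ifelse(!cfg@applyDeleteriousFilter | del[idx],
                         "DEL_PAV", "NONDEL_PAV")

    ## NAV branch: protein-altering only, then the 2% gate.
    nav <- !pav
    idx <- nav & !v$proteinAltering
    reason[idx] <- ifelse(v$inProteinCodingGene[idx],
                          "non_protein_altering", "non_coding")
    idx <- nav & v$proteinAltering & !mafNav
    reason[idx] <- "common_maf"
    idx <- nav & v$proteinAltering & mafNav
    class[idx] <- ifelse(!cfg@applyDeleteriousFilter | del[idx],
                         "DEL_NAV", "NONDEL_NAV")

    reason[class != "EXCLUDED"] <- "none"
    out <- data.frame(variant_id = v$variant_id, class = class,
                      exclusion_reason = reason, stringsAsFactors = FALSE)
    attr(out, "merged") <- !cfg@applyDeleteriousFilter
    out
}

#' Per-individual variant counts by class
#'
#' Carrier mode counts each surviving variant carried on at least one allele;
#' allele_dosage mode sums allele counts. Missing genotypes never contribute.
#'
#' @param cohort an \linkS4class{AdmixedCohort}.
#' @param classified output of \code{\link{classifyVariants}}.
#' @param mode "carrier" (default) or "allele_dosage".
#' @return numeric matrix, individuals x the four classes.
#' @export
perIndividualCounts <- function(cohort, classified,
                                mode = c("carrier", "allele_dosage")) {
    mode <- match.arg(mode)
    g <- genotypes(cohort)
    missing <- is.na(g)
    if (any(rowSums(!missing) == 0L))
        warning("individual(s) with all-missing genotypes: counts are 0")
    m <- if (mode == "carrier") (g >= 1L) * 1 else g * 1
    m[missing] <- 0
    cls <- structure(classified$class, names = classified$variant_id)
    cls <- cls[colnames(g)]
    out <- vapply(COUNTED_CLASSES, function(k) {
        j <- which(!is.na(cls) & cls == k)
        if (!length(j)) numeric(nrow(g)) else rowSums(m[, j, drop = FALSE])
    }, numeric(nrow(g)))
    rownames(out) <- rownames(g)
    out
}
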