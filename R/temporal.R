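## Database-version drift: correlation trajectory, sign-flip detection and
## driver-variant attribution.

#' Override the ClinVar assertion slot with a release snapshot
#'
#' Variants present in the release get its assertion; all others become
#' absent. Release entries for variants outside the annotation set are
#' ignored for cohort counting (they still count toward database size) and
#' logged.
#'
#' @param ann a \linkS4class{VariantAnnotations}.
#' @param release a \linkS4class{DatabaseRelease}.
#' @return the modified \linkS4class{VariantAnnotations}.
#' @export
overrideClinVar <- function(ann, release) {
    a <- assertions(ann)
    ids <- variantIds(ann)
    rel <- assertions(release)
    unknown <- sum(!names(rel) %in% ids)
    if (unknown > 0L)
        .log("info", unknown, " release variant(s) absent from the ",
             "annotation set: counted in db size only")
    newCol <- rep("absent", length(ids))
    m <- match(ids, names(rel))
    hit <- !is.na(m)
    newCol[hit] <- unname(rel[m[hit]])
    a[, "ClinVar"] <- newCol
    initialize(ann, assertions = a)
}

## per-individual pathogenic carrier counts under one release snapshot.
## unfiltered: a variant counts when carried and ClinVar-asserted pathogenic,
## with no MAF/consequence/deleteriousness gates. filtered: the full
## classification pipeline is re-run (ClinVar as the pathogenic database) and
## surviving deleterious PAVs are counted.
.releaseQualifies <- function(ann, cfg, filtered) {
    if (!filtered) return(assertions(ann)[, "ClinVar"] == "pathogenic")
    cfgCV <- initialize(cfg, pathogenicDatabases = "ClinVar")
    cl <- classifyVariants(ann, cfgCV)
    cl$class == "DEL_PAV"
}

.carrierMatrix <- function(cohort) {
    g <- genotypes(cohort)
    m <- (g >= 1L) * 1
    m[is.na(g)] <- 0
    m
}

#' Ancestry-correlation trajectory across database releases
#'
#' For each release the ClinVar slot of the annotation set is overridden,
#' per-individual pathogenic carrier counts are recomputed (see
#' \code{filtered}), and the pooled within-population correlation with
#' African ancestry is evaluated.
#'
#' @param series a \linkS4class{ReleaseSeries} (>= 2 releases).
#' @param cohort an \linkS4class{AdmixedCohort}.
#' @param ann a \linkS4class{VariantAnnotations}.
#' @param cfg a \linkS4class{FilterConfig} (used in filtered mode).
#' @param filtered apply the full classification gates (TRUE) or count any
#'   carried ClinVar-pathogenic variant (FALSE).
#' @return data.frame with one row per release: \code{date},
#'   \code{n_pathogenic_in_db}, \code{pooled_r}, \code{p_value},
#'   \code{degenerate} (TRUE when no usable strata), \code{filtered}.
#' @export
correlationTrajectory <- function(series, cohort, ann, cfg = FilterConfig(),
                                  filtered = FALSE) {
    rel <- releases(series)
    if (length(rel) < 2L) stop("a trajectory needs >= 2 releases")
    carrier <- .carrierMatrix(cohort)
    ids <- colnames(carrier)
    rows <- lapply(rel, function(r) {
        annR <- overrideClinVar(ann, r)
        qual <- .releaseQualifies(annR, cfg, filtered)
        qualIds <- intersect(variantIds(ann)[qual], ids)
        counts <- if (length(qualIds))
            rowSums(carrier[, qualIds, drop = FALSE]) else
            numeric(nrow(carrier))
        res <- tryCatch(pooledAncestryCorrelation(cohort, counts),
                        error = function(e) NULL)
        data.frame(date = r@date,
                   n_pathogenic_in_db = sum(assertions(r) == "pathogenic"),
                   pooled_r = if (is.null(res)) NA_real_ else pooledR(res),
                   p_value = if (is.null(res)) NA_real_ else pValue(res),
                   degenerate = is.null(res))
    })
    out <- do.call(rbind, rows)
    out$filtered <- filtered
    out
}

#' Detect significant sign flips in a correlation trajectory
#'
#' Flags consecutive release pairs where both correlations are significant at
#' \code{alpha} and their signs differ.
#'
#' @param traj output of \code{\link{correlationTrajectory}}.
#' @param alpha significance level (default 0.05).
#' @return data.frame with \code{date_A}, \code{date_B}, \code{r_A},
#'   \code{r_B} (zero rows when no flip).
#' @export
detectFlips <- function(traj, alpha = 0.05) {
    n <- nrow(traj)
    out <- data.frame(date_A = as.Date(character()),
                      date_B = as.Date(character()),
                      r_A = numeric(), r_B = numeric())
    if (n < 2L) return(out)
    for (i in seq_len(n - 1L)) {
        rA <- traj$pooled_r[i]; rB <- traj$pooled_r[i + 1L]
        pA <- traj$p_value[i]; pB <- traj$p_value[i + 1L]
        if (anyNA(c(rA, rB, pA, pB))) next
        if (pA < alpha && pB < alpha && sign(rA) != sign(rB) &&
            rA != 0 && rB != 0)
            out[nrow(out) + 1L, ] <- list(traj$date[i], traj$date[i + 1L],
                                          rA, rB)
    }
    out
}

#' Attribute a between-release correlation change to driver variants
#'
#' Candidates are the variants whose assertion state differs between the two
#' releases. Each candidate's marginal effect is the pooled-correlation change
#' when that single difference is reverted on the B side; candidates are
#' ranked by absolute marginal effect and selected greedily until reverting
#' the selected set moves the correlation at least \code{coverage} of the way
#' from r(B) back to r(A).
#'
#' @param releaseA,releaseB two \linkS4class{DatabaseRelease} objects, A
#'   preceding B.
#' @param cohort an \linkS4class{AdmixedCohort}.
#' @param ann a \linkS4class{VariantAnnotations}.
#' @param cfg a \linkS4class{FilterConfig}.
#' @param coverage fraction of the correlation change the selected set must
#'   explain (default 0.9).
#' @param filtered count under the full classification gates instead of the
#'   plain ClinVar-pathogenic rule.
#' @return A \linkS4class{DriverReport}.
#' @export
attributeDrivers <- function(releaseA, releaseB, cohort, ann,
                             cfg = FilterConfig(), coverage = 0.9,
                             filtered = FALSE) {
    if (releaseA@date >= releaseB@date)
        stop("release A must precede release B")
    aA <- assertions(releaseA); aB <- assertions(releaseB)
    ids <- variantIds(ann)
    stateA <- structure(rep("absent", length(ids)), names = ids)
    mA <- match(ids, names(aA)); hA <- !is.na(mA)
    stateA[hA] <- unname(aA[mA[hA]])
    stateB <- structure(rep("absent", length(ids)), names = ids)
    mB <- match(ids, names(aB)); hB <- !is.na(mB)
    stateB[hB] <- unname(aB[mB[hB]])

    carrier <- .carrierMatrix(cohort)
    qualA <- .releaseQualifies(overrideClinVar(ann, releaseA), cfg, filtered)
    qualB <- .releaseQualifies(overrideClinVar(ann, releaseB), cfg, filtered)
    names(qualA) <- names(qualB) <- ids
    common <- intersect(ids, colnames(carrier))
    countsFor <- function(qual) {
        qi <- intersect(names(qual)[qual], common)
        if (length(qi)) rowSums(carrier[, qi, drop = FALSE]) else
            numeric(nrow(carrier))
    }
    countsA <- countsFor(qualA)
    countsB <- countsFor(qualB)
    rA <- pooledR(pooledAncestryCorrelation(cohort, countsA))
    rB <- pooledR(pooledAncestryCorrelation(cohort, countsB))
    deltaR <- rB - rA

    cand <- ids[stateA != stateB]
    if (!length(cand)) {
        if (abs(deltaR) > 1e-12)
            stop("no assertion differences between releases but the ",
                 "correlation changed: inconsistent inputs")
        return(new("DriverReport", dateA = releaseA@date,
                   dateB = releaseB@date, rA = rA, rB = rB,
                   drivers = data.frame(variant_id = character(),
                                        change_type = character(),
                                        marginal_delta_r = numeric(),
                                        selected = logical()),
                   selectedSetSize = 0L, coverage = coverage,
                   achievedCoverage = 1))
    }
    changeType <- ifelse(stateA[cand] == "absent", "added",
                  ifelse(stateB[cand] == "absent", "removed", "reclassified"))

    ## reverting candidate v changes the count vector by
    ## carrier_v * (qualA_v - qualB_v); candidates the cohort does not carry
    ## (or whose qualification is unchanged) have exactly zero effect.
    shift <- as.numeric(qualA[cand]) - as.numeric(qualB[cand])
    inCohort <- cand %in% common
    Y <- matrix(countsB, nrow(carrier), length(cand))
    act <- which(inCohort & shift != 0)
    if (length(act))
        Y[, act] <- Y[, act] + carrier[, cand[act], drop = FALSE] *
            rep(shift[act], each = nrow(carrier))
    rRev <- .pooledRMatrix(cohort, Y)
    marginal <- rRev - rB
    marginal[is.na(marginal)] <- 0

    ord <- order(abs(marginal), decreasing = TRUE)
    drv <- data.frame(variant_id = cand[ord],
                      change_type = unname(changeType[ord]),
                      marginal_delta_r = unname(marginal[ord]),
                      stringsAsFactors = FALSE)

    ## greedy selection in rank order until the joint reversion covers the
    ## requested fraction of the change
    target <- coverage
    counts <- countsB
    achieved <- if (abs(deltaR) < 1e-12) 1 else 0
    selSize <- 0L
    if (abs(deltaR) >= 1e-12) {
        for (kk in seq_len(nrow(drv))) {
            v <- drv$variant_id[kk]
            if (v %in% common && qualA[v] != qualB[v])
                counts <- counts + carrier[, v] *
                    (as.numeric(qualA[v]) - as.numeric(qualB[v]))
            rCum <- pooledR(pooledAncestryCorrelation(cohort, counts))
            achieved <- (rCum - rB) / (rA - rB)
            selSize <- kk
            if (achieved >= target) break
        }
    }
    drv$selected <- seq_len(nrow(drv)) <= selSize
    new("DriverReport", dateA = releaseA@date, dateB = releaseB@date,
        rA = rA, rB = rB, drivers = drv, selectedSetSize = selSize,
        coverage = coverage, achievedCoverage = achieved)
}
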