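## Population-structure-aware correlation machinery and related tests.
##
## Cohorts are sampled as population blocks, so a plain Pearson correlation
## across all individuals would confound between-population differences with
## the within-population signal. The pooled estimator computes Pearson r
## within each population, maps each to Fisher z = atanh(r), combines them as
## a fixed-effect meta-analysis with the standard (n - 3) inverse-variance
## weights, and maps back: r_pooled = tanh(sum w z / sum w). The two-sided
## p-value comes from the normal statistic z_pooled * sqrt(sum w).

.usableStrata <- function(theta, y, pop) {
    pops <- split(seq_along(pop), pop)
    usable <- list(); excluded <- list()
    for (p in names(pops)) {
        i <- pops[[p]]
        n <- length(i)
        if (n < 4L) {
            excluded[[p]] <- data.frame(population = p, n = n,
                                        reason = "n<4")
        } else if (stats::sd(theta[i]) == 0 || stats::sd(y[i]) == 0) {
            excluded[[p]] <- data.frame(population = p, n = n,
                                        reason = "zero variance")
        } else {
            usable[[p]] <- data.frame(population = p, n = n,
                                      r = stats::cor(theta[i], y[i]))
        }
    }
    list(usable = do.call(rbind, usable), excluded = do.call(rbind, excluded))
}

#' Pooled within-population correlation with African ancestry
#'
#' Pearson correlations between the African-ancestry proportion and a
#' per-individual count are estimated within each population and combined by
#' sample-size-weighted Fisher-z pooling. Populations with fewer than 4
#' individuals or zero variance in either variable are excluded from pooling
#' and listed in the result.
#'
#' @param cohort an \linkS4class{AdmixedCohort}.
#' @param counts numeric vector of per-individual values, either in cohort
#'   order or named by individual id.
#' @return A \linkS4class{BiasResult}.
#' @export
pooledAncestryCorrelation <- function(cohort, counts) {
    ind <- individuals(cohort)
    if (!is.null(names(counts))) {
        if (!all(ind$individual_id %in% names(counts)))
            stop("named counts must cover every individual in the cohort")
        counts <- counts[ind$individual_id]
    }
    if (length(counts) != nrow(ind))
        stop("counts must have one value per individual")
    st <- .usableStrata(ind$africanAncestry, as.numeric(counts),
                        ind$population)
    if (is.null(st$usable)) stop("no usable strata")
    u <- st$usable
    w <- u$n - 3
    z <- atanh(pmax(pmin(u$r, 1), -1))
    pooledZ <- sum(w * z) / sum(w)
    stat <- pooledZ * sqrt(sum(w))
    p <- max(2 * stats::pnorm(-abs(stat)), .Machine$double.xmin)
    excl <- st$excluded
    if (is.null(excl))
        excl <- data.frame(population = character(), n = integer(),
                           reason = character())
    new("BiasResult", pooledR = tanh(pooledZ), z = pooledZ, pValue = p,
        nEffective = sum(w), perPopulation = u, excludedPopulations = excl)
}

## Pooled r for many count vectors at once (columns of Y). Must agree with
## pooledAncestryCorrelation column by column; exclusions mirror
## .usableStrata: pops with n < 4 or sd(theta) = 0 are dropped everywhere,
## zero count variance drops a population for that column only.
.pooledRMatrix <- function(cohort, Y) {
    ind <- individuals(cohort)
    theta <- ind$africanAncestry
    m <- ncol(Y)
    num <- numeric(m); den <- numeric(m)
    for (p in unique(ind$population)) {
        i <- which(ind$population == p)
        n <- length(i)
        if (n < 4L) next
        x <- theta[i]
        sx <- stats::sd(x)
        if (sx == 0) next
        Yp <- Y[i, , drop = FALSE]
        xc <- x - mean(x)
        sxy <- as.numeric(crossprod(xc, Yp)) / (n - 1)
        mu <- colMeans(Yp)
        sy2 <- (colSums(Yp * Yp) - n * mu * mu) / (n - 1)
        ok <- sy2 > 0
        r <- rep(NA_real_, m)
        r[ok] <- sxy[ok] / (sx * sqrt(sy2[ok]))
        z <- atanh(pmax(pmin(r, 1), -1))
        w <- n - 3
        num[ok] <- num[ok] + w * z[ok]
        den[ok] <- den[ok] + w
    }
    out <- rep(NA_real_, m)
    out[den > 0] <- tanh(num[den > 0] / den[den > 0])
    out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of BH step-up adjusted q-values.
#' @export
bhFDR <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] with no missing values")
    stats::p.adjust(p, method = "BH")
}

## Pearson chi-square of independence on a contingency table, with an exact
## fallback when any expected cell drops below 1.
.chisqIndependence <- function(tab) {
    tab <- as.matrix(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    exact <- any(expected < 1)
    if (exact) {
        warning("expected cell count < 1: reporting Fisher's exact p-value")
        list(chi2 = NA_real_, df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
             p.value = stats::fisher.test(tab)$p.value, table = tab,
             expected = expected, exact = TRUE)
    } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
             p.value = ct$p.value, table = tab, expected = expected,
             exact = FALSE)
    }
}

#' Are database-trained and agnostic predictors used differently for PAVs
#' and NAVs?
#'
#' Builds a contingency table of deleterious predictor calls over the
#' classified deleterious PAV and deleterious NAV variants (each deleterious
#' call by each predictor on each variant contributes one count), with rows
#' given by predictor category (or by predictor when \code{perPredictor}) and
#' columns PAV / NAV, and tests independence with Pearson's chi-square.
#'
#' @param classified output of \code{\link{classifyVariants}}.
#' @param ann the matching \linkS4class{VariantAnnotations}.
#' @param perPredictor use one row per predictor instead of the two
#'   categories.
#' @return list with \code{chi2}, \code{df}, \code{p.value}, \code{table},
#'   \code{expected} and \code{exact} (TRUE when the exact fallback fired).
#' @export
predictorIndependenceTest <- function(classified, ann, perPredictor = FALSE) {
    calls <- predictorCalls(ann)
    cls <- structure(classified$class, names = classified$variant_id)
    cls <- cls[variantIds(ann)]
    keep <- cls %in% c("DEL_PAV", "DEL_NAV")
    if (!any(cls == "DEL_PAV") || !any(cls == "DEL_NAV"))
        stop("both DEL_PAV and DEL_NAV must be non-empty")
    del <- (calls[keep, , drop = FALSE] == "deleterious") * 1
    grp <- ifelse(cls[keep] == "DEL_PAV", "PAV", "NAV")
    perPred <- rbind(PAV = colSums(del[grp == "PAV", , drop = FALSE]),
                     NAV = colSums(del[grp == "NAV", , drop = FALSE]))
    if (perPredictor) {
        tab <- t(perPred)[, c("PAV", "NAV"), drop = FALSE]
    } else {
        cat_ <- predictorCategories(ann)[colnames(calls)]
        tab <- rbind(
            database_trained = rowSums(perPred[, cat_ == "database_trained",
                                               drop = FALSE]),
            agnostic = rowSums(perPred[, cat_ == "agnostic", drop = FALSE]))
        tab <- tab[, c("PAV", "NAV"), drop = FALSE]
    }
    .chisqIndependence(tab)
}

#' Gene-level scan for ancestry-correlated pathogenic-annotated burden
#'
#' For every gene harbouring at least one cohort-polymorphic PAV, the
#' per-individual count of carried PAVs in that gene is correlated with
#' African ancestry via \code{\link{pooledAncestryCorrelation}}; q-values are
#' BH-adjusted across the tested genes only. Genes failing the preconditions
#' (no usable strata, zero count variance) are reported as untested.
#'
#' @param cohort an \linkS4class{AdmixedCohort}.
#' @param ann a \linkS4class{VariantAnnotations}.
#' @param cfg a \linkS4class{FilterConfig}.
#' @param release optional \linkS4class{DatabaseRelease} whose assertions
#'   override the ClinVar slot before classification.
#' @param classes which classes count as PAVs for the scan.
#' @return data.frame with \code{gene}, \code{pooled_r}, \code{p_value},
#'   \code{q_value}, sorted by p-value; attribute \code{untested} lists genes
#'   that could not be tested and why.
#' @export
geneLevelScan <- function(cohort, ann, cfg = FilterConfig(), release = NULL,
                          classes = c("DEL_PAV", "NONDEL_PAV")) {
    if (!is.null(release)) ann <- overrideClinVar(ann, release)
    classified <- classifyVariants(ann, cfg)
    v <- variants(ann)
    pavIds <- classified$variant_id[classified$class %in% classes]
    pavIds <- intersect(pavIds, variantIds(cohort))
    gene <- structure(v$gene, names = v$variant_id)[pavIds]
    keep <- !is.na(gene) & gene != ""
    pavIds <- pavIds[keep]; gene <- gene[keep]
    untested <- list(); rows <- list()
    g <- genotypes(cohort)
    for (gn in unique(gene)) {
        ids <- pavIds[gene == gn]
        gm <- g[, ids, drop = FALSE]
        gm[is.na(gm)] <- 0L
        y <- rowSums(gm >= 1L)
        if (stats::sd(y) == 0) {
            untested[[gn]] <- data.frame(gene = gn, reason = "zero count variance")
            next
        }
        res <- tryCatch(pooledAncestryCorrelation(cohort, y),
                        error = function(e) NULL)
        if (is.null(res)) {
            untested[[gn]] <- data.frame(gene = gn, reason = "no usable strata")
        } else {
            rows[[gn]] <- data.frame(gene = gn, pooled_r = pooledR(res),
                                     p_value = pValue(res))
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene = character(), pooled_r = numeric(),
                   p_value = numeric())
    if (nrow(out)) {
        out$q_value <- bhFDR(out$p_value)
        out <- out[order(out$p_value), , drop = FALSE]
        rownames(out) <- NULL
    } else out$q_value <- numeric()
    attr(out, "untested") <- if (length(untested)) do.call(rbind, untested) else
        data.frame(gene = character(), reason = character())
    out
}

#' Gene-set enrichment of scan hits against a reference list
#'
#' Two-sided Fisher's exact test on the 2x2 table of hit/non-hit versus
#' in-reference/not, within the tested universe.
#'
#' @param hits character vector of hit genes (subset of \code{universe}).
#' @param universe character vector of all tested genes.
#' @param reference character vector of reference genes (intersected with the
#'   universe).
#' @return list with \code{odds_ratio}, \code{p_value} and the \code{table}.
#' @export
geneSetEnrichment <- function(hits, universe, reference) {
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    hits <- intersect(unique(hits), universe)
    reference <- intersect(unique(reference), universe)
    if (!length(hits))
        return(list(odds_ratio = 0, p_value = 1,
                    table = matrix(c(0, length(reference), 0,
                                     length(universe) - length(reference)),
                                   2, 2)))
    a <- length(intersect(hits, reference))
    b <- length(setdiff(hits, reference))
    c_ <- length(setdiff(reference, hits))
    d <- length(universe) - a - b - c_
    tab <- matrix(c(a, c_, b, d), 2, 2,
                  dimnames = list(c("hit", "non_hit"),
                                  c("in_reference", "not_in_reference")))
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
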