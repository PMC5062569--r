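## Confirmation-cost model: prioritized variants inside a candidate gene
## panel, and cost comparison between ancestry strata.

#' Per-individual prioritized variant counts within a candidate panel
#'
#' Counts carried variants whose class is prioritized (default: both PAV
#' classes plus deleterious NAVs) and whose gene belongs to the candidate
#' panel (roughly 1\% of the genome, about 200 genes, in the default cost
#' scenario).
#'
#' @param cohort an \linkS4class{AdmixedCohort}.
#' @param classified output of \code{\link{classifyVariants}}.
#' @param ann the matching \linkS4class{VariantAnnotations} (provides gene
#'   symbols).
#' @param panelGenes character vector of candidate-panel genes.
#' @param cfg a \linkS4class{CostConfig}.
#' @return named numeric vector of per-individual prioritized counts.
#' @export
prioritizedCounts <- function(cohort, classified, ann, panelGenes,
                              cfg = CostConfig()) {
    if (!length(panelGenes)) stop("empty candidate gene panel")
    gene <- structure(variants(ann)$gene, names = variantIds(ann))
    keep <- classified$variant_id[
        classified$class %in% cfg@prioritizedClasses &
        gene[classified$variant_id] %in% panelGenes]
    keep <- intersect(keep, variantIds(cohort))
    carrier <- .carrierMatrix(cohort)
    if (!length(keep))
        return(structure(numeric(nrow(carrier)), names = rownames(carrier)))
    structure(rowSums(carrier[, keep, drop = FALSE]),
              names = rownames(carrier))
}

#' Sample a default candidate gene panel
#' @param ann a \linkS4class{VariantAnnotations}.
#' @param size panel size (default 200 genes).
#' @param seed seed for the draw.
#' @return character vector of gene symbols.
#' @export
samplePanelGenes <- function(ann, size = 200L, seed = 1L) {
    pool <- sort(unique(setdiff(variants(ann)$gene, "")))
    set.seed(.streamSeed(seed, "panel"))
    sort(sample(pool, min(size, length(pool))))
}

#' Fold increase and confirmation-cost difference between two strata
#'
#' @param meanCountA,meanCountB mean per-patient prioritized counts in the
#'   two strata (A is the higher-burden stratum in the usual reading).
#' @param cfg a \linkS4class{CostConfig} supplying the per-variant
#'   confirmation cost.
#' @return list with \code{fold} = meanCountA / meanCountB and
#'   \code{costDifference} = (meanCountA - meanCountB) * cost per
#'   confirmation.
#' @export
strataCostComparison <- function(meanCountA, meanCountB, cfg = CostConfig()) {
    if (meanCountB <= 0) stop("meanCountB must be > 0")
    list(fold = meanCountA / meanCountB,
         costDifference = (meanCountA - meanCountB) *
             cfg@costPerConfirmation)
}

#' Compare confirmation costs between ancestry strata of a cohort
#'
#' Strata are defined by thresholding the African-ancestry proportion:
#' individuals with theta >= \code{afrThreshold} form the African-ancestry
#' stratum, those with theta <= \code{eurThreshold} the European-ancestry
#' stratum.
#'
#' @param cohort an \linkS4class{AdmixedCohort}.
#' @param counts per-individual prioritized counts (named, from
#'   \code{\link{prioritizedCounts}}).
#' @param cfg a \linkS4class{CostConfig}.
#' @param afrThreshold,eurThreshold ancestry cutoffs (defaults 0.5 / 0.1).
#' @return list with \code{meanAfrican}, \code{meanEuropean}, \code{nAfrican},
#'   \code{nEuropean}, \code{fold}, \code{costDifference}.
#' @export
ancestryStrataComparison <- function(cohort, counts, cfg = CostConfig(),
                                     afrThreshold = 0.5,
                                     eurThreshold = 0.1) {
    theta <- africanAncestry(cohort)
    counts <- counts[names(theta)]
    afr <- counts[theta >= afrThreshold]
    eur <- counts[theta <= eurThreshold]
    if (!length(afr) || !length(eur))
        stop("one of the ancestry strata is empty at the given thresholds")
    cmp <- strataCostComparison(mean(afr), mean(eur), cfg)
    list(meanAfrican = mean(afr), meanEuropean = mean(eur),
         nAfrican = length(afr), nEuropean = length(eur),
         fold = cmp$fold, costDifference = cmp$costDifference)
}
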