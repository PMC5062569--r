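## Compact fixture builders used across the suite.

## Build a VariantAnnotations object from a compact per-variant description.
## Defaults give a rare, protein-altering missense variant with no
## assertions and zero deleterious predictor calls.
makeAnn <- function(n = 1L, consequence = "missense", gene = "G1",
                    coding = TRUE, altering = consequence %in%
                        c("missense", "nonsense", "splice"),
                    freqAFR = 0.01, freqEUR = 0.01, nDel = 0L,
                    nMissing = 0L, omim = "absent", hgmd = "absent",
                    clinvar = "absent") {
    rec <- function(x) rep_len(x, n)
    v <- data.frame(variant_id = sprintf("chr1:%d:A:T", seq_len(n) * 100L),
                    chrom = "chr1", pos = seq_len(n) * 100L, ref = "A",
                    alt = "T", gene = rec(gene),
                    consequence = rec(consequence),
                    inProteinCodingGene = rec(coding),
                    proteinAltering = rec(altering),
                    stringsAsFactors = FALSE)
    f <- cbind(AFR = rec(freqAFR), EUR = rec(freqEUR))
    preds <- AncestryBias:::.DEFAULT_PREDICTORS
    nDel <- rec(as.integer(nDel)); nMissing <- rec(as.integer(nMissing))
    calls <- t(vapply(seq_len(n), function(i) {
        x <- rep("benign", 11L)
        if (nDel[i] > 0L) x[seq_len(nDel[i])] <- "deleterious"
        if (nMissing[i] > 0L)
            x[nDel[i] + seq_len(nMissing[i])] <- "missing"
        x
    }, character(11L)))
    colnames(calls) <- preds
    a <- cbind(OMIM = rec(omim), HGMD = rec(hgmd), ClinVar = rec(clinvar))
    VariantAnnotations(v, f, calls, AncestryBias:::.DEFAULT_PREDICTOR_CATEGORIES,
                       a)
}

## A small cohort with explicit populations, ancestry and genotypes.
makeCohortFixture <- function(genotypes, population, theta) {
    ids <- sprintf("S%03d", seq_len(nrow(genotypes)))
    rownames(genotypes) <- ids
    AdmixedCohort(data.frame(individual_id = ids, population = population,
                             africanAncestry = theta,
                             stringsAsFactors = FALSE),
                  genotypes)
}

## Independently coded Fisher-z fixed-effect pooling oracle (kept distinct
## from the implementation: explicit log form, scale()-based Pearson).
poolOracle <- function(theta, y, pop) {
    zs <- numeric(0); ws <- numeric(0)
    for (p in unique(pop)) {
        i <- pop == p
        n <- sum(i)
        if (n < 4L || sd(theta[i]) == 0 || sd(y[i]) == 0) next
        r <- sum(scale(theta[i]) * scale(y[i])) / (n - 1)
        zs <- c(zs, 0.5 * log((1 + r) / (1 - r)))
        ws <- c(ws, n - 3)
    }
    if (!length(ws)) return(NA_real_)
    tanh(sum(ws * zs) / sum(ws))
}

## Classical BH step-up rejected set (index vector), coded independently.
bhStepUpRejected <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    k <- which(p[o] <= seq_len(m) / m * alpha)
    if (!length(k)) integer(0) else sort(o[seq_len(max(k))])
}

## A cohort whose ancestry-count correlation is planted exactly: theta
## uniform within pops, y = rho * std(theta) + sqrt(1 - rho^2) * noise.
plantedCorrelationCohort <- function(nPop = 16L, nPer = 40L, rho = 0) {
    pop <- rep(sprintf("P%02d", seq_len(nPop)), each = nPer)
    theta <- runif(nPop * nPer, 0.2, 0.8)
    y <- numeric(nPop * nPer)
    for (p in unique(pop)) {
        i <- pop == p
        ts <- scale(theta[i])
        y[i] <- rho * ts + sqrt(1 - rho^2) * rnorm(sum(i))
    }
    g <- matrix(0L, nPop * nPer, 1L,
                dimnames = list(sprintf("S%04d", seq_len(nPop * nPer)),
                                "chr1:1:A:T"))
    list(cohort = AdmixedCohort(
             data.frame(individual_id = rownames(g), population = pop,
                        africanAncestry = theta, stringsAsFactors = FALSE),
             g),
         counts = y)
}

## Small SimConfig for fast io round-trips.
tinySimConfig <- function(seed = 1L, ...) {
    SimConfig(seed = seed, nPopulations = 4L, nPerPopulation = 10L,
              ancestryMeans = c(0.2, 0.4, 0.6, 0.8), nGenes = 30L,
              nVariants = 400L, nReleases = 6L, depositRelease = 4L,
              depositNBiased = 5L, depositNNeutral = 20L,
              nReferenceAfricans = 5L, ...)
}
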