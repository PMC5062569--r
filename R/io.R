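## Readers and writers for every external artifact of the audit.
##
## Conventions: coordinates stay 1-based throughout; the canonical join key
## across all tables is variant_id = "chrom:pos:ref:alt". The annotation TSV
## is the exchange format for the per-variant annotation record (one row per
## variant; frequency columns "freq.<panel>", predictor columns
## "pred.<category>.<name>", assertion columns "assert.<database>").

## ---------------------------------------------------------------------------
## VCF
## ---------------------------------------------------------------------------

#' Write a cohort to a plain-text VCF 4.2 file
#'
#' @param cohort an \linkS4class{AdmixedCohort}.
#' @param variants variant data.frame (chrom, pos, ref, alt, variant_id);
#'   column order in the file follows this table.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCohortVCF <- function(cohort, variants, path) {
    g <- genotypes(cohort)
    stopifnot(identical(colnames(g), variants$variant_id))
    gtCodes <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(g), ncol(g))
    ok <- !is.na(g)
    gt[ok] <- gtCodes[g[ok] + 1L]
    body <- paste(variants$chrom, variants$pos, variants$variant_id,
                  variants$ref, variants$alt, ".", "PASS", ".", "GT",
                  apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    header <- c("##fileformat=VCFv4.2",
                "##source=AncestryBias synthetic cohort",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", rownames(g)), collapse = "\t"))
    writeLines(c(header, body), path)
    invisible(path)
}

.gtToCount <- function(gt, altIndex = 1L) {
    ## map unique genotype strings to allele counts of the requested alt
    u <- unique(as.vector(gt))
    cnt <- vapply(u, function(s) {
        if (is.na(s)) return(NA_integer_)
        al <- strsplit(s, "[/|]")[[1]]
        if (any(al == ".")) return(NA_integer_)
        sum(al == as.character(altIndex))
    }, integer(1))
    matrix(cnt[match(as.vector(gt), u)], nrow(gt), ncol(gt),
           dimnames = dimnames(gt))
}

#' Read cohort genotypes from a VCF file
#'
#' Decodes diploid GT fields into alternate-allele counts; "./." is recorded
#' as missing (NA), never as 0. Multi-allelic records are split into one
#' variant per alternate allele or rejected, per \code{multiallelic}.
#'
#' @param path VCF file path.
#' @param sampleSubset optional character vector of sample ids to keep.
#' @param multiallelic "reject" (default: error on multi-allelic records) or
#'   "split".
#' @return list with \code{genotypes} (samples x variants integer matrix) and
#'   \code{variants} (data.frame: variant_id, chrom, pos, ref, alt).
#' @export
readCohortVCF <- function(path, sampleSubset = NULL,
                          multiallelic = c("reject", "split")) {
    multiallelic <- match.arg(multiallelic)
    ## cheap structural validation so parse errors carry a line number
    lines <- readLines(path)
    hdr <- grepl("^#", lines)
    nfield <- lengths(strsplit(lines[!hdr], "\t", fixed = TRUE))
    expected <- lengths(strsplit(lines[which(hdr)[sum(hdr)]], "\t",
                                 fixed = TRUE))
    bad <- which(nfield != expected)
    if (length(bad))
        stop(sprintf("malformed VCF line %d: expected %d fields, found %d",
                     which(!hdr)[bad[1]], expected, nfield[bad[1]]))
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                       dimnames = list(NULL, names(gt)))
    samples <- colnames(gt)
    if (!is.null(sampleSubset)) {
        miss <- setdiff(sampleSubset, samples)
        if (length(miss))
            stop("sample id(s) not found in VCF: ",
                 paste(miss, collapse = ", "))
        gt <- gt[, sampleSubset, drop = FALSE]
        samples <- sampleSubset
    }
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi) && multiallelic == "reject")
        stop("multi-allelic record(s) at ",
             paste(head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]),
                        5), collapse = ", "),
             "; re-run with multiallelic = \"split\" to split them")
    outV <- list(); outG <- list()
    bi <- !multi
    if (any(bi)) {
        cnt <- .gtToCount(gt[bi, , drop = FALSE], 1L)
        outV[[1]] <- data.frame(chrom = fix[bi, "CHROM"],
                                pos = as.integer(fix[bi, "POS"]),
                                ref = fix[bi, "REF"], alt = fix[bi, "ALT"],
                                stringsAsFactors = FALSE)
        outG[[1]] <- cnt
    }
    if (any(multi)) {
        for (i in which(multi)) {
            alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
            for (a in seq_along(alts)) {
                outV[[length(outV) + 1L]] <-
                    data.frame(chrom = fix[i, "CHROM"],
                               pos = as.integer(fix[i, "POS"]),
                               ref = fix[i, "REF"], alt = alts[a],
                               stringsAsFactors = FALSE)
                outG[[length(outG) + 1L]] <-
                    .gtToCount(gt[i, , drop = FALSE], a)
            }
        }
        .log("info", "split ", sum(multi), " multi-allelic record(s)")
    }
    v <- do.call(rbind, outV)
    g <- do.call(rbind, outG)
    v$variant_id <- .variantId(v$chrom, v$pos, v$ref, v$alt)
    g <- t(g)                       # samples x variants
    storage.mode(g) <- "integer"
    dimnames(g) <- list(samples, v$variant_id)
    list(genotypes = g, variants = v[, c("variant_id", "chrom", "pos",
                                         "ref", "alt")])
}

#' Assemble an AdmixedCohort from genotypes, labels and ancestry proportions
#'
#' @param genotypes samples x variants integer matrix (as from
#'   \code{\link{readCohortVCF}}).
#' @param labels data.frame with \code{individual_id} and \code{population}
#'   (reference-panel rows are dropped).
#' @param theta named numeric vector of African-ancestry proportions (as from
#'   \code{\link{readQMatrix}}).
#' @return An \linkS4class{AdmixedCohort}.
#' @export
makeCohort <- function(genotypes, labels, theta) {
    ids <- rownames(genotypes)
    lab <- labels[match(ids, labels$individual_id), ]
    if (any(is.na(lab$individual_id)))
        stop("population label missing for: ",
             paste(head(ids[is.na(lab$individual_id)], 5), collapse = ", "))
    if (!all(ids %in% names(theta)))
        stop("ancestry proportion missing for: ",
             paste(head(setdiff(ids, names(theta)), 5), collapse = ", "))
    AdmixedCohort(data.frame(individual_id = ids,
                             population = lab$population,
                             africanAncestry = unname(theta[ids]),
                             stringsAsFactors = FALSE),
                  genotypes)
}

## ---------------------------------------------------------------------------
## annotation table
## ---------------------------------------------------------------------------

#' Write a VariantAnnotations object to TSV
#' @param ann a \linkS4class{VariantAnnotations}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnnotationTable <- function(ann, path) {
    v <- variants(ann)
    f <- popFreqs(ann); colnames(f) <- paste0("freq.", colnames(f))
    cats <- predictorCategories(ann)
    p <- predictorCalls(ann)
    colnames(p) <- paste0("pred.",
                          ifelse(cats[colnames(p)] == "database_trained",
                                 "db", "ag"), ".", colnames(p))
    a <- assertions(ann); colnames(a) <- paste0("assert.", colnames(a))
    tab <- cbind(v, as.data.frame(f), as.data.frame(p, stringsAsFactors = FALSE),
                 as.data.frame(a, stringsAsFactors = FALSE))
    names(tab)[names(tab) == "inProteinCodingGene"] <- "in_protein_coding_gene"
    names(tab)[names(tab) == "proteinAltering"] <- "protein_altering"
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a VariantAnnotations object from TSV
#' @param path annotation TSV written by \code{\link{writeAnnotationTable}}
#'   (or following the same column conventions).
#' @return A \linkS4class{VariantAnnotations}.
#' @export
readAnnotationTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
              "consequence", "in_protein_coding_gene", "protein_altering")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("annotation table lacks column(s): ",
             paste(miss, collapse = ", "))
    v <- tab[, need]
    names(v)[8:9] <- c("inProteinCodingGene", "proteinAltering")
    v$gene[is.na(v$gene)] <- ""
    fCols <- grep("^freq\\.", names(tab), value = TRUE)
    f <- as.matrix(tab[, fCols, drop = FALSE])
    colnames(f) <- sub("^freq\\.", "", fCols)
    pCols <- grep("^pred\\.", names(tab), value = TRUE)
    p <- as.matrix(tab[, pCols, drop = FALSE])
    predNames <- sub("^pred\\.(db|ag)\\.", "", pCols)
    cats <- structure(ifelse(grepl("^pred\\.db\\.", pCols),
                             "database_trained", "agnostic"),
                      names = predNames)
    colnames(p) <- predNames
    aCols <- grep("^assert\\.", names(tab), value = TRUE)
    a <- as.matrix(tab[, aCols, drop = FALSE])
    colnames(a) <- sub("^assert\\.", "", aCols)
    VariantAnnotations(v, f, p, cats, a)
}

## ---------------------------------------------------------------------------
## Q-matrix and population labels
## ---------------------------------------------------------------------------

#' Read population labels
#' @param path TSV with header columns \code{individual_id},
#'   \code{population}; row order matches the Q-matrix.
#' @return data.frame.
#' @export
readPopulationLabels <- function(path) {
    lab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("individual_id", "population") %in% names(lab)))
        stop("population label file needs individual_id and population columns")
    lab
}

#' Read an ADMIXTURE-style Q-matrix and extract African-ancestry proportions
#'
#' The African cluster is identified as the unique cluster in which the mean
#' membership of the reference-panel African individuals exceeds 0.99; that
#' column is the per-individual African-ancestry proportion.
#'
#' @param qPath whitespace-delimited Q-matrix (one row per individual, K
#'   columns, no header).
#' @param labels population-label data.frame (or path to one), rows aligned
#'   with the Q-matrix.
#' @param referenceLabels population label(s) marking reference-African
#'   individuals.
#' @return list with \code{theta} (named proportions for non-reference
#'   individuals), \code{africanCluster} (column index), \code{proportions}
#'   (full matrix, rows named) and \code{labels}.
#' @export
readQMatrix <- function(qPath, labels, referenceLabels = "ref_AFR") {
    if (is.character(labels)) labels <- readPopulationLabels(labels)
    Q <- as.matrix(utils::read.table(qPath))
    if (nrow(Q) != nrow(labels))
        stop("Q-matrix and label file disagree on the number of individuals")
    if (any(abs(rowSums(Q) - 1) > 1e-6))
        stop("Q-matrix rows must sum to 1 (tolerance 1e-6)")
    rownames(Q) <- labels$individual_id
    isRef <- labels$population %in% referenceLabels
    if (!any(isRef))
        stop("no reference-African individuals labelled ",
             paste(referenceLabels, collapse = "/"))
    refMeans <- colMeans(Q[isRef, , drop = FALSE])
    qual <- which(refMeans > 0.99)
    if (length(qual) == 0L)
        stop("African cluster unidentifiable: no cluster exceeds 0.99 mean ",
             "membership for the reference panel")
    if (length(qual) > 1L)
        stop("African cluster ambiguous: ", length(qual),
             " clusters exceed 0.99 mean reference membership")
    theta <- Q[!isRef, qual]
    list(theta = theta, africanCluster = unname(qual), proportions = Q,
         labels = labels)
}

## ---------------------------------------------------------------------------
## release series
## ---------------------------------------------------------------------------

#' Write a release series as one dated TSV per release
#' @param series a \linkS4class{ReleaseSeries}.
#' @param dir output directory (created if needed); files are named
#'   \code{YYYY-MM-DD.tsv}.
#' @return the written paths, invisibly.
#' @export
writeReleaseSeries <- function(series, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(releases(series), function(r) {
        p <- file.path(dir, paste0(as.character(r@date), ".tsv"))
        utils::write.table(data.frame(variant_id = names(r@assertions),
                                      assertion = unname(r@assertions)),
                           p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
    }, character(1))
    invisible(paths)
}

#' Read a directory of dated release tables
#'
#' Files must be named by ISO date (\code{YYYY-MM-DD.tsv}) and contain
#' tab-separated \code{variant_id} and \code{assertion} columns. Duplicate
#' variant rows within one release keep the last occurrence (logged).
#'
#' @param dir directory of release TSVs.
#' @return A \linkS4class{ReleaseSeries} sorted ascending by date.
#' @export
readReleaseSeries <- function(dir) {
    files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("empty release directory: ", dir)
    dates <- as.Date(sub("\\.tsv$", "", basename(files)),
                     format = "%Y-%m-%d")
    if (any(is.na(dates)))
        stop("unparseable release date in filename(s): ",
             paste(basename(files)[is.na(dates)], collapse = ", "))
    rel <- lapply(seq_along(files), function(i) {
        tab <- utils::read.delim(files[i], stringsAsFactors = FALSE)
        if (!all(c("variant_id", "assertion") %in% names(tab)))
            stop("release file needs variant_id and assertion columns: ",
                 files[i])
        dup <- duplicated(tab$variant_id, fromLast = TRUE)
        if (any(dup)) {
            warning(sum(dup), " duplicate variant row(s) in ",
                    basename(files[i]), ": last occurrence kept")
            tab <- tab[!dup, , drop = FALSE]
        }
        DatabaseRelease(dates[i], structure(tab$assertion,
                                            names = tab$variant_id))
    })
    ReleaseSeries(rel)
}

## ---------------------------------------------------------------------------
## gene lists and whole bundles
## ---------------------------------------------------------------------------

#' Read a one-gene-per-line list
#' @param path text file.
#' @return character vector (blank lines dropped).
#' @export
readGeneList <- function(path) {
    g <- trimws(readLines(path))
    g[nzchar(g)]
}

#' Load a complete synthetic bundle directory into domain objects
#'
#' Reads the artifacts written by \code{\link{simulateBundle}} and assembles
#' the analysis-ready objects.
#'
#' @param dir bundle directory.
#' @param referenceLabels reference-African population label(s) in pops.tsv.
#' @return list with \code{cohort}, \code{ann}, \code{series},
#'   \code{panelGenes}, \code{mendelianGenes}, \code{gwasGenes},
#'   \code{qmatrix}.
#' @export
loadBundle <- function(dir, referenceLabels = "ref_AFR") {
    labels <- readPopulationLabels(file.path(dir, "pops.tsv"))
    qm <- readQMatrix(file.path(dir, "qmatrix.Q"), labels, referenceLabels)
    vcf <- readCohortVCF(file.path(dir, "cohort.vcf"))
    cohort <- makeCohort(vcf$genotypes,
                         labels[!labels$population %in% referenceLabels, ],
                         qm$theta)
    ann <- readAnnotationTable(file.path(dir, "annotations.tsv"))
    series <- readReleaseSeries(file.path(dir, "releases"))
    list(cohort = cohort, ann = ann, series = series,
         panelGenes = readGeneList(file.path(dir, "panel_genes.txt")),
         mendelianGenes = readGeneList(file.path(dir, "mendelian_genes.txt")),
         gwasGenes = readGeneList(file.path(dir, "gwas_genes.txt")),
         qmatrix = qm)
}
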