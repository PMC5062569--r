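## End-to-end orchestration: simulate -> classify -> correlate -> timeseries
## -> genescan -> cost, driven by one YAML config, with a manifest recording
## the seed, config digest, input digests and outputs. Unchanged stages are
## skipped on re-runs when their input digests match.

.PIPELINE_STAGES <- c("simulate", "classify", "correlate", "timeseries",
                      "genescan", "cost")
.STAGE_DEPS <- list(simulate = character(), classify = "simulate",
                    correlate = "classify", timeseries = "simulate",
                    genescan = "simulate", cost = "classify")

.validatePipelineConfig <- function(config) {
    if (is.null(config$stages)) config$stages <- .PIPELINE_STAGES
    bad <- setdiff(config$stages, .PIPELINE_STAGES)
    if (length(bad))
        stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
    config$stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% config$stages]
    for (s in config$stages) {
        need <- setdiff(.STAGE_DEPS[[s]], config$stages)
        if (length(need))
            stop("stage '", s, "' requires upstream stage(s): ",
                 paste(need, collapse = ", "))
    }
    if (is.null(config$seed)) config$seed <- 1L
    config
}

.digestFiles <- function(paths) {
    paths <- paths[file.exists(paths)]
    structure(as.character(tools::md5sum(paths)), names = basename(paths))
}

#' Run the full bias-audit pipeline from a config
#'
#' Stages: \code{simulate} (write the synthetic bundle), \code{classify}
#' (per-variant classes and per-individual count matrix), \code{correlate}
#' (pooled ancestry correlation per class), \code{timeseries} (release
#' trajectory, sign flips, driver attribution for the largest flip),
#' \code{genescan} (gene-level PAV scan) and \code{cost} (panel-restricted
#' prioritized counts and strata cost comparison). A manifest
#' (\code{manifest.yaml}) records seed, config digest, per-stage input
#' digests and outputs; a stage whose recorded input digests still match is
#' skipped as a cache hit.
#'
#' @param config path to a YAML config, or an equivalent named list. Keys:
#'   \code{seed}, \code{stages}, \code{sim} (SimConfig overrides),
#'   \code{filter} (FilterConfig fields), \code{cost} (CostConfig fields plus
#'   \code{afrThreshold}/\code{eurThreshold}), \code{alpha},
#'   \code{coverage}.
#' @param outDir output directory.
#' @param seed optional override of the config seed.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
    configDigest <- NA_character_
    if (is.character(config)) {
        configDigest <- as.character(tools::md5sum(config))
        config <- yaml::read_yaml(config)
    }
    config <- .validatePipelineConfig(config)
    if (!is.null(seed)) config$seed <- as.integer(seed)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    manifestPath <- file.path(outDir, "manifest.yaml")
    oldManifest <- if (file.exists(manifestPath))
        yaml::read_yaml(manifestPath) else NULL
    manifest <- list(timestamp = format(Sys.time(), tz = "UTC"),
                     seed = config$seed, config_digest = configDigest,
                     package_version =
                         as.character(utils::packageVersion("AncestryBias")),
                     stages = list(), outputs = character())

    simCfg <- do.call(SimConfig, c(list(seed = config$seed),
                                   config$sim))
    filterCfg <- do.call(FilterConfig, as.list(config$filter))
    costArgs <- as.list(config$cost)
    afrThr <- costArgs$afrThreshold %||% 0.5
    eurThr <- costArgs$eurThreshold %||% 0.1
    costArgs$afrThreshold <- NULL; costArgs$eurThreshold <- NULL
    costCfg <- do.call(CostConfig, costArgs)
    alpha <- config$alpha %||% 0.05
    coverage <- config$coverage %||% 0.9

    bundleDir <- file.path(outDir, "bundle")
    state <- new.env(parent = emptyenv())

    stageInputs <- function(stage) {
        switch(stage,
            simulate = character(),
            classify = file.path(bundleDir, c("cohort.vcf",
                                              "annotations.tsv")),
            correlate = file.path(outDir, "classify",
                                  c("classes.tsv", "counts.tsv")),
            timeseries = c(file.path(bundleDir, c("cohort.vcf",
                                                  "annotations.tsv")),
                           list.files(file.path(bundleDir, "releases"),
                                      full.names = TRUE)),
            genescan = file.path(bundleDir, c("cohort.vcf",
                                              "annotations.tsv")),
            cost = file.path(outDir, "classify", "classes.tsv"))
    }

    needBundle <- function() {
        if (is.null(state$bundle))
            state$bundle <- loadBundle(bundleDir,
                                       simCfg@referenceLabel)
        state$bundle
    }
    needClassified <- function() {
        if (is.null(state$classified)) {
            b <- needBundle()
            state$classified <- classifyVariants(b$ann, filterCfg)
            state$counts <- perIndividualCounts(b$cohort, state$classified)
        }
        list(classified = state$classified, counts = state$counts)
    }

    runStage <- list(
        simulate = function(dir) {
            simulateBundle(simCfg, bundleDir)
            character()  # outputs tracked via the bundle dir
        },
        classify = function(dir) {
            cl <- needClassified()
            f1 <- file.path(dir, "classes.tsv")
            utils::write.table(cl$classified, f1, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            f2 <- file.path(dir, "counts.tsv")
            utils::write.table(data.frame(individual_id =
                                              rownames(cl$counts),
                                          cl$counts, check.names = FALSE),
                               f2, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            c(f1, f2)
        },
        correlate = function(dir) {
            b <- needBundle(); cl <- needClassified()
            rows <- lapply(colnames(cl$counts), function(k) {
                res <- tryCatch(
                    pooledAncestryCorrelation(b$cohort, cl$counts[, k]),
                    error = function(e) NULL)
                data.frame(class = k,
                           pooled_r = if (is.null(res)) NA else pooledR(res),
                           p_value = if (is.null(res)) NA else pValue(res),
                           n_effective = if (is.null(res)) NA else
                               res@nEffective)
            })
            f <- file.path(dir, "bias.tsv")
            utils::write.table(do.call(rbind, rows), f, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            f
        },
        timeseries = function(dir) {
            b <- needBundle()
            traj <- correlationTrajectory(b$series, b$cohort, b$ann,
                                          filterCfg, filtered = FALSE)
            f1 <- file.path(dir, "trajectory.tsv")
            utils::write.table(traj, f1, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            flips <- detectFlips(traj, alpha)
            f2 <- file.path(dir, "flips.tsv")
            utils::write.table(flips, f2, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            outs <- c(f1, f2)
            if (nrow(flips)) {
                i <- which.max(abs(flips$r_B - flips$r_A))
                rel <- releases(b$series)
                dts <- releaseDates(b$series)
                rep_ <- attributeDrivers(rel[[which(dts == flips$date_A[i])]],
                                         rel[[which(dts == flips$date_B[i])]],
                                         b$cohort, b$ann, filterCfg,
                                         coverage)
                f3 <- file.path(dir, "drivers.tsv")
                utils::write.table(drivers(rep_), f3, sep = "\t",
                                   quote = FALSE, row.names = FALSE)
                outs <- c(outs, f3)
            }
            outs
        },
        genescan = function(dir) {
            b <- needBundle()
            scan <- geneLevelScan(b$cohort, b$ann, filterCfg)
            f <- file.path(dir, "genes.tsv")
            utils::write.table(scan, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            f
        },
        cost = function(dir) {
            b <- needBundle(); cl <- needClassified()
            pc <- prioritizedCounts(b$cohort, cl$classified, b$ann,
                                    b$panelGenes, costCfg)
            cmp <- ancestryStrataComparison(b$cohort, pc, costCfg,
                                            afrThr, eurThr)
            f <- file.path(dir, "cost.tsv")
            utils::write.table(as.data.frame(cmp), f, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            f
        })

    for (stage in config$stages) {
        dir <- if (stage == "simulate") bundleDir else
            file.path(outDir, stage)
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        inputs <- .digestFiles(stageInputs(stage))
        old <- oldManifest$stages[[stage]]
        outFiles <- if (stage == "simulate")
            list.files(bundleDir, recursive = TRUE, full.names = TRUE) else
            unlist(old$outputs)
        norm <- function(x) {
            x <- unname(unlist(x))
            if (is.null(x)) character(0) else as.character(x)
        }
        cached <- !is.null(old) &&
            identical(as.integer(old$seed), as.integer(config$seed)) &&
            identical(norm(old$inputs), norm(inputs)) &&
            length(outFiles) > 0 && all(file.exists(outFiles))
        if (cached) {
            .log("info", "stage '", stage, "': cache hit, skipped")
            manifest$stages[[stage]] <- old
            manifest$stages[[stage]]$cached <- TRUE
        } else {
            .log("info", "stage '", stage, "': running")
            outs <- runStage[[stage]](dir)
            if (stage == "simulate")
                outs <- list.files(bundleDir, recursive = TRUE,
                                   full.names = TRUE)
            manifest$stages[[stage]] <- list(
                seed = config$seed, inputs = as.list(inputs),
                outputs = as.list(outs),
                output_digests = as.list(.digestFiles(outs)),
                cached = FALSE)
        }
        manifest$outputs <- c(manifest$outputs,
                              unlist(manifest$stages[[stage]]$outputs))
    }
    yaml::write_yaml(manifest, manifestPath)
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
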