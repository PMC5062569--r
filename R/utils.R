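## Seed streams and logging helpers.

## Offsets give each generator its own reproducible stream derived from the
## single user seed. Values stay well below 2^31.
.STREAM_OFFSETS <- c(cohort = 101L, annotations = 211L, releases = 307L,
                     panel = 401L, qmatrix = 503L, pipeline = 601L)

.streamSeed <- function(seed, stream) {
    stopifnot(stream %in% names(.STREAM_OFFSETS))
    (as.integer(seed) %% 2000000000L) + .STREAM_OFFSETS[[stream]]
}

.LOG_LEVELS <- c(debug = 1L, info = 2L, warning = 3L, quiet = 4L)

#' Set the package log level
#' @param level one of "debug", "info", "warning", "quiet".
#' @return the previous level, invisibly.
#' @export
setLogLevel <- function(level = c("info", "debug", "warning", "quiet")) {
    level <- match.arg(level)
    old <- getOption("AncestryBias.logLevel", "info")
    options(AncestryBias.logLevel = level)
    invisible(old)
}

.log <- function(level, ...) {
    cur <- getOption("AncestryBias.logLevel", "info")
    if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[cur]])
        message(sprintf("[%s] %s", level, paste0(...)))
    invisible(NULL)
}

## canonical variant key
.variantId <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

## row-wise max ignoring NA; rows that are all-NA come back NA
.rowMaxNA <- function(m) {
    if (ncol(m) == 0L) return(rep(NA_real_, nrow(m)))
    out <- do.call(pmax, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                           list(na.rm = TRUE)))
    out[!is.finite(out)] <- NA_real_
    out
}
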