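# Reading/writing expression matrices, phenotype files, result tables and
# run configurations. Matrices are plain tab-delimited text: first row sample
# ids, first column feature ids. Values are assumed log-transformed and
# pre-processed; no normalization is performed here.

#' Read a tab-delimited expression matrix with group labels
#'
#' The file layout is: first row sample ids, first column feature ids,
#' tab-delimited numeric body. Group labels come from (in order of
#' precedence): \code{groupSpec} given as a named character vector; a
#' two-column phenotype file (\code{sample_id<TAB>group}, with header) named
#' by \code{groupSpec}; or an embedded second line whose first field is
#' \code{group}. When both a phenotype file and an embedded line are present
#' the phenotype file wins (explicit beats embedded).
#'
#' @param path path to the matrix file.
#' @param groupSpec named character vector (names = sample ids, values
#'   \code{"A"}/\code{"B"}), or the path of a two-column phenotype TSV, or
#'   \code{NULL} to rely on an embedded \code{group} line.
#' @return A \linkS4class{TwoGroupExperiment}; row and column order are
#'   preserved from the file.
#' @export
readExpressionMatrix <- function(path, groupSpec = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    header <- strsplit(readLines(path, n = 2L), "\t", fixed = TRUE)
    sampleIds <- header[[1L]][-1L]
    embedded <- NULL
    skip <- 1L
    if (length(header) > 1L && identical(header[[2L]][1L], "group")) {
        embedded <- structure(header[[2L]][-1L], names = sampleIds)
        skip <- 2L
    }
    body <- read.delim(path, header = FALSE, skip = skip,
                       colClasses = c("character", rep("numeric",
                                                       length(sampleIds))),
                       stringsAsFactors = FALSE, check.names = FALSE)
    featureIds <- body[[1L]]
    if (anyDuplicated(featureIds))
        stop("duplicate feature id: '",
             featureIds[anyDuplicated(featureIds)], "'")
    values <- as.matrix(body[, -1L, drop = FALSE])
    dimnames(values) <- list(featureIds, sampleIds)
    if (anyNA(values)) {
        bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
        stop(sprintf("missing value at feature '%s', sample '%s'",
                     featureIds[bad[1L]], sampleIds[bad[2L]]))
    }
    labels <- embedded
    if (!is.null(groupSpec)) {
        if (is.character(groupSpec) && length(groupSpec) == 1L &&
            is.null(names(groupSpec))) {
            pheno <- read.delim(groupSpec, header = TRUE,
                                colClasses = "character")
            labels <- structure(pheno[[2L]], names = pheno[[1L]])
        } else labels <- groupSpec
    }
    if (is.null(labels))
        stop("no group labels: supply 'groupSpec' or an embedded 'group' line")
    missing <- setdiff(sampleIds, names(labels))
    if (length(missing))
        stop("sample without group label: ", paste(missing, collapse = ", "))
    TwoGroupExperiment(values, group = labels[sampleIds])
}

#' Write a TwoGroupExperiment back to the tab-delimited matrix format
#'
#' Emits the matrix with an embedded \code{group} line so the file round-trips
#' through [readExpressionMatrix()] on its own. Values are rendered with 17
#' significant digits, so a write/read round trip is bit-exact for doubles.
#'
#' @param dataset a \linkS4class{TwoGroupExperiment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(dataset, path) {
    v <- exprValues(dataset)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("feature_id", colnames(v)), collapse = "\t"), con)
    writeLines(paste(c("group", as.character(groupLabels(dataset))),
                     collapse = "\t"), con)
    body <- apply(v, 1L, function(r)
        paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(paste(rownames(v), body, sep = "\t"), con)
    invisible(path)
}

#' Write a per-feature results table
#'
#' Tab-delimited with header; numeric columns are rendered with 12
#' significant digits so p-values survive a write/read round trip to at least
#' 10 significant digits.
#'
#' @param rows a data.frame of per-feature records (typically feature id,
#'   filter statistic, test statistic, p-value, adjusted value, rejection
#'   flag). An empty data.frame yields a header-only file.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(rows, path) {
    stopifnot(is.data.frame(rows))
    out <- rows
    num <- vapply(out, is.numeric, logical(1L))
    out[num] <- lapply(out[num], function(x)
        format(x, digits = 12, trim = TRUE))
    tryCatch(
        suppressWarnings(write.table(out, path, sep = "\t", quote = FALSE,
                                     row.names = FALSE)),
        error = function(e) stop("cannot write results table to '", path,
                                 "': ", conditionMessage(e)))
    invisible(path)
}

# Documented defaults for every configurable knob; loadConfig() fills these
# in for absent keys and rejects anything it does not know.
.configDefaults <- function() {
    list(
        simulation = list(
            m = 1000L, pi0 = 0.8, nX = 5L, nY = 5L, delta = 1, sigma = 1,
            n_datasets = 200L, phi = 0.05,
            fractions = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
            filters = c("signal", "fold_change", "variance"),
            fdr_methods = "bh", test = "t", seed = 1L),
        filter = list(statistic = "variance", fraction_out = 0),
        fdr = list(method = "bh", level = 0.05, lambda = 0.5),
        bias_test = list(filter = "fold_change", fraction_out = 0.1,
                         n_permutations = 100L, test = "t", mode = "ks",
                         seed = 1L))
}

.validateConfig <- function(config) {
    sim <- config$simulation
    for (key in c("m", "nX", "nY", "n_datasets"))
        if (sim[[key]] <= 0)
            stop("config: simulation$", key, " must be positive")
    for (f in c(sim$fractions, config$filter$fraction_out,
                config$bias_test$fraction_out))
        if (f < 0 || f >= 1)
            stop("config: fraction filtered out must lie in [0, 1); got ", f)
    if (sim$pi0 <= 0 || sim$pi0 > 1)
        stop("config: simulation$pi0 must be in (0, 1]")
    for (lvl in c(sim$phi, config$fdr$level))
        if (lvl <= 0 || lvl >= 1)
            stop("config: FDR level must lie in (0, 1); got ", lvl)
    if ("qvalue" %in% sim$fdr_methods && "fold_change" %in% sim$filters)
        stop("config: the q-value method cannot be combined with the ",
             "fold-change filter (the filtered p-value range no longer ",
             "covers [0, 1])")
    config
}

#' Load (or default) a run configuration
#'
#' Reads a YAML or JSON configuration with sections \code{simulation},
#' \code{filter}, \code{fdr} and \code{bias_test}; absent keys are filled
#' with the documented defaults, unknown keys are rejected, and bounds are
#' validated (fractions in [0, 1), positive counts, levels in (0, 1), and the
#' forbidden q-value x fold-change combination).
#'
#' @param path path to a \code{.yaml}/\code{.yml}/\code{.json} file, or
#'   \code{NULL} for the full default configuration.
#' @return validated configuration list.
#' @export
loadConfig <- function(path = NULL) {
    defaults <- .configDefaults()
    user <- list()
    if (!is.null(path)) {
        user <- if (grepl("\\.json$", path, ignore.case = TRUE))
            jsonlite::read_json(path, simplifyVector = TRUE)
        else yaml::read_yaml(path)
        if (is.null(user)) user <- list()
    }
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
        stop("config: unknown section(s): ", paste(unknown, collapse = ", "))
    for (section in names(user)) {
        bad <- setdiff(names(user[[section]]), names(defaults[[section]]))
        if (length(bad))
            stop("config: unknown key(s) in '", section, "': ",
                 paste(bad, collapse = ", "))
    }
    config <- modifyList(defaults, user)
    for (key in c("m", "nX", "nY", "n_datasets", "seed"))
        config$simulation[[key]] <- as.integer(config$simulation[[key]])
    config$bias_test$n_permutations <-
        as.integer(config$bias_test$n_permutations)
    config$bias_test$seed <- as.integer(config$bias_test$seed)
    .validateConfig(config)
}

#' Serialize a configuration to YAML
#'
#' @param config a configuration list as returned by [loadConfig()].
#' @param path output path (\code{.yaml}).
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}
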