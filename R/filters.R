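# Filter statistics and fraction-based filtering. A feature is retained when
# its statistic W(Z_i) is at least the threshold w; experiments are
# parameterized by the fraction filtered out (the paper-comparable quantity),
# and w is derived from it.

#' Filter statistics
#'
#' Per-feature filter statistics for a two-group dataset:
#' \describe{
#'   \item{signal}{WS = (mean(X) + mean(Y)) / 2, the average signal over the
#'     two group means — the classical "above background" filter.}
#'   \item{fold change}{WFC = |mean(X) - mean(Y)|, absolute (log) fold
#'     change.}
#'   \item{variance}{WV = S_Z^2, the overall sample variance across all n
#'     samples (single overall mean, denominator n - 1; groups pooled).}
#' }
#'
#' @param dataset a \linkS4class{TwoGroupExperiment}.
#' @return numeric vector, one statistic per feature, named by feature id.
#' @name filter-statistics
NULL

#' @rdname filter-statistics
#' @export
signalStatistic <- function(dataset) {
    gs <- .groupStats(dataset)
    (gs$meanA + gs$meanB) / 2
}

#' @rdname filter-statistics
#' @export
foldChangeStatistic <- function(dataset) {
    gs <- .groupStats(dataset)
    abs(gs$meanA - gs$meanB)
}

#' @rdname filter-statistics
#' @export
varianceStatistic <- function(dataset) {
    v <- exprValues(dataset)
    if (ncol(v) < 2L)
        stop("variance filter needs at least 2 samples")
    rowSums((v - rowMeans(v))^2) / (ncol(v) - 1L)
}

# Dispatch table used by the bias test and the simulation grid. "best" and
# "random" are oracle reference filters and are handled separately.
.filterStatistic <- function(dataset, name) {
    switch(name,
        signal = signalStatistic(dataset),
        fold_change = foldChangeStatistic(dataset),
        variance = varianceStatistic(dataset),
        stop("unknown filter statistic: '", name, "'"))
}

#' Filter features by the fraction to be removed
#'
#' Removes the features with the smallest statistic values so that exactly
#' \code{round((1 - fractionOut) * m)} features are retained. The threshold w
#' is the statistic value at the cut (the smallest retained value); ties at w
#' are broken by original feature order (earlier features retained first), so
#' the retained count is exact. The result is invariant under any strictly
#' increasing transform of the statistic.
#'
#' @param values numeric per-feature filter statistic.
#' @param fractionOut fraction of features to remove, in [0, 1).
#' @param statisticName label stored in the result.
#' @return A \linkS4class{FilterResult}.
#' @examples
#' fr <- applyFilter(1:10, fractionOut = 0.3)
#' filterThreshold(fr)  # 4: features with values 4..10 are retained
#' @export
applyFilter <- function(values, fractionOut, statisticName = "custom") {
    if (!is.numeric(fractionOut) || fractionOut < 0 || fractionOut >= 1)
        stop("'fractionOut' must lie in [0, 1)")
    m <- length(values)
    if (m < 1L) stop("no features to filter")
    nKeep <- as.integer(round((1 - fractionOut) * m))
    nKeep <- max(1L, nKeep)
    # stable ascending order: ties broken by original index, so the first
    # of tied features are removed first and retained counts stay exact
    ord <- order(values, seq_len(m))
    keepIdx <- ord[seq.int(m - nKeep + 1L, m)]
    retained <- logical(m)
    retained[keepIdx] <- TRUE
    new("FilterResult", statisticName = statisticName,
        values = as.numeric(values),
        threshold = as.numeric(values[ord[m - nKeep + 1L]]),
        retained = retained, gamma = nKeep / m)
}

#' Oracle "best" filter
#'
#' Simulation-only reference filter that removes only null features while any
#' remain (in index order); once the nulls are exhausted, remaining removals
#' proceed over the alternative features by index. Bounds every realistic
#' filter from below in the retained-null-proportion curve.
#'
#' @param isNull logical per feature; TRUE when the feature follows the null
#'   (the simulation truth V_i = 1).
#' @param fractionOut fraction of features to remove, in [0, 1).
#' @return A \linkS4class{FilterResult} (its \code{values} slot holds the
#'   removal-priority score the cut is taken over).
#' @export
oracleBestFilter <- function(isNull, fractionOut) {
    if (!is.logical(isNull)) stop("'isNull' must be logical")
    if (anyNA(isNull)) stop("'isNull' must not contain NA")
    m <- length(isNull)
    # removal priority: all nulls (by index) strictly before all alternatives
    score <- numeric(m)
    score[isNull] <- seq_len(sum(isNull))
    score[!isNull] <- sum(isNull) + seq_len(sum(!isNull))
    res <- applyFilter(score, fractionOut, statisticName = "best")
    res
}

#' Random reference filter
#'
#' Retains a uniformly random subset of round((1 - fractionOut) * m)
#' features, independent of the data — the upper reference bound: the
#' retained null proportion stays at the generating pi0 in expectation.
#'
#' @param m number of features.
#' @param fractionOut fraction of features to remove, in [0, 1).
#' @param seed integer seed; the same seed reproduces the same subset.
#' @return A \linkS4class{FilterResult}.
#' @export
randomFilter <- function(m, fractionOut, seed) {
    score <- withSeed(seed, runif(m))
    res <- applyFilter(score, fractionOut, statisticName = "random")
    res@values <- rep(NA_real_, m)  # no meaningful statistic
    res@threshold <- NA_real_
    res
}

#' @rdname FilterResult-accessors
#' @export
setMethod("retained", "FilterResult", function(x) x@retained)

#' @rdname FilterResult-accessors
#' @export
setMethod("filterValues", "FilterResult", function(x) x@values)

#' @rdname FilterResult-accessors
#' @export
setMethod("filterThreshold", "FilterResult", function(x) x@threshold)

#' @rdname FilterResult-accessors
#' @export
setMethod("gammaRetained", "FilterResult", function(x) x@gamma)

setMethod("show", "FilterResult", function(object) {
    cat(sprintf(
        "FilterResult '%s': %d of %d features retained (gamma = %.3f, w = %s)\n",
        object@statisticName, sum(object@retained), length(object@retained),
        object@gamma, format(object@threshold, digits = 4)))
})
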