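# Synthetic two-group data and the factorial experiment measuring achieved
# FDR, observed power and the retained null proportion across
# filter x fraction x FDR-method cells.

#' Simulate a two-group Gaussian expression dataset
#'
#' Emulates a microarray experiment with m independent features over two
#' groups of nX and nY samples. round(pi0 * m) features are null (both group
#' means 0, s.d. sigma, listed first); the remaining features are
#' differential with group means +/- Delta/2 where
#' Delta = delta * sigma * sqrt(1/nX + 1/nY), the sign drawn per feature with
#' equal probability. Centering the effect at +/- Delta/2 keeps the average
#' signal (mean(X) + mean(Y))/2 identically distributed for null and
#' differential features, so the signal filter carries no information about
#' the hypothesis — the configuration under which the reference curves are
#' derived.
#'
#' @param m number of features.
#' @param pi0 null proportion in (0, 1].
#' @param nX,nY group sizes.
#' @param delta t noncentrality of differential features.
#' @param sigma within-group standard deviation.
#' @param seed integer seed; the dataset is reproducible from it.
#' @return list with \code{dataset} (a \linkS4class{TwoGroupExperiment}) and
#'   \code{isNull} (logical truth vector, TRUE for null features).
#' @examples
#' sim <- simulateTwoGroupData(m = 100, seed = 1)
#' table(sim$isNull)
#' @export
simulateTwoGroupData <- function(m = 1000L, pi0 = 0.8, nX = 5L, nY = 5L,
                                 delta = 1, sigma = 1, seed = 1L) {
    stopifnot(m >= 1L, pi0 > 0, pi0 <= 1, nX >= 2L, nY >= 2L, sigma > 0)
    m <- as.integer(m)
    m0 <- as.integer(round(pi0 * m))
    Delta <- delta * sigma * sqrt(1 / nX + 1 / nY)
    n <- nX + nY
    vals <- withSeed(seed, {
        x <- matrix(rnorm(m * n, sd = sigma), nrow = m, ncol = n)
        if (m0 < m) {
            sign <- sample(c(-1, 1), m - m0, replace = TRUE)
            alt <- seq.int(m0 + 1L, m)
            x[alt, seq_len(nX)] <- x[alt, seq_len(nX)] + sign * Delta / 2
            x[alt, seq.int(nX + 1L, n)] <-
                x[alt, seq.int(nX + 1L, n)] - sign * Delta / 2
        }
        x
    })
    dimnames(vals) <- list(sprintf("feature_%04d", seq_len(m)),
                           c(sprintf("A%d", seq_len(nX)),
                             sprintf("B%d", seq_len(nY))))
    list(dataset = TwoGroupExperiment(vals,
                                      group = rep(c("A", "B"), c(nX, nY))),
         isNull = seq_len(m) <= m0)
}

#' Achieved FDR, observed power and retained null proportion
#'
#' Bookkeeping for simulation cells where the truth is known:
#' \describe{
#'   \item{achievedFdr}{fraction of rejected features that are true nulls;
#'     defined as 0 when nothing is rejected.}
#'   \item{observedPower}{fraction of truly differential features of the
#'     ORIGINAL (pre-filter) dataset that are rejected — features filtered
#'     out count as non-rejected, so the maximum attainable power can be
#'     below 1 after filtering.}
#'   \item{pi0Retained}{null proportion among retained features; an empty
#'     retained set is an error.}
#' }
#'
#' @param rejectedVec logical per-feature rejection indicator (full length).
#' @param isNull logical truth vector, TRUE for null features.
#' @param retainedVec logical per-feature retained indicator (full length).
#' @return numeric scalar in [0, 1].
#' @name simulation-metrics
NULL

#' @rdname simulation-metrics
#' @export
achievedFdr <- function(rejectedVec, isNull) {
    if (length(rejectedVec) != length(isNull))
        stop("'rejectedVec' and 'isNull' lengths differ")
    r <- sum(rejectedVec)
    if (r == 0L) return(0)
    sum(rejectedVec & isNull) / r
}

#' @rdname simulation-metrics
#' @export
observedPower <- function(rejectedVec, isNull) {
    if (length(rejectedVec) != length(isNull))
        stop("'rejectedVec' and 'isNull' lengths differ")
    nAlt <- sum(!isNull)
    if (nAlt == 0L) return(0)
    sum(rejectedVec & !isNull) / nAlt
}

#' @rdname simulation-metrics
#' @export
pi0Retained <- function(retainedVec, isNull) {
    if (length(retainedVec) != length(isNull))
        stop("'retainedVec' and 'isNull' lengths differ")
    k <- sum(retainedVec)
    if (k == 0L) stop("no features retained: retained null proportion undefined")
    sum(retainedVec & isNull) / k
}

# FilterResult for one named filter on one dataset.
.filterFor <- function(name, dataset, isNull, fractionOut, seed) {
    switch(name,
        best = oracleBestFilter(isNull, fractionOut),
        random = randomFilter(length(isNull), fractionOut, seed),
        applyFilter(.filterStatistic(dataset, name), fractionOut,
                    statisticName = name))
}

#' Run the full filter x fraction x FDR-method simulation grid
#'
#' For each of \code{n_datasets} replicates: generate a dataset with
#' [simulateTwoGroupData()] (replicate r uses sub-seed \code{subSeed(seed,
#' r)}), compute per-feature p-values once, then for every configured filter
#' and filtered-out fraction remove that fraction of features (smallest
#' statistic values first) and apply every configured FDR method at level
#' phi to the retained p-values. Features filtered out are never rejected.
#' Per cell the mean and Monte-Carlo standard error of the achieved FDR,
#' observed power and retained null proportion are accumulated.
#'
#' The combination q-value x fold-change filter is rejected up front: after
#' fold-change filtering the p-values no longer span [0, 1], so the q-value
#' null-proportion estimate is degenerate.
#'
#' @param config configuration list as returned by [loadConfig()], or just
#'   its \code{simulation} section.
#' @param verbose logical; log per-replicate progress to stderr.
#' @return data.frame, one row per (filter, fraction_out, fdr_method) cell,
#'   with columns \code{achieved_fdr_mean/se}, \code{power_mean/se},
#'   \code{pi0_retained_mean/se} and \code{n_datasets}. Fully reproducible
#'   from the master seed.
#' @export
runSimulationGrid <- function(config = loadConfig(), verbose = FALSE) {
    sim <- if (!is.null(config$simulation)) config$simulation else config
    if ("qvalue" %in% sim$fdr_methods && "fold_change" %in% sim$filters)
        stop("invalid combination: q-value FDR with the fold-change filter")
    cells <- expand.grid(filter = sim$filters, fraction_out = sim$fractions,
                         fdr_method = sim$fdr_methods,
                         stringsAsFactors = FALSE)
    acc <- array(NA_real_,
                 dim = c(nrow(cells), sim$n_datasets, 3L),
                 dimnames = list(NULL, NULL, c("fdr", "power", "pi0")))
    for (r in seq_len(sim$n_datasets)) {
        rSeed <- subSeed(sim$seed, r)
        gen <- simulateTwoGroupData(sim$m, sim$pi0, sim$nX, sim$nY,
                                    sim$delta, sim$sigma, seed = rSeed)
        p <- pvalues(.testBy(gen$dataset, sim$test))
        for (ci in seq_len(nrow(cells))) {
            keep <- retained(.filterFor(cells$filter[ci], gen$dataset,
                                        gen$isNull, cells$fraction_out[ci],
                                        seed = subSeed(rSeed, ci)))
            fdrRes <- fdrControl(p[keep], cells$fdr_method[ci], sim$phi)
            rej <- logical(sim$m)
            rej[keep] <- rejected(fdrRes)
            acc[ci, r, "fdr"] <- achievedFdr(rej, gen$isNull)
            acc[ci, r, "power"] <- observedPower(rej, gen$isNull)
            acc[ci, r, "pi0"] <- pi0Retained(keep, gen$isNull)
        }
        if (verbose && r %% 50L == 0L)
            message("replicate ", r, "/", sim$n_datasets)
    }
    mse <- function(x) sd(x) / sqrt(length(x))
    data.frame(cells,
               achieved_fdr_mean = apply(acc[, , "fdr", drop = FALSE], 1, mean),
               achieved_fdr_se = apply(acc[, , "fdr", drop = FALSE], 1, mse),
               power_mean = apply(acc[, , "power", drop = FALSE], 1, mean),
               power_se = apply(acc[, , "power", drop = FALSE], 1, mse),
               pi0_retained_mean = apply(acc[, , "pi0", drop = FALSE], 1, mean),
               pi0_retained_se = apply(acc[, , "pi0", drop = FALSE], 1, mse),
               n_datasets = sim$n_datasets)
}

#' Filtering a rejection list after FDR correction
#'
#' Models the practice of prioritizing an already FDR-corrected list by a
#' filter statistic (e.g. shortening a 5%-FDR gene list by fold change for
#' validation): the filter is applied only to the rejected features, keeping
#' the fraction \code{1 - fractionOut} with the largest filter values.
#' Because filtering happens after correction it cannot bias the correction
#' itself, but the shortened list is no longer expected to carry the nominal
#' false-positive percentage — this function recomputes the achieved FDR
#' within the shortened list, alongside the (never larger) power.
#'
#' @param fdrResult a \linkS4class{FdrResult} from the unfiltered analysis.
#' @param filterValuesVec numeric per-feature filter statistic (full length).
#' @param fractionOut fraction of the REJECTED list to drop, in [0, 1).
#' @param isNull logical truth vector.
#' @return list with \code{achievedFdr}, \code{power} and \code{kept} (the
#'   shortened rejection indicator).
#' @export
postFdrFilter <- function(fdrResult, filterValuesVec, fractionOut, isNull) {
    rej <- rejected(fdrResult)
    if (length(filterValuesVec) != length(rej) ||
        length(isNull) != length(rej))
        stop("length mismatch between rejection, filter and truth vectors")
    kept <- rej
    idx <- which(rej)
    if (length(idx) > 0L && fractionOut > 0) {
        sub <- applyFilter(filterValuesVec[idx], fractionOut)
        kept[idx] <- retained(sub)
    }
    list(achievedFdr = achievedFdr(kept, isNull),
         power = observedPower(kept, isNull), kept = kept)
}
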