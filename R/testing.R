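# Per-feature two-sample tests. The pooled (equal-variance) t is the primary
# statistic; the Wilcoxon rank-sum test is provided as a robustness check.

#' Pooled two-sample t test, per feature
#'
#' Equal-variance two-sample t statistic for every feature:
#' T = (mean(X) - mean(Y)) / (Sp * sqrt(1/nX + 1/nY)) with pooled variance
#' Sp^2 = ((nX-1) SX^2 + (nY-1) SY^2) / (nX + nY - 2). Under the null, T is
#' Student t with v = nX + nY - 2 degrees of freedom, and the two-sided
#' p-value is P = 2 * (1 - F0(|T|)) with F0 the central t cdf at v.
#'
#' Features with zero pooled variance have no defined p-value and raise an
#' error naming the first offending feature; constant features must be
#' removed or rejected upstream so that the p-value distribution is never
#' silently distorted.
#'
#' @param dataset a \linkS4class{TwoGroupExperiment} with at least two
#'   samples per group.
#' @return A \linkS4class{TestResult} with \code{testName = "student_t"}.
#' @export
pooledT <- function(dataset) {
    gs <- .groupStats(dataset)
    if (gs$nX < 2L || gs$nY < 2L)
        stop("pooled t test needs at least 2 samples per group")
    v <- gs$nX + gs$nY - 2L
    sp2 <- ((gs$nX - 1L) * gs$varA + (gs$nY - 1L) * gs$varB) / v
    if (any(sp2 <= 0)) {
        bad <- rownames(exprValues(dataset))[which(sp2 <= 0)[1L]]
        stop("zero pooled variance (constant feature): '", bad,
             "'; p-value undefined")
    }
    tt <- (gs$meanA - gs$meanB) / sqrt(sp2 * (1 / gs$nX + 1 / gs$nY))
    p <- 2 * pt(abs(tt), df = v, lower.tail = FALSE)
    new("TestResult", testName = "student_t", statistic = unname(tt),
        df = as.numeric(v), pooledSD = unname(sqrt(sp2)), pvalue = unname(p))
}

# Two-sided p-value for one rank-sum statistic. w = #{(x, y): x > y} (the
# Mann-Whitney count). Exact distribution (pwilcox) when both groups are
# small and there are no ties; normal approximation with continuity and tie
# correction otherwise, mirroring the conventions of stats::wilcox.test.
.wilcoxP <- function(x, y, exactMax = 10L) {
    nX <- length(x); nY <- length(y)
    r <- rank(c(x, y))
    w <- sum(r[seq_len(nX)]) - nX * (nX + 1) / 2
    ties <- any(duplicated(c(x, y)))
    if (!ties && min(nX, nY) <= exactMax) {
        p <- if (w > nX * nY / 2)
            pwilcox(w - 1, nX, nY, lower.tail = FALSE)
        else pwilcox(w, nX, nY)
        return(list(w = w, p = min(1, 2 * p)))
    }
    mu <- nX * nY / 2
    tie <- table(r)
    sigma <- sqrt((nX * nY / 12) *
                  ((nX + nY + 1) - sum(tie^3 - tie) /
                   ((nX + nY) * (nX + nY - 1))))
    z <- w - mu
    z <- z - sign(z) * 0.5  # continuity correction
    if (sigma == 0) return(list(w = w, p = 1))
    list(w = w, p = min(1, 2 * pnorm(abs(z / sigma), lower.tail = FALSE)))
}

#' Wilcoxon rank-sum test, per feature
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test per feature: exact null
#' distribution when min(nX, nY) <= 10 and the feature has no ties, normal
#' approximation with continuity (and tie) correction otherwise. Ties are
#' handled by midranks.
#'
#' @inheritParams pooledT
#' @return A \linkS4class{TestResult} with \code{testName = "wilcoxon"}; the
#'   statistic is the Mann-Whitney count.
#' @importFrom stats pwilcox
#' @export
wilcoxonTest <- function(dataset) {
    v <- exprValues(dataset)
    g <- groupLabels(dataset)
    if (min(table(g)) < 2L)
        stop("Wilcoxon test needs at least 2 samples per group")
    ia <- which(g == "A"); ib <- which(g == "B")
    res <- apply(v, 1L, function(z) unlist(.wilcoxP(z[ia], z[ib])))
    new("TestResult", testName = "wilcoxon", statistic = unname(res["w", ]),
        df = NA_real_, pooledSD = numeric(0), pvalue = unname(res["p", ]))
}

.testBy <- function(dataset, method = c("t", "wilcoxon")) {
    switch(match.arg(method), t = pooledT(dataset),
           wilcoxon = wilcoxonTest(dataset))
}

#' Permute the group labels of a dataset
#'
#' Returns a dataset with identical expression values and a uniformly random
#' reassignment of samples to groups, preserving the group sizes nX and nY.
#' This breaks any association between group membership and expression, so
#' per-feature statistics computed on the permuted dataset estimate their
#' null law — the building block of the FDR-bias test.
#'
#' @param dataset a \linkS4class{TwoGroupExperiment}.
#' @param seed integer seed; the same seed reproduces the same assignment.
#' @return A \linkS4class{TwoGroupExperiment}.
#' @export
permuteGroupLabels <- function(dataset, seed) {
    g <- groupLabels(dataset)
    perm <- withSeed(seed, sample(length(g)))
    TwoGroupExperiment(exprValues(dataset), group = as.character(g)[perm])
}

#' @rdname TestResult-accessors
#' @export
setMethod("pvalues", "TestResult", function(x) x@pvalue)

#' @rdname TestResult-accessors
#' @export
setMethod("testStatistics", "TestResult", function(x) x@statistic)

setMethod("show", "TestResult", function(object) {
    cat(sprintf("TestResult '%s': %d features%s; median p = %.3g\n",
                object@testName, length(object@pvalue),
                if (!is.na(object@df)) sprintf(", df = %g", object@df) else "",
                stats::median(object@pvalue)))
})
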