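#' @import methods
#' @importFrom stats integrate pnorm qnorm dnorm pt qt dt dchisq pchisq rchisq
#'   rnorm runif uniroot p.adjust ks.test var sd rbinom
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Two-group expression experiment
#'
#' A \linkS4class{SummarizedExperiment} holding a single assay \code{"exprs"}
#' (a numeric feature-by-sample matrix of processed, log-scale expression
#' values) together with a two-level group factor in
#' \code{colData(x)$group} (levels \code{"A"} and \code{"B"}).  All filter
#' statistics, tests and the FDR-bias test consume this class.  Values are
#' assumed complete: missing entries are an input error, never imputed.
#'
#' @slot .  Inherits all slots from \code{SummarizedExperiment}.
#'
#' @seealso [TwoGroupExperiment()] for the constructor,
#'   [readExpressionMatrix()] to build one from a tab-delimited file.
#' @export
setClass("TwoGroupExperiment", contains = "SummarizedExperiment")

.validTwoGroupExperiment <- function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(v))
            msg <- c(msg, "assay 'exprs' must be numeric")
        if (anyNA(v)) {
            bad <- which(is.na(v), arr.ind = TRUE)[1L, ]
            msg <- c(msg, sprintf(
                "missing value in 'exprs' at feature '%s', sample '%s'",
                rownames(object)[bad[1L]], colnames(object)[bad[2L]]))
        }
        if (nrow(v) < 1L)
            msg <- c(msg, "at least one feature is required")
    }
    g <- SummarizedExperiment::colData(object)$group
    if (is.null(g))
        msg <- c(msg, "colData column 'group' is required")
    else {
        if (!is.factor(g) || !identical(levels(g), c("A", "B")))
            msg <- c(msg, "'group' must be a factor with levels A, B")
        if (anyNA(g)) {
            bad <- colnames(object)[which(is.na(g))]
            msg <- c(msg, sprintf("sample(s) without group label: %s",
                                  paste(bad, collapse = ", ")))
        } else if (any(table(g) == 0L))
            msg <- c(msg, "both groups must be non-empty")
    }
    if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicate feature id: '%s'",
                              rownames(object)[anyDuplicated(rownames(object))]))
    if (is.null(msg)) TRUE else msg
}
setValidity("TwoGroupExperiment", .validTwoGroupExperiment)

#' Per-feature filter result
#'
#' The outcome of applying a filter statistic W and a retained-fraction cut to
#' a dataset: the statistic values W(Z_i), the derived threshold w, the
#' retained indicator R_i (TRUE when a feature is kept, i.e. W(Z_i) >= w up to
#' the stable tie rule) and the retained fraction gamma.
#'
#' @slot statisticName character; one of \code{"signal"}, \code{"fold_change"},
#'   \code{"variance"}, \code{"best"}, \code{"random"}.
#' @slot values numeric; per-feature filter statistic (data-scale units, or
#'   variance units for the variance filter; NA for the random filter, which
#'   has no statistic).
#' @slot threshold numeric(1); the statistic value at the cut.
#' @slot retained logical; R_i, TRUE for features kept in the analysis.
#' @slot gamma numeric(1); retained fraction in (0, 1].
#' @export
setClass("FilterResult",
    representation(statisticName = "character", values = "numeric",
                   threshold = "numeric", retained = "logical",
                   gamma = "numeric"))

setValidity("FilterResult", function(object) {
    msg <- NULL
    if (length(object@retained) != length(object@values))
        msg <- c(msg, "'values' and 'retained' lengths differ")
    if (object@gamma <= 0 || object@gamma > 1)
        msg <- c(msg, "'gamma' must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Per-feature two-sample test result
#'
#' @slot testName character; \code{"student_t"} or \code{"wilcoxon"}.
#' @slot statistic numeric; per-feature test statistic (T, or the rank-sum W).
#' @slot df numeric(1); degrees of freedom v = nX + nY - 2 (NA for Wilcoxon).
#' @slot pooledSD numeric; per-feature pooled standard deviation Sp (length 0
#'   for Wilcoxon).
#' @slot pvalue numeric; two-sided p-values in [0, 1].
#' @export
setClass("TestResult",
    representation(testName = "character", statistic = "numeric",
                   df = "numeric", pooledSD = "numeric", pvalue = "numeric"))

setValidity("TestResult", function(object) {
    p <- object@pvalue
    if (length(p) != length(object@statistic))
        return("'statistic' and 'pvalue' lengths differ")
    if (any(p < 0 | p > 1, na.rm = TRUE))
        return("p-values must lie in [0, 1]")
    TRUE
})

#' Multiple-testing (FDR) procedure result
#'
#' All step-up procedures share the representation: a rejection threshold
#' u* on the p-value scale with rejected_i <=> P_i <= u*.  When nothing is
#' rejected, u* = 0 and the rejection set is empty.
#'
#' @slot method character; one of \code{"bh"}, \code{"by"}, \code{"abh"},
#'   \code{"qvalue"}, \code{"bonferroni"}.
#' @slot phi numeric(1); nominal FDR (or FWER) level in (0, 1).
#' @slot uStar numeric(1); rejection threshold on the p-value scale.
#' @slot rejected logical; per-feature rejection indicator.
#' @slot pi0Hat numeric(1); estimated null proportion (abh, qvalue; NA else).
#' @slot qvalues numeric; per-feature q-values (qvalue method only, else
#'   length 0).
#' @export
setClass("FdrResult",
    representation(method = "character", phi = "numeric", uStar = "numeric",
                   rejected = "logical", pi0Hat = "numeric",
                   qvalues = "numeric"))

setValidity("FdrResult", function(object) {
    msg <- NULL
    if (object@phi <= 0 || object@phi >= 1)
        msg <- c(msg, "'phi' must be in (0, 1)")
    if (object@uStar < 0 || object@uStar > 1)
        msg <- c(msg, "'uStar' must be in [0, 1]")
    if (!is.na(object@pi0Hat) && (object@pi0Hat <= 0 || object@pi0Hat > 1))
        msg <- c(msg, "'pi0Hat' must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Report of the permutation-based FDR-bias test
#'
#' @slot filterName character; filter statistic under test.
#' @slot fractionOut numeric(1); fraction of features filtered out.
#' @slot testMethod character; per-feature test used (\code{"t"} or
#'   \code{"wilcoxon"}).
#' @slot mode character; per-round uniformity check, \code{"ks"} (one-sided
#'   Kolmogorov-Smirnov) or \code{"bh"} (minimum BH-adjusted p-value).
#' @slot nPermutations integer(1); number of permutation rounds N0.
#' @slot permPvalues numeric; the round-level uniformity p-values q_1..q_N0.
#' @slot finalPvalue numeric(1); meta-level KS p-value comparing Gq to U[0,1].
#' @slot seed integer(1); master seed, making the report reproducible.
#' @export
setClass("BiasTestReport",
    representation(filterName = "character", fractionOut = "numeric",
                   testMethod = "character", mode = "character",
                   nPermutations = "integer", permPvalues = "numeric",
                   finalPvalue = "numeric", seed = "integer"))

setValidity("BiasTestReport", function(object) {
    msg <- NULL
    if (length(object@permPvalues) != object@nPermutations)
        msg <- c(msg, "length(permPvalues) must equal nPermutations")
    if (any(object@permPvalues < 0 | object@permPvalues > 1))
        msg <- c(msg, "round p-values must lie in [0, 1]")
    if (object@finalPvalue < 0 || object@finalPvalue > 1)
        msg <- c(msg, "'finalPvalue' must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Distributional model for the two-group design
#'
#' Parameterizes the Gaussian two-group sampling model behind both the
#' analytic (theory) results and the simulation engine: nX and nY samples per
#' group with common within-group standard deviation sigma; differential
#' features have a mean difference Delta = delta * sigma * sqrt(1/nX + 1/nY),
#' i.e. delta is the noncentrality parameter of the pooled t statistic with
#' v = nX + nY - 2 degrees of freedom; pi0 is the null proportion.
#'
#' @slot nX,nY integer(1); group sizes.
#' @slot sigma numeric(1); common within-group standard deviation (> 0).
#' @slot delta numeric(1); t noncentrality under the alternative (delta = 0
#'   recovers the null).
#' @slot pi0 numeric(1); null proportion in (0, 1].
#' @export
setClass("ModelSpec",
    representation(nX = "integer", nY = "integer", sigma = "numeric",
                   delta = "numeric", pi0 = "numeric"))

setValidity("ModelSpec", function(object) {
    msg <- NULL
    if (object@nX < 2L || object@nY < 2L)
        msg <- c(msg, "group sizes must be at least 2")
    if (object@nX + object@nY - 2L < 1L)
        msg <- c(msg, "degrees of freedom must be >= 1")
    if (object@sigma <= 0) msg <- c(msg, "'sigma' must be positive")
    if (object@pi0 <= 0 || object@pi0 > 1)
        msg <- c(msg, "'pi0' must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
})
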