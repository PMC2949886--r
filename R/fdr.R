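# Multiple-testing procedures. Each procedure is available twice: through
# its classical formulation (sorting/adjusting p-values, via stats::p.adjust
# where base R provides it) and through the unified empirical-cdf step-up
# formulation u* = max{ u : g(u, phi) <= Gm(u) }, where Gm is the empirical
# cdf of the p-values. The two routes are asserted equal in the test suite.

#' Empirical cdf of a p-value vector
#'
#' Right-continuous step function Gm(u) = #\{P_i <= u\} / m on [0, 1].
#'
#' @param pvalues numeric vector of p-values in [0, 1]; must be non-empty.
#' @return a function of \code{u} (vectorized), with Gm(1) = 1.
#' @export
empiricalCdf <- function(pvalues) {
    if (length(pvalues) == 0L) stop("empty p-value vector")
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues))
        stop("p-values must lie in [0, 1]")
    sp <- sort(pvalues)
    m <- length(sp)
    function(u) findInterval(u, sp) / m
}

.newFdrResult <- function(method, phi, uStar, rejected,
                          pi0Hat = NA_real_, qvalues = numeric(0)) {
    new("FdrResult", method = method, phi = phi, uStar = uStar,
        rejected = rejected, pi0Hat = pi0Hat, qvalues = qvalues)
}

.checkPhi <- function(phi) {
    if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi >= 1)
        stop("'phi' must be a single value in (0, 1)")
}

#' Generic empirical-cdf step-up procedure
#'
#' Selects all p-values P_i <= u*, where
#' u* = max\{ u in [0,1] : g(u, phi) <= Gm(u) \} and Gm is the empirical cdf
#' of the p-values. Since Gm only jumps at observed p-values and g is
#' nondecreasing in u, the maximum is attained at an order statistic, so the
#' search is over the sorted p-values. With g(u, phi) = u/phi this is the
#' Benjamini-Hochberg step-up; other g forms give the adaptive BH and
#' Benjamini-Yekutieli procedures.
#'
#' @param pvalues numeric p-values in [0, 1].
#' @param g function(u, phi) -> numeric, nondecreasing in u.
#' @param phi nominal FDR level in (0, 1).
#' @param method label stored in the result.
#' @return A \linkS4class{FdrResult}; when no order statistic qualifies,
#'   \code{uStar = 0} and nothing is rejected.
#' @export
stepUpGeneric <- function(pvalues, g, phi, method = "generic") {
    .checkPhi(phi)
    Gm <- empiricalCdf(pvalues)  # validates input
    sp <- sort(pvalues)
    ok <- g(sp, phi) <= Gm(sp)
    if (any(ok)) {
        uStar <- max(sp[ok])
        rej <- pvalues <= uStar
    } else {
        uStar <- 0
        rej <- rep(FALSE, length(pvalues))
    }
    .newFdrResult(method, phi, uStar, rej)
}

#' FDR and FWER procedures
#'
#' Classical implementations of the procedures the step-up formulation
#' unifies:
#' \describe{
#'   \item{fdrBH}{Benjamini-Hochberg step-up: reject H0i whenever
#'     P_(i) <= i * phi / m; equivalent to g(u, phi) = u / phi.}
#'   \item{fdrBY}{Benjamini-Yekutieli: BH at level phi / c(m) with
#'     c(m) = sum_{j=1}^m 1/j, valid under arbitrary dependence.}
#'   \item{fdrABH}{adaptive BH: BH at level phi / pi0_hat, with the null
#'     proportion estimated by the lowest-slope estimator (default) or
#'     Storey's lambda estimator.}
#'   \item{fdrQvalue}{Storey's q-value procedure: pi0_hat =
#'     #\{P_i > lambda\} / (m (1 - lambda)); q_i is the minimum of
#'     pi0_hat * m * P_(j) / j over j with P_(j) >= P_i; reject q_i <= phi.
#'     Requires p-values spanning the whole unit interval: when
#'     max(pvalues) < lambda the pi0 estimate is degenerate and the
#'     procedure refuses (this is why the q-value method cannot be combined
#'     with the fold-change filter, which empties the upper p-value range).}
#'   \item{fdrBonferroni}{Bonferroni FWER control: reject P_i <= phi / m
#'     (shown for comparison alongside the FDR procedures).}
#' }
#'
#' @param pvalues numeric p-values in [0, 1].
#' @param phi nominal level in (0, 1).
#' @return A \linkS4class{FdrResult}.
#' @name fdr-procedures
NULL

#' @rdname fdr-procedures
#' @export
fdrBH <- function(pvalues, phi) {
    .checkPhi(phi)
    empiricalCdf(pvalues)  # input validation
    adj <- p.adjust(pvalues, method = "BH")
    rej <- adj <= phi
    .newFdrResult("bh", phi, if (any(rej)) max(pvalues[rej]) else 0, rej)
}

#' @rdname fdr-procedures
#' @export
fdrBY <- function(pvalues, phi) {
    .checkPhi(phi)
    empiricalCdf(pvalues)
    adj <- p.adjust(pvalues, method = "BY")
    rej <- adj <= phi
    .newFdrResult("by", phi, if (any(rej)) max(pvalues[rej]) else 0, rej)
}

#' Lowest-slope estimator of the null proportion
#'
#' The estimator of Benjamini & Hochberg (2000): with ordered p-values
#' P_(1) <= ... <= P_(m), compute slopes S_i = (1 - P_(i)) / (m + 1 - i) and
#' scan from i = 2 until the first decrease S_i < S_(i-1); then
#' pi0_hat = min(1, (1/S_i + 1) / m), clipped to (0, 1]. If the slopes never
#' decrease the last slope is used.
#'
#' @param pvalues numeric p-values in [0, 1]; length >= 2.
#' @return estimated null proportion in (0, 1].
#' @export
estimatePi0LSL <- function(pvalues) {
    m <- length(pvalues)
    if (m < 2L) stop("need at least 2 p-values")
    sp <- sort(pvalues)
    s <- (1 - sp) / (m + 1 - seq_len(m))
    dec <- which(diff(s) < 0)
    i <- if (length(dec)) dec[1L] + 1L else m
    pi0 <- (1 / s[i] + 1) / m
    min(1, max(pi0, 1 / m))
}

#' Storey's lambda estimator of the null proportion
#'
#' pi0_hat = #\{P_i > lambda\} / (m (1 - lambda)), clipped to (0, 1].
#'
#' @param pvalues numeric p-values in [0, 1].
#' @param lambda tuning parameter in [0, 1).
#' @return estimated null proportion in (0, 1].
#' @export
estimatePi0Storey <- function(pvalues, lambda = 0.5) {
    if (lambda < 0 || lambda >= 1) stop("'lambda' must lie in [0, 1)")
    m <- length(pvalues)
    pi0 <- sum(pvalues > lambda) / (m * (1 - lambda))
    min(1, max(pi0, 1 / m))
}

#' @rdname fdr-procedures
#' @param pi0Estimator for [fdrABH()]: \code{"lsl"} (lowest slope, default)
#'   or \code{"storey"}.
#' @export
fdrABH <- function(pvalues, phi, pi0Estimator = c("lsl", "storey")) {
    .checkPhi(phi)
    empiricalCdf(pvalues)
    pi0 <- switch(match.arg(pi0Estimator),
                  lsl = estimatePi0LSL(pvalues),
                  storey = estimatePi0Storey(pvalues))
    adj <- p.adjust(pvalues, method = "BH")
    rej <- adj <= min(1, phi / pi0)
    .newFdrResult("abh", phi, if (any(rej)) max(pvalues[rej]) else 0, rej,
                  pi0Hat = pi0)
}

#' @rdname fdr-procedures
#' @param lambda for [fdrQvalue()]: pi0 tuning parameter in [0, 1)
#'   (default 0.5).
#' @export
fdrQvalue <- function(pvalues, phi, lambda = 0.5) {
    .checkPhi(phi)
    empiricalCdf(pvalues)
    if (max(pvalues) < lambda)
        stop("q-value method refused: max(pvalues) = ",
             format(max(pvalues), digits = 3), " < lambda = ", lambda,
             "; the pi0 estimate is degenerate because the p-values do not ",
             "span [0, 1] (e.g. after fold-change filtering)")
    pi0 <- estimatePi0Storey(pvalues, lambda)
    m <- length(pvalues)
    ord <- order(pvalues, decreasing = TRUE)
    q <- numeric(m)
    q[ord] <- cummin(pi0 * m * pvalues[ord] / rank(pvalues, ties.method = "max")[ord])
    q <- pmin(q, 1)
    rej <- q <= phi
    .newFdrResult("qvalue", phi, if (any(rej)) max(pvalues[rej]) else 0, rej,
                  pi0Hat = pi0, qvalues = q)
}

#' @rdname fdr-procedures
#' @export
fdrBonferroni <- function(pvalues, phi) {
    .checkPhi(phi)
    empiricalCdf(pvalues)
    m <- length(pvalues)
    rej <- pvalues <= phi / m
    .newFdrResult("bonferroni", phi, phi / m, rej)
}

#' Run an FDR procedure by name
#'
#' @param pvalues numeric p-values in [0, 1].
#' @param method one of \code{"bh"}, \code{"by"}, \code{"abh"},
#'   \code{"qvalue"}, \code{"bonferroni"}.
#' @param phi nominal level in (0, 1).
#' @param ... passed through to the procedure (e.g. \code{lambda}).
#' @return A \linkS4class{FdrResult}.
#' @export
fdrControl <- function(pvalues, method, phi, ...) {
    switch(method,
        bh = fdrBH(pvalues, phi),
        by = fdrBY(pvalues, phi),
        abh = fdrABH(pvalues, phi, ...),
        qvalue = fdrQvalue(pvalues, phi, ...),
        bonferroni = fdrBonferroni(pvalues, phi),
        stop("unknown FDR method: '", method, "'"))
}

#' The g threshold functions of the step-up formulation
#'
#' Returns the function g(u, phi) whose step-up procedure (see
#' [stepUpGeneric()]) reproduces the named method: \code{u/phi} for BH,
#' \code{pi0 * u/phi} for adaptive BH, and \code{(u/phi) * c(m)} with the
#' harmonic sum c(m) for BY.
#'
#' @param method \code{"bh"}, \code{"abh"} or \code{"by"}.
#' @param m number of hypotheses (needed for BY).
#' @param pi0 null proportion (needed for aBH).
#' @return function(u, phi).
#' @export
gForm <- function(method, m = NULL, pi0 = NULL) {
    switch(method,
        bh = function(u, phi) u / phi,
        abh = function(u, phi) pi0 * u / phi,
        by = function(u, phi) (u / phi) * sum(1 / seq_len(m)),
        stop("no g-form for method '", method, "'"))
}

#' @rdname FdrResult-accessors
#' @export
setMethod("rejected", "FdrResult", function(x) x@rejected)

#' @rdname FdrResult-accessors
#' @export
setMethod("uStar", "FdrResult", function(x) x@uStar)

#' @rdname FdrResult-accessors
#' @export
setMethod("pi0Hat", "FdrResult", function(x) x@pi0Hat)

#' @rdname FdrResult-accessors
#' @export
setMethod("qvalues", "FdrResult", function(x) x@qvalues)

setMethod("show", "FdrResult", function(object) {
    cat(sprintf("FdrResult '%s' at phi = %g: %d of %d rejected (u* = %.4g)%s\n",
                object@method, object@phi, sum(object@rejected),
                length(object@rejected), object@uStar,
                if (!is.na(object@pi0Hat))
                    sprintf(", pi0_hat = %.3f", object@pi0Hat) else ""))
})
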