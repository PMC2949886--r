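# Analytic/numerical distribution theory for the pooled t statistic after
# filtering. The model structure makes everything one-dimensional: with
# c2 = 1/nX + 1/nY, the group-mean difference D = mean(X) - mean(Y) is
# Normal(Delta, sigma^2 c2) and is independent of the pooled variance
# Sp^2 = sigma^2 * Q / v with Q ~ chi^2_v, so T = D / (Sp sqrt(c2)) and all
# post-filter laws are integrals over Q of closed-form Gaussian expressions:
#   fold-change filter: condition |D| >= w;
#   variance filter:    condition Sp^2 >= w on the pooled within-group
#                       variance, i.e. Q >= v w / sigma^2 (the law of Sp^2 is
#                       the same under null and alternative, so this
#                       conditioning never enriches for effects -- the
#                       analytic counterpart of the variance filter's
#                       FDR-neutrality; the empirical filter cuts on the
#                       overall variance S_Z^2, whose extra D^2/c2 term adds
#                       only a mild association at small v);
#   signal filter:      M = (mean(X)+mean(Y))/2 is independent of (D, Sp)
#                       when nX = nY, so conditioning changes nothing.

#' Construct a ModelSpec
#'
#' @param nX,nY group sizes (>= 2 each).
#' @param sigma common within-group standard deviation (> 0).
#' @param delta noncentrality parameter of the t statistic under the
#'   alternative; the group-mean difference is the derived quantity
#'   \code{Delta = delta * sigma * sqrt(1/nX + 1/nY)}. \code{delta = 0}
#'   gives the null model.
#' @param pi0 null proportion in (0, 1].
#' @return A \linkS4class{ModelSpec}.
#' @examples
#' modelSpec()  # the default study model: v = 8, delta = 1, pi0 = 0.8
#' @export
modelSpec <- function(nX = 5L, nY = 5L, sigma = 1, delta = 1, pi0 = 0.8) {
    new("ModelSpec", nX = as.integer(nX), nY = as.integer(nY),
        sigma = sigma, delta = delta, pi0 = pi0)
}

setMethod("show", "ModelSpec", function(object) {
    cat(sprintf(
        "ModelSpec: nX = %d, nY = %d (v = %d), sigma = %g, delta = %g, pi0 = %g\n",
        object@nX, object@nY, object@nX + object@nY - 2L, object@sigma,
        object@delta, object@pi0))
})

# Shared derived constants.
.modelConsts <- function(model) {
    v <- model@nX + model@nY - 2L
    c2 <- 1 / model@nX + 1 / model@nY
    list(v = v, c2 = c2, n = model@nX + model@nY,
         sdD = model@sigma * sqrt(c2),
         Delta = model@delta * model@sigma * sqrt(c2))
}

# Pr{D <= a, |D| >= b} for D ~ Normal(mean, sd); b <= 0 means no constraint.
# Vectorized over a and b jointly (integrate() passes vectors).
.pTailTrunc <- function(a, b, mean, sd) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    out <- pnorm(pmin(a, -b), mean, sd) +
        pmax(0, pnorm(a, mean, sd) - pnorm(b, mean, sd))
    noB <- b <= 0
    out[noB] <- pnorm(a[noB], mean, sd)
    out
}

# Piecewise adaptive quadrature over q in (0, Inf) with interior breakpoints
# at the integrand's kinks. abs.tol 1e-10 per piece keeps the composed error
# comfortably below the documented 1e-8.
.intQ <- function(f, breaks = numeric(0)) {
    pts <- sort(unique(c(0, breaks[is.finite(breaks) & breaks > 0], Inf)))
    total <- 0
    for (i in seq_len(length(pts) - 1L))
        total <- total + integrate(f, pts[i], pts[i + 1L],
                                   rel.tol = 1e-10, abs.tol = 1e-10,
                                   subdivisions = 1000L)$value
    total
}

# Retention probability Pr{W >= w | Delta} under the model component with
# group-mean difference Delta. For the signal filter the law of
# M ~ Normal(0, sdD/2) is the same for null and alternative components
# (group means are centered at +/- Delta/2).
.retentionProb <- function(model, filter, w, Delta) {
    k <- .modelConsts(model)
    if (filter == "none" || w == -Inf) return(1)
    switch(filter,
        signal = pnorm(w, 0, k$sdD / 2, lower.tail = FALSE),
        fold_change = {
            if (w <= 0) 1
            else 1 - (pnorm(w, Delta, k$sdD) - pnorm(-w, Delta, k$sdD))
        },
        variance = {
            if (w <= 0) 1
            else pchisq(k$v * w / model@sigma^2, k$v, lower.tail = FALSE)
        },
        stop("unknown filter: '", filter, "'"))
}

# Unnormalized Pr{T <= t, W >= w | Delta} for scalar t.
.condTNum <- function(model, filter, w, t, Delta) {
    k <- .modelConsts(model)
    s <- function(q) model@sigma * sqrt(q / k$v)
    a <- function(q) t * s(q) * sqrt(k$c2)  # D <= a(q) <=> T <= t given q
    if (filter %in% c("none", "signal") || w <= 0 && filter != "signal" ||
        w == -Inf) {
        f <- function(q) dchisq(q, k$v) * pnorm(a(q), Delta, k$sdD)
        # signal: M independent of (D, Sp), so the joint factorizes
        fac <- if (filter == "signal")
            .retentionProb(model, "signal", w, Delta) else 1
        return(.intQ(f) * fac)
    }
    if (filter == "fold_change") {
        f <- function(q) dchisq(q, k$v) * .pTailTrunc(a(q), w, Delta, k$sdD)
        qKink <- if (t != 0) k$v * w^2 / (model@sigma^2 * k$c2 * t^2) else Inf
        return(.intQ(f, breaks = qKink))
    }
    if (filter == "variance") {
        q0 <- k$v * w / model@sigma^2
        f <- function(q) dchisq(q, k$v) * pnorm(a(q), Delta, k$sdD)
        return(.intQ(f, breaks = q0) -
                   integrate(f, 0, q0, rel.tol = 1e-10, abs.tol = 1e-10,
                             subdivisions = 1000L)$value)
    }
    stop("unknown filter: '", filter, "'")
}

#' Conditional cdf of the t statistic after filtering
#'
#' Evaluates F_T^W(t) = Pr\{T <= t, W >= w\} / Pr\{W >= w\} under the
#' two-group Gaussian model, by adaptive quadrature over the pooled-variance
#' mixing variable with analytic Gaussian tail forms over the group-mean
#' difference (absolute tolerance 1e-8). With \code{w} at or below the
#' statistic's minimum (or \code{filter = "none"}) the unconditional
#' (non)central t cdf is recovered; the signal filter (requires nX = nY) is
#' independent of (D, Sp), so its conditional cdf equals the unconditional
#' one for every threshold.
#'
#' @param model a \linkS4class{ModelSpec}; its \code{delta} selects the null
#'   (0) or alternative component.
#' @param filter \code{"fold_change"}, \code{"variance"}, \code{"signal"} or
#'   \code{"none"}.
#' @param w filter threshold on the statistic scale.
#' @param t numeric vector of evaluation points.
#' @return data.frame with columns \code{t} and \code{cdf}; attributes
#'   \code{filter} and \code{w} record the conditioning.
#' @export
conditionalTCdf <- function(model, filter, w, t) {
    stopifnot(is(model, "ModelSpec"))
    if (filter == "signal" && model@nX != model@nY)
        stop("signal-filter theory requires nX = nY (independence of the ",
             "average signal from the test statistic)")
    Delta <- .modelConsts(model)$Delta
    pRet <- .retentionProb(model, filter, w, Delta)
    if (pRet < 1e-12)
        stop("conditioning probability below 1e-12: the filter removes ",
             "essentially everything")
    cdf <- vapply(t, function(ti)
        .condTNum(model, filter, w, ti, Delta) / pRet, numeric(1L))
    structure(data.frame(t = t, cdf = pmin(1, pmax(0, cdf))),
              filter = filter, w = w)
}

#' Threshold implied by a filtered-out fraction under the model
#'
#' Solves F_W(w) = fractionOut under the MIXTURE law of the filter statistic
#' W: pi0 parts null component (mean difference 0) and 1 - pi0 parts
#' alternative component (mean difference +/- Delta; all three filter laws
#' are symmetric in the effect sign), mirroring how the empirical pipeline
#' cuts a pooled statistic vector at a per-dataset quantile.
#'
#' @inheritParams conditionalTCdf
#' @param fractionOut fraction filtered out, in [0, 1).
#' @return the threshold w (\code{-Inf}/0 when \code{fractionOut = 0}).
#' @export
solveFilterThreshold <- function(model, filter, fractionOut) {
    if (fractionOut < 0 || fractionOut >= 1)
        stop("'fractionOut' must lie in [0, 1)")
    k <- .modelConsts(model)
    if (fractionOut == 0)
        return(if (filter == "signal") -Inf else 0)
    if (filter == "variance")  # Sp^2 ~ sigma^2 chi^2_v / v for every feature
        return(model@sigma^2 * qchisq(fractionOut, k$v) / k$v)
    mixCdf <- function(w)
        model@pi0 * (1 - .retentionProb(model, filter, w, 0)) +
        (1 - model@pi0) * (1 - .retentionProb(model, filter, w, k$Delta))
    lower <- if (filter == "signal") -10 * k$sdD else 0
    upper <- if (filter == "signal") 10 * k$sdD else {
        u <- k$sdD
        while (mixCdf(u) < fractionOut) u <- u * 2
        u
    }
    uniroot(function(w) mixCdf(w) - fractionOut, c(lower, upper),
            tol = 1e-12)$root
}

# Conditional density of T (unnormalized by retention prob): analytic lower
# integration bound in q replaces the conditioning indicator.
.condTDens <- function(model, filter, w, t, Delta) {
    k <- .modelConsts(model)
    qMin <- if (filter %in% c("none", "signal") || w <= 0) 0
        else if (filter == "fold_change") {
            if (t == 0) return(0)
            k$v * w^2 / (model@sigma^2 * k$c2 * t^2)
        } else if (filter == "variance")
            k$v * w / model@sigma^2
        else stop("unknown filter: '", filter, "'")
    f <- function(q) {
        s <- model@sigma * sqrt(q / k$v)
        dchisq(q, k$v) * s * sqrt(k$c2) *
            dnorm(t * s * sqrt(k$c2), Delta, k$sdD)
    }
    if (!is.finite(qMin)) return(0)
    # signal: M independent of (D, Sp), so the joint factorizes
    fac <- if (filter == "signal") .retentionProb(model, "signal", w, Delta)
           else 1
    fac * integrate(f, qMin, Inf, rel.tol = 1e-10, abs.tol = 1e-10,
                    subdivisions = 1000L)$value
}

#' Density of p-values after filtering
#'
#' Maps the conditional law of T through the two-sided p-value transform
#' P = 2 (1 - F0(|T|)) (F0 the central t cdf at v degrees of freedom) and
#' returns the p-value density of the requested mixture component after
#' filtering. The threshold w is solved from \code{fractionOut} under the
#' mixture law of the filter statistic (pi0 null + (1 - pi0) alternative
#' with effect signs +/- Delta equally likely), mirroring how the empirical
#' pipeline cuts a pooled statistic vector. With no filtering the null
#' density is identically 1 (uniform).
#'
#' @inheritParams conditionalTCdf
#' @param fractionOut fraction of features filtered out, in [0, 1).
#' @param pGrid numeric grid in (0, 1] at which to evaluate the density.
#' @param component \code{"null"} (delta = 0) or \code{"alternative"}
#'   (the +/- delta mixture of the model).
#' @return data.frame with columns \code{p} and \code{density}; attributes
#'   \code{w} and \code{component}.
#' @export
pvalueDensityAfterFilter <- function(model, filter, fractionOut, pGrid,
                                     component = c("null", "alternative")) {
    component <- match.arg(component)
    stopifnot(is(model, "ModelSpec"))
    if (any(pGrid <= 0 | pGrid > 1))
        stop("'pGrid' values must lie in (0, 1]")
    k <- .modelConsts(model)
    w <- solveFilterThreshold(model, filter, fractionOut)
    Delta <- if (component == "null") 0 else k$Delta
    pRet <- .retentionProb(model, filter, w, Delta)
    if (pRet < 1e-12)
        stop("conditioning probability below 1e-12")
    dens <- vapply(pGrid, function(p) {
        tp <- qt(1 - p / 2, df = k$v)
        # density of the +/-Delta mixture at +/-tp collapses to the
        # single-Delta symmetrized form since f_{-Delta}(t) = f_Delta(-t)
        (.condTDens(model, filter, w, tp, Delta) +
         .condTDens(model, filter, w, -tp, Delta)) /
            (2 * dt(tp, df = k$v)) / pRet
    }, numeric(1L))
    structure(data.frame(p = pGrid, density = dens),
              w = w, component = component, filter = filter)
}

# Pr{P <= u | component, retained}: the post-filter p-value cdf.
.pvalueCdfAfterFilter <- function(model, filter, w, u, Delta, pRet) {
    k <- .modelConsts(model)
    vapply(u, function(ui) {
        if (ui <= 0) return(0)
        if (ui >= 1) return(1)
        tu <- qt(1 - ui / 2, df = k$v)
        num <- .condTNum(model, filter, w, -tu, Delta) +
            (pRet - .condTNum(model, filter, w, tu, Delta))
        min(1, max(0, num / pRet))
    }, numeric(1L))
}

#' Asymptotic BH operating point and power after filtering
#'
#' Solves the large-m Benjamini-Hochberg operating point after filtering:
#' the largest u in [0, 1] where the mixture p-value cdf
#' GmW(u) = pi0W G0W(u) + (1 - pi0W) GaW(u) still satisfies the step-up
#' condition GmW(u) >= u / phi — equivalently the intersection
#' GaW(u) = [u/phi - pi0W G0W(u)] / (1 - pi0W). pi0W is the post-filter null
#' proportion implied by the model and the threshold solved from
#' \code{fractionOut}. The root is located by bracketing and bisection to
#' 1e-10. Power is GaW at the operating point; when no intersection above
#' u = 0 exists, power 0 and uStar 0 are returned (a valid operating point,
#' not an error).
#'
#' @inheritParams pvalueDensityAfterFilter
#' @param phi nominal FDR level in (0, 1).
#' @return list with \code{uStar}, \code{power}, \code{pi0W} and \code{w}.
#' @export
analyticPowerAfterFilter <- function(model, filter, fractionOut, phi) {
    .checkPhi(phi)
    stopifnot(is(model, "ModelSpec"))
    if (model@pi0 >= 1)
        stop("power analysis needs pi0 < 1 (some alternative features)")
    k <- .modelConsts(model)
    w <- solveFilterThreshold(model, filter, fractionOut)
    pNull <- .retentionProb(model, filter, w, 0)
    pAlt <- .retentionProb(model, filter, w, k$Delta)
    pi0W <- model@pi0 * pNull / (model@pi0 * pNull +
                                     (1 - model@pi0) * pAlt)
    noFilter <- filter == "none" || fractionOut == 0 || filter == "signal"
    G0W <- if (noFilter) function(u) u
        else function(u) .pvalueCdfAfterFilter(model, filter, w, u, 0, pNull)
    GaW <- if (noFilter) function(u) {
        tu <- qt(1 - u / 2, df = k$v)
        pt(-tu, df = k$v, ncp = model@delta) +
            pt(tu, df = k$v, ncp = model@delta, lower.tail = FALSE)
    } else function(u)
        .pvalueCdfAfterFilter(model, filter, w, u, k$Delta, pAlt)
    h <- function(u) pi0W * G0W(u) + (1 - pi0W) * GaW(u) - u / phi
    # largest u with h(u) >= 0: scan a decreasing log grid for a bracket
    grid <- exp(seq(log(1 - 1e-9), log(1e-12), length.out = 80L))
    hi <- NULL
    for (i in seq_along(grid)) {
        if (h(grid[i]) >= 0) { hi <- i; break }
    }
    if (is.null(hi)) return(list(uStar = 0, power = 0, pi0W = pi0W, w = w))
    uStar <- if (hi == 1L) grid[1L]
        else uniroot(h, c(grid[hi], grid[hi - 1L]), tol = 1e-10)$root
    list(uStar = uStar, power = GaW(uStar), pi0W = pi0W, w = w)
}

#' Reference retained-null-proportion curves
#'
#' Closed forms for the two bounding reference filters as a function of the
#' fraction filtered out x: the oracle best filter removes only nulls while
#' any remain, pi0(x) = max(0, (pi0 - x) / (1 - x)); the random filter
#' removes features blindly, pi0(x) = pi0 for all x. Every realistic filter's
#' curve lies between the two.
#'
#' @param pi0 generating null proportion in (0, 1).
#' @param xGrid fractions filtered out, each in [0, 1).
#' @return data.frame with columns \code{x}, \code{best}, \code{random}.
#' @export
pi0ReferenceCurves <- function(pi0, xGrid) {
    if (pi0 <= 0 || pi0 >= 1) stop("'pi0' must lie in (0, 1)")
    if (any(xGrid < 0 | xGrid >= 1)) stop("fractions must lie in [0, 1)")
    data.frame(x = xGrid, best = pmax(0, (pi0 - xGrid) / (1 - xGrid)),
               random = rep(pi0, length(xGrid)))
}
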