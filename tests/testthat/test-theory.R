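# Model draws straight from the sampling structure (D independent of Sp^2),
# used as the Monte-Carlo oracle for the quadrature-based laws.
drawModel <- function(n, delta = 0, seed = 1) {
    set.seed(seed)
    sdD <- sqrt(0.4)
    list(D = rnorm(n, delta * sdD, sdD), q = rchisq(n, 8))
}

test_that("a null threshold recovers the unconditional t distribution", {
    tg <- c(-4, -1.5, -0.3, 0, 0.7, 2.1, 5)
    m0 <- modelSpec(delta = 0)
    expect_equal(conditionalTCdf(m0, "fold_change", 0, tg)$cdf,
                 pt(tg, 8), tolerance = 1e-8)
    expect_equal(conditionalTCdf(m0, "variance", 0, tg)$cdf,
                 pt(tg, 8), tolerance = 1e-8)
    m1 <- modelSpec(delta = 1)
    expect_equal(conditionalTCdf(m1, "none", 0, tg)$cdf,
                 pt(tg, 8, ncp = 1), tolerance = 1e-8)
})

test_that("the signal filter leaves the t distribution untouched (nX = nY)", {
    tg <- seq(-3, 3, by = 0.75)
    for (d in c(0, 1)) {
        md <- modelSpec(delta = d)
        got <- conditionalTCdf(md, "signal", 0.8, tg)$cdf
        expect_equal(got, pt(tg, 8, ncp = d), tolerance = 1e-8)
    }
    expect_error(conditionalTCdf(modelSpec(nX = 4, nY = 6), "signal", 0.5,
                                 0), "nX = nY")
})

test_that("fold-change and variance conditional cdfs match model draws", {
    draws <- drawModel(2e5, delta = 0, seed = 42)
    T <- draws$D / sqrt(draws$q / 8 * 0.4)
    m0 <- modelSpec(delta = 0)
    tg <- c(-3, -1, -0.5, 0.5, 1, 3)

    w <- qnorm(0.625) * sqrt(0.4)  # 25% quantile of |D| under the null
    keep <- abs(draws$D) >= w
    emp <- vapply(tg, function(t) mean(T[keep] <= t), numeric(1))
    th <- conditionalTCdf(m0, "fold_change", w, tg)$cdf
    se <- sqrt(pmax(emp * (1 - emp), 1e-12) / sum(keep))
    expect_true(all(abs(emp - th) <= 3 * se))

    wv <- solveFilterThreshold(m0, "variance", 0.25)
    keepv <- draws$q / 8 >= wv  # Sp^2 with sigma = 1
    empv <- vapply(tg, function(t) mean(T[keepv] <= t), numeric(1))
    thv <- conditionalTCdf(m0, "variance", wv, tg)$cdf
    sev <- sqrt(pmax(empv * (1 - empv), 1e-12) / sum(keepv))
    expect_true(all(abs(empv - thv) <= 3 * sev))

    # cdfs are monotone within numerical tolerance
    grid <- seq(-6, 6, length.out = 60)
    expect_true(all(diff(conditionalTCdf(m0, "fold_change", w,
                                         grid)$cdf) >= -1e-10))
    # a filter that removes essentially everything is an error
    expect_error(conditionalTCdf(m0, "fold_change", 100, 0),
                 "conditioning probability")
})

test_that("post-filter p-value densities normalize and shape as derived", {
    m0 <- modelSpec(delta = 0)
    # unfiltered null: uniform
    d0 <- pvalueDensityAfterFilter(m0, "fold_change", 0,
                                   seq(0.05, 0.95, 0.1))
    expect_equal(d0$density, rep(1, 10), tolerance = 1e-8)
    # fold change, 25% removed: excess small p-values, depleted near 1
    d <- pvalueDensityAfterFilter(m0, "fold_change", 0.25, c(0.02, 0.98))
    expect_gt(d$density[1], 1)
    expect_lt(d$density[2], 1)
    # densities integrate to 1
    for (flt in c("fold_change", "variance")) {
        tot <- integrate(function(p)
            pvalueDensityAfterFilter(m0, flt, 0.25, p)$density,
            0, 1, rel.tol = 1e-7)$value
        expect_equal(tot, 1, tolerance = 1e-6)
    }
    # variance filter under the alternative: fewer p-values near 0
    m1 <- modelSpec(delta = 1)
    dAlt <- pvalueDensityAfterFilter(m1, "variance", 0.25, 0.02,
                                     component = "alternative")$density
    dRef <- pvalueDensityAfterFilter(m1, "variance", 0, 0.02,
                                     component = "alternative")$density
    expect_lt(dAlt, dRef)
})

test_that("analytic BH power matches a large Monte-Carlo run", {
    # interior operating point needs a detectable effect; delta = 3 here
    m3 <- modelSpec(delta = 3)
    a0 <- analyticPowerAfterFilter(m3, "none", 0, 0.05)
    expect_gt(a0$power, 0)
    # simulate 4e5 features from the mixture and run BH
    set.seed(33)
    N <- 4e5
    isNull <- seq_len(N) <= 0.8 * N
    sgn <- sample(c(-1, 1), N, TRUE)
    mu <- ifelse(isNull, 0, 3) * sgn * sqrt(0.4)
    X <- matrix(rnorm(N * 5), N) + mu / 2
    Y <- matrix(rnorm(N * 5), N) - mu / 2
    D <- rowMeans(X) - rowMeans(Y)
    sp2 <- (rowSums((X - rowMeans(X))^2) +
            rowSums((Y - rowMeans(Y))^2)) / 8
    p <- 2 * pt(abs(D / sqrt(sp2 * 0.4)), 8, lower.tail = FALSE)
    rej <- p.adjust(p, "BH") <= 0.05
    mcPower <- mean(rej[!isNull])
    # pointwise agreement of the alternative p-value cdf at the operating
    # point, within 3 binomial se
    GaMC <- mean(p[!isNull] <= a0$uStar)
    tu <- qt(1 - a0$uStar / 2, 8)
    GaTh <- pt(-tu, 8, ncp = 3) + pt(tu, 8, ncp = 3, lower.tail = FALSE)
    expect_lt(abs(GaMC - GaTh), 3 * sqrt(GaTh * (1 - GaTh) / (0.2 * N)))
    # the finite-m BH operating point is slightly upward-biased, so the
    # power comparison carries a small systematic term beyond binomial noise
    expect_lt(abs(a0$power - mcPower), 0.01)
    # fold-change filtering improves power; the variance filter does not
    af <- analyticPowerAfterFilter(m3, "fold_change", 0.25, 0.05)
    expect_gte(af$power, a0$power)
    av <- analyticPowerAfterFilter(m3, "variance", 0.25, 0.05)
    expect_lte(av$power, a0$power)
    # vanishing level drives the power to 0 (monotone limit)
    expect_equal(analyticPowerAfterFilter(m3, "none", 0, 1e-9)$power, 0)
    # at the study default delta = 1 the asymptotic operating point is
    # degenerate: zero rejections, power 0, returned as a valid output
    a1 <- analyticPowerAfterFilter(modelSpec(delta = 1), "none", 0, 0.05)
    expect_identical(a1$uStar, 0)
    expect_identical(a1$power, 0)
})

test_that("reference pi0(x) curves follow the counting argument", {
    cur <- pi0ReferenceCurves(0.8, c(0, 0.5, 0.79))
    expect_equal(cur$best, c(0.8, 0.6, (0.8 - 0.79) / 0.21))
    expect_equal(cur$random, rep(0.8, 3))
    expect_equal(pi0ReferenceCurves(0.6, 0.6)$best, 0)  # exhaustion point
    expect_error(pi0ReferenceCurves(0.8, 1), "\\[0, 1\\)")
    expect_error(pi0ReferenceCurves(1.2, 0.5), "pi0")
})
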