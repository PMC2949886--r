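test_that("the empirical cdf is a right-continuous counting function", {
    Gm <- empiricalCdf(0.5)
    expect_equal(Gm(0.4), 0)
    expect_equal(Gm(0.5), 1)
    expect_equal(Gm(1), 1)
    expect_error(empiricalCdf(numeric(0)), "empty")
    expect_error(empiricalCdf(c(0.2, 1.4)), "\\[0, 1\\]")
    set.seed(1)
    p <- runif(1000)
    Gm <- empiricalCdf(p)
    u <- runif(100)
    expect_equal(Gm(u), vapply(u, function(ui) mean(p <= ui), numeric(1)))
})

test_that("hand-computed step-up worked examples", {
    p <- c(0.01, 0.02, 0.5)
    # BH thresholds i * 0.05 / 3 = 0.0167, 0.0333, 0.05 -> largest i is 2
    expect_identical(rejected(fdrBH(p, 0.05)), c(TRUE, TRUE, FALSE))
    # BY thresholds i * 0.05 / (3 * c(3)), c(3) = 11/6:
    # 0.00909, 0.01818, 0.02727 -> no order statistic qualifies
    cm <- sum(1 / (1:3))
    byHand <- vapply(1:3, function(i) sort(p)[i] <= i * 0.05 / (3 * cm),
                     logical(1))
    expect_false(any(byHand))
    expect_identical(sum(rejected(fdrBY(p, 0.05))), 0L)
    # Bonferroni threshold 0.05 / 3 = 0.0167 -> rejects exactly the 0.01
    expect_identical(rejected(fdrBonferroni(p, 0.05)),
                     c(TRUE, FALSE, FALSE))
    # m = 1 reduces to a plain level-phi test, and BY collapses to BH
    expect_true(rejected(fdrBH(0.04, 0.05)))
    expect_true(rejected(fdrBonferroni(0.04, 0.05)))
    expect_identical(rejected(fdrBY(0.04, 0.05)),
                     rejected(fdrBH(0.04, 0.05)))
})

test_that("degenerate p-value vectors behave by convention", {
    ones <- rep(1, 6)
    expect_identical(sum(rejected(fdrBH(ones, 0.05))), 0L)
    expect_identical(uStar(fdrBH(ones, 0.05)), 0)
    expect_identical(sum(rejected(stepUpGeneric(ones, gForm("bh"), 0.05))),
                     0L)
    zeros <- rep(0, 6)
    expect_identical(sum(rejected(fdrBH(zeros, 0.05))), 6L)
    expect_identical(sum(rejected(stepUpGeneric(zeros, gForm("bh"), 0.05))),
                     6L)
    expect_error(fdrBH(ones, 1.5), "phi")
    expect_error(stepUpGeneric(ones, gForm("bh"), 0), "phi")
})

test_that("step-up specializations equal their classical implementations", {
    set.seed(99)
    for (i in 1:300) {
        p <- randomPvalues(sample(3:60, 1))
        phi <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
        m <- length(p)
        expect_identical(rejected(stepUpGeneric(p, gForm("bh"), phi)),
                         rejected(fdrBH(p, phi)))
        expect_identical(
            rejected(stepUpGeneric(p, gForm("by", m = m), phi)),
            rejected(fdrBY(p, phi)))
        pi0 <- estimatePi0LSL(p)
        expect_identical(
            rejected(stepUpGeneric(p, gForm("abh", pi0 = pi0), phi)),
            rejected(fdrABH(p, phi)))
        # conservativeness inclusions on every vector (Bonferroni and BY
        # are each contained in BH; adaptive BH contains BH)
        rb <- rejected(fdrBonferroni(p, phi))
        ry <- rejected(fdrBY(p, phi))
        rh <- rejected(fdrBH(p, phi))
        ra <- rejected(fdrABH(p, phi))
        expect_true(all(rb <= rh))
        expect_true(all(ry <= rh))
        expect_true(all(rh <= ra))
        # step-up family invariant: rejected <=> p <= uStar
        f <- fdrBH(p, phi)
        expect_identical(rejected(f),
                         p <= uStar(f) & sum(rejected(f)) > 0)
    }
})

test_that("the lowest-slope pi0 estimator behaves per its construction", {
    expect_equal(estimatePi0LSL(rep(1, 50)), 1)
    # all p-values near 0: estimate collapses far below 1
    expect_lte(estimatePi0LSL(rep(1e-6, 100) + seq(0, 1e-4, length = 100)),
               0.5)
    expect_error(estimatePi0LSL(0.5), "at least 2")
    # calibration: mean estimate over 200 simulated datasets (true pi0 0.8)
    est <- vapply(1:200, function(r) {
        sim <- simulateTwoGroupData(m = 1000, seed = subSeed(77, r))
        estimatePi0LSL(pvalues(pooledT(sim$dataset)))
    }, numeric(1))
    expect_gte(mean(est), 0.7)
    expect_lte(mean(est), 1.0)
})

test_that("q-value procedure: closed forms, refusal and monotonicity", {
    m <- 100
    grid <- (1:m) / m
    res <- fdrQvalue(grid, 0.05, lambda = 0.5)
    # pi0_hat = #(p > 0.5) / (m * 0.5) = 1 on the uniform grid
    expect_equal(pi0Hat(res), 1)
    # q_i = min_{j >= i} pi0 * m * p_(j) / j = 1 for every i on the grid
    expect_equal(qvalues(res), rep(1, m))
    # refusal when p-values do not span the unit interval
    expect_error(fdrQvalue(runif(50, 0, 0.39), 0.05, lambda = 0.5),
                 "lambda")
    # monotone nondecreasing in p on random vectors
    set.seed(5)
    for (i in 1:20) {
        p <- randomPvalues(80)
        p[which.max(p)] <- 0.99  # keep the estimator non-degenerate
        q <- qvalues(fdrQvalue(p, 0.05))
        expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
})

test_that("adaptive BH reduces to BH when pi0_hat = 1 and never below it", {
    # heavy mass near 1 drives the lowest-slope estimate to 1
    set.seed(8)
    p <- runif(200, 0.5, 1)
    expect_equal(estimatePi0LSL(p), 1)
    expect_identical(rejected(fdrABH(p, 0.05)), rejected(fdrBH(p, 0.05)))
    # Storey estimator variant is accepted too
    r2 <- fdrABH(randomPvalues(100, signal = TRUE), 0.05,
                 pi0Estimator = "storey")
    expect_s4_class(r2, "FdrResult")
    expect_true(pi0Hat(r2) > 0 && pi0Hat(r2) <= 1)
})

test_that("BH controls the FDR on the unfiltered standard simulation", {
    fdp <- vapply(1:100, function(r) {
        sim <- simulateTwoGroupData(m = 500, seed = subSeed(123, r))
        achievedFdr(rejected(fdrBH(pvalues(pooledT(sim$dataset)), 0.05)),
                    sim$isNull)
    }, numeric(1))
    se <- sd(fdp) / sqrt(length(fdp))
    expect_lte(mean(fdp), 0.05 + 3 * se)
})
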