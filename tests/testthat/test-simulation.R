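test_that("the generator produces calibrated null and alternative features", {
    sim <- simulateTwoGroupData(m = 10000, pi0 = 1, seed = 31)
    expect_identical(sum(sim$isNull), 10000L)
    # pure-null p-values are uniform
    expect_gt(ksUniform(pvalues(pooledT(sim$dataset))), 0.01)
    # delta = 0 alternatives are indistinguishable from nulls
    deg <- simulateTwoGroupData(m = 500, pi0 = 0.5, delta = 0, seed = 7)
    expect_gt(ksUniform(pvalues(pooledT(deg$dataset))), 0.01)
    # alternative |T| matches the noncentral-t mean |E|T|| at delta = 1
    mix <- simulateTwoGroupData(m = 10000, seed = 4)
    expect_identical(sum(mix$isNull), 8000L)
    Talt <- abs(testStatistics(pooledT(mix$dataset))[!mix$isNull])
    expected <- suppressWarnings(
        integrate(function(t) abs(t) * dt(t, 8, ncp = 1),
                  -Inf, Inf)$value)  # noncentral-t precision notes
    se <- sd(Talt) / sqrt(length(Talt))
    expect_lt(abs(mean(Talt) - expected), 3 * se)
})

test_that("achieved FDR, observed power and retained pi0 count correctly", {
    truth <- c(TRUE, FALSE, FALSE, TRUE)      # nulls at 1 and 4
    rej <- c(TRUE, TRUE, TRUE, FALSE)         # one rejected null
    expect_equal(achievedFdr(rej, truth), 1 / 3)
    expect_equal(observedPower(rej, truth), 1)
    expect_equal(achievedFdr(rep(FALSE, 4), truth), 0)  # 0/0 convention
    expect_equal(observedPower(c(TRUE, TRUE, FALSE, FALSE), truth), 0.5)
    expect_error(achievedFdr(rej, truth[1:3]), "lengths differ")
    expect_error(observedPower(rej, truth[1:3]), "lengths differ")
    expect_error(pi0Retained(rep(FALSE, 4), truth), "no features retained")
    # brute-force set arithmetic on random masks
    set.seed(12)
    for (i in 1:50) {
        n <- sample(5:50, 1)
        truth <- runif(n) < 0.7
        rej <- runif(n) < 0.3
        keep <- runif(n) < 0.8
        keep[1] <- TRUE
        expect_equal(achievedFdr(rej, truth),
                     if (!any(rej)) 0 else
                         length(intersect(which(rej), which(truth))) /
                             length(which(rej)))
        expect_equal(observedPower(rej, truth),
                     if (!any(!truth)) 0 else
                         length(intersect(which(rej), which(!truth))) /
                             length(which(!truth)))
        expect_equal(pi0Retained(keep, truth),
                     length(intersect(which(keep), which(truth))) /
                         length(which(keep)))
    }
})

test_that("the best filter hits the theoretical pi0 curve exactly", {
    sim <- simulateTwoGroupData(m = 1000, seed = 1)
    fr <- oracleBestFilter(sim$isNull, 0.5)
    expect_identical(pi0Retained(retained(fr), sim$isNull), 0.6)
    expect_equal(
        pi0Retained(retained(fr), sim$isNull),
        pi0ReferenceCurves(0.8, 0.5)$best)
})

test_that("the simulation grid is reproducible and bookkeeps correctly", {
    cfg <- loadConfig()
    cfg$simulation$m <- 100L
    cfg$simulation$n_datasets <- 5L
    cfg$simulation$fractions <- c(0, 0.3)
    cfg$simulation$filters <- c("fold_change", "best")
    cfg$simulation$fdr_methods <- c("bh", "bonferroni")
    g1 <- runSimulationGrid(cfg)
    g2 <- runSimulationGrid(cfg)
    expect_identical(g1, g2)
    expect_identical(nrow(g1), 8L)  # 2 filters x 2 fractions x 2 methods
    expect_true(all(g1$achieved_fdr_mean >= 0 & g1$achieved_fdr_mean <= 1))
    expect_true(all(g1$pi0_retained_se >= 0))
    # best filter at fraction 0.3 retains pi0 (0.8 - 0.3)/0.7 exactly in
    # every replicate
    best3 <- g1[g1$filter == "best" & g1$fraction_out == 0.3, ]
    expect_equal(unique(best3$pi0_retained_mean), 0.5 / 0.7,
                 tolerance = 1e-12)
    # invalid combination rejected up front
    cfg$simulation$fdr_methods <- "qvalue"
    cfg$simulation$filters <- "fold_change"
    expect_error(runSimulationGrid(cfg), "q-value")
})

test_that("the grid runs with the Wilcoxon test and keeps filter behaviour", {
    cfg <- loadConfig()
    cfg$simulation$m <- 200L
    cfg$simulation$n_datasets <- 10L
    cfg$simulation$fractions <- c(0, 0.5)
    cfg$simulation$filters <- c("fold_change", "signal")
    cfg$simulation$test <- "wilcoxon"
    g <- runSimulationGrid(cfg)
    expect_identical(nrow(g), 4L)
    # filter statistics act on the data, not the test: fold change still
    # enriches alternatives (lower retained pi0) relative to signal
    fc <- g[g$filter == "fold_change" & g$fraction_out == 0.5, ]
    sg <- g[g$filter == "signal" & g$fraction_out == 0.5, ]
    expect_lt(fc$pi0_retained_mean, sg$pi0_retained_mean)
})

test_that("power accounting treats filtered-out alternatives as losses", {
    sim <- simulateTwoGroupData(m = 50, pi0 = 0.5, seed = 3)
    # a filter that removes every alternative caps power at 0
    keepNullsOnly <- sim$isNull
    rej <- logical(50)
    rej[keepNullsOnly][1] <- TRUE  # even with rejections among retained
    expect_equal(observedPower(rej & keepNullsOnly, sim$isNull), 0)
    # denominator is always the original alternative count
    half <- !sim$isNull & cumsum(!sim$isNull) <= sum(!sim$isNull) / 2
    expect_equal(observedPower(half, sim$isNull), 0.5, tolerance = 0.05)
})

test_that("post-FDR filtering shortens the list and shifts its FDR", {
    sim <- simulateTwoGroupData(m = 2000, delta = 3, seed = 21)
    p <- pvalues(pooledT(sim$dataset))
    f <- fdrBH(p, 0.1)
    fc <- foldChangeStatistic(sim$dataset)
    # identity at fractionOut = 0
    r0 <- postFdrFilter(f, fc, 0, sim$isNull)
    expect_identical(r0$kept, rejected(f))
    expect_equal(r0$achievedFdr, achievedFdr(rejected(f), sim$isNull))
    # the shortened list is a subset with never-larger power
    r5 <- postFdrFilter(f, fc, 0.5, sim$isNull)
    expect_true(all(r5$kept <= rejected(f)))
    expect_lte(r5$power, r0$power)
    expect_error(postFdrFilter(f, fc[-1], 0.5, sim$isNull), "length")
    # prioritizing rejections by fold change systematically changes the
    # within-list false-positive fraction (here: enriches true positives)
    prePost <- vapply(1:40, function(r) {
        g <- simulateTwoGroupData(m = 1000, delta = 3,
                                  seed = subSeed(99, r))
        pr <- pvalues(pooledT(g$dataset))
        fr <- fdrBH(pr, 0.1)
        c(achievedFdr(rejected(fr), g$isNull),
          postFdrFilter(fr, foldChangeStatistic(g$dataset), 0.5,
                        g$isNull)$achievedFdr)
    }, numeric(2))
    d <- prePost[2, ] - prePost[1, ]
    expect_lt(mean(d) / (sd(d) / sqrt(length(d))), -3)
})
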