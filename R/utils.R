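# RNG plumbing shared by every stochastic operation.

#' Derive a reproducible sub-seed from a master seed
#'
#' Splitting rule used throughout the package (permutation rounds, simulation
#' replicates, random filters): \code{(seed * 1009 + k) mod (2^31 - 1)}.
#' Keeps derived seeds valid 32-bit integers and distinct across consecutive
#' rounds.
#'
#' @param seed integer master seed.
#' @param k integer round/replicate index (>= 0).
#' @return integer sub-seed.
#' @export
subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% (2^31 - 1))
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Per-feature group means/variances for a TwoGroupExperiment; the workhorse
# behind every filter and test statistic.
.groupStats <- function(dataset) {
    v <- exprValues(dataset)
    g <- groupLabels(dataset)
    xa <- v[, g == "A", drop = FALSE]
    xb <- v[, g == "B", drop = FALSE]
    nX <- ncol(xa); nY <- ncol(xb)
    meanA <- rowMeans(xa)
    meanB <- rowMeans(xb)
    varA <- if (nX >= 2) rowSums((xa - meanA)^2) / (nX - 1) else rep(NA_real_, nrow(v))
    varB <- if (nY >= 2) rowSums((xb - meanB)^2) / (nY - 1) else rep(NA_real_, nrow(v))
    list(meanA = meanA, meanB = meanB, varA = varA, varB = varB,
         nX = nX, nY = nY)
}
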