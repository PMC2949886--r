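# The permutation-based test for filtering-induced FDR bias. One round:
# permute group labels (breaking the group-expression association),
# recompute BOTH the filter statistic and the test p-values on the permuted
# data, filter, and measure how far the retained null p-values are from
# U[0,1]. Repeating N0 rounds yields an empirical distribution Gq of
# uniformity p-values; a meta-level KS test of Gq against U[0,1] gives the
# final p-value. A small final p-value means the filter distorts the null
# p-value distribution, hence biases any FDR method relying on it.

#' One-sample Kolmogorov-Smirnov test against U[0,1]
#'
#' Thin, argument-checked wrapper around the standard one-sample KS test
#' specialized to the uniform null. \code{"one_sided_excess_small"} uses
#' D+ = sup_u (empirical cdf - u), sensitive to a surplus of small p-values
#' (the direction in which filtering inflates the FDR); \code{"two_sided"}
#' uses the usual D. Exact small-sample p-values are used for n < 100
#' (without ties), the asymptotic distribution otherwise.
#'
#' @param values numeric vector in [0, 1]; must be non-empty.
#' @param sided \code{"one_sided_excess_small"} or \code{"two_sided"}.
#' @return the KS p-value (numeric scalar).
#' @export
ksUniform <- function(values, sided = c("two_sided",
                                        "one_sided_excess_small")) {
    sided <- match.arg(sided)
    if (length(values) == 0L) stop("empty input")
    if (any(values < 0 | values > 1) || anyNA(values))
        stop("values must lie in [0, 1]")
    alternative <- if (sided == "one_sided_excess_small") "greater"
                   else "two.sided"
    suppressWarnings(
        ks.test(values, "punif", alternative = alternative)$p.value)
}

#' Null p-values after permutation and filtering
#'
#' One permutation round of the FDR-bias test: permute the group labels with
#' [permuteGroupLabels()], recompute the filter statistic and the per-feature
#' test p-values on the permuted dataset, apply the fraction-based filter,
#' and return the retained p-values. Their distribution estimates G0W, the
#' null p-value law after filtering by W. The filter statistic is recomputed
#' on the permuted data (not frozen from the original labels) so that
#' label-dependent filters such as the fold change co-vary with the permuted
#' test statistic, as the conditional null law requires.
#'
#' @param dataset a \linkS4class{TwoGroupExperiment}.
#' @param filterName \code{"signal"}, \code{"fold_change"}, \code{"variance"}
#'   or \code{"random"}.
#' @param fractionOut fraction of features filtered out, in [0, 1).
#' @param testMethod \code{"t"} (pooled t) or \code{"wilcoxon"}.
#' @param seed integer seed for the permutation (and the random filter).
#' @return numeric vector of retained permuted-null p-values.
#' @export
filteredNullPvalues <- function(dataset, filterName, fractionOut,
                                testMethod = "t", seed = 1L) {
    perm <- permuteGroupLabels(dataset, seed)
    p <- pvalues(.testBy(perm, testMethod))
    keep <- if (filterName == "random")
        retained(randomFilter(nrow(perm), fractionOut,
                              seed = subSeed(seed, 1L)))
    else
        retained(applyFilter(.filterStatistic(perm, filterName), fractionOut,
                             statisticName = filterName))
    p[keep]
}

#' Permutation test for filtering-induced FDR bias
#'
#' Runs [filteredNullPvalues()] for \code{nPermutations} independent rounds
#' (round r uses sub-seed \code{subSeed(seed, r)}), converts each round's
#' retained p-values into a uniformity p-value q_r, and finally compares the
#' empirical distribution Gq of q_1..q_N0 to U[0,1] with a two-sided KS test.
#' Under an unbiased filter each round's retained p-values are uniform, so
#' the q_r are uniform and the final p-value is large; a final p-value below
#' conventional levels is evidence that the filter biases FDR estimation.
#'
#' Round-level modes:
#' \describe{
#'   \item{ks}{(default) one-sided KS p-value (D+), sensitive to the excess
#'     of small p-values that inflates the FDR and less conservative than the
#'     two-sided test.}
#'   \item{bh}{the minimum BH-adjusted p-value of the round — a valid
#'     p-value for the intersection null "all retained features null", the
#'     literal FDR-correction-as-test variant.}
#' }
#'
#' @inheritParams filteredNullPvalues
#' @param nPermutations number of rounds N0 (>= 20; default 100).
#' @param mode round-level uniformity check, \code{"ks"} or \code{"bh"}.
#' @param seed integer master seed; the whole report is reproducible from it.
#' @return A \linkS4class{BiasTestReport}.
#' @examples
#' sim <- simulateTwoGroupData(m = 200, seed = 7)
#' rep <- fdrBiasTest(sim$dataset, "fold_change", fractionOut = 0.3,
#'                    nPermutations = 25, seed = 7)
#' finalPvalue(rep)
#' @export
fdrBiasTest <- function(dataset, filterName, fractionOut, testMethod = "t",
                        nPermutations = 100L, mode = c("ks", "bh"),
                        seed = 1L) {
    mode <- match.arg(mode)
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 20L)
        stop("'nPermutations' must be at least 20: the meta-level test of ",
             "the round p-values against U[0,1] needs a reasonable sample ",
             "size to be informative")
    q <- vapply(seq_len(nPermutations), function(r) {
        p <- filteredNullPvalues(dataset, filterName, fractionOut,
                                 testMethod, seed = subSeed(seed, r))
        if (mode == "ks") ksUniform(p, "one_sided_excess_small")
        else min(p.adjust(p, method = "BH"))
    }, numeric(1L))
    new("BiasTestReport", filterName = filterName,
        fractionOut = fractionOut, testMethod = testMethod, mode = mode,
        nPermutations = nPermutations, permPvalues = q,
        finalPvalue = ksUniform(q, "two_sided"), seed = as.integer(seed))
}

#' @rdname BiasTestReport-accessors
#' @export
setMethod("finalPvalue", "BiasTestReport", function(x) x@finalPvalue)

#' @rdname BiasTestReport-accessors
#' @export
setMethod("permPvalues", "BiasTestReport", function(x) x@permPvalues)

setMethod("show", "BiasTestReport", function(object) {
    verdict <- if (object@finalPvalue < 0.001) "strong evidence of FDR bias"
        else if (object@finalPvalue < 0.05) "evidence of FDR bias"
        else "no evidence of FDR bias"
    cat(sprintf(
        "FDR-bias test: filter '%s', fraction out %.2f, %s test, N0 = %d\n",
        object@filterName, object@fractionOut, object@testMethod,
        object@nPermutations))
    cat(sprintf("  final p-value = %.4g  (%s)\n", object@finalPvalue,
                verdict))
})

#' Serialize a BiasTestReport to JSON
#'
#' @param report a \linkS4class{BiasTestReport}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBiasTestReport <- function(report, path) {
    jsonlite::write_json(list(
        filter = report@filterName, fraction_out = report@fractionOut,
        test = report@testMethod, mode = report@mode,
        n_permutations = report@nPermutations, seed = report@seed,
        per_perm_pvalues = report@permPvalues,
        final_pvalue = report@finalPvalue),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
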