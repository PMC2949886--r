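#' Construct a TwoGroupExperiment
#'
#' @param values numeric matrix, m features x n samples (log-scale expression,
#'   already normalized/pre-processed; no missing values allowed).
#' @param group character or factor of length \code{ncol(values)} assigning
#'   each sample to group \code{"A"} or \code{"B"}; both groups must be
#'   non-empty.
#' @param featureIds,sampleIds optional row/column names; taken from
#'   \code{dimnames(values)} when present, generated otherwise.
#'
#' @return A \linkS4class{TwoGroupExperiment}.
#'
#' @examples
#' x <- matrix(rnorm(40), nrow = 10)
#' tge <- TwoGroupExperiment(x, group = c("A", "A", "B", "B"))
#' groupSizes(tge)
#' @export
TwoGroupExperiment <- function(values, group, featureIds = NULL,
                               sampleIds = NULL) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.null(featureIds))
        featureIds <- rownames(values)
    if (is.null(featureIds))
        featureIds <- sprintf("feature_%d", seq_len(nrow(values)))
    if (is.null(sampleIds))
        sampleIds <- colnames(values)
    if (is.null(sampleIds))
        sampleIds <- sprintf("sample_%d", seq_len(ncol(values)))
    dimnames(values) <- list(featureIds, sampleIds)
    if (length(group) != ncol(values))
        stop("'group' must have one label per sample")
    bad <- setdiff(as.character(group[!is.na(group)]), c("A", "B"))
    if (length(bad))
        stop("group labels must be 'A' or 'B'; found: ",
             paste(unique(bad), collapse = ", "))
    group <- factor(as.character(group), levels = c("A", "B"))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(group = group, row.names = sampleIds))
    new("TwoGroupExperiment", se)
}

#' @describeIn TwoGroupExperiment the expression matrix (assay
#'   \code{"exprs"}).
#' @export
setMethod("exprValues", "TwoGroupExperiment", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @describeIn TwoGroupExperiment the two-level group factor.
#' @export
setMethod("groupLabels", "TwoGroupExperiment", function(x)
    SummarizedExperiment::colData(x)$group)

#' @describeIn TwoGroupExperiment named integer vector c(A = nX, B = nY).
#' @export
setMethod("groupSizes", "TwoGroupExperiment", function(x) {
    tab <- table(groupLabels(x))
    c(A = unname(tab["A"]), B = unname(tab["B"]))
})

setMethod("show", "TwoGroupExperiment", function(object) {
    ns <- groupSizes(object)
    cat(sprintf("TwoGroupExperiment: %d features, %d samples (A: %d, B: %d)\n",
                nrow(object), ncol(object), ns["A"], ns["B"]))
    callNextMethod()
})
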