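#' @rdname TwoGroupExperiment
#' @param x an object.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname TwoGroupExperiment
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname TwoGroupExperiment
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname FilterResult-accessors
#' @param x an object.
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))

#' @rdname FilterResult-accessors
#' @export
setGeneric("filterValues", function(x) standardGeneric("filterValues"))

#' @rdname FilterResult-accessors
#' @export
setGeneric("filterThreshold", function(x) standardGeneric("filterThreshold"))

#' @rdname FilterResult-accessors
#' @export
setGeneric("gammaRetained", function(x) standardGeneric("gammaRetained"))

#' @rdname TestResult-accessors
#' @param x an object.
#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))

#' @rdname TestResult-accessors
#' @export
setGeneric("testStatistics", function(x) standardGeneric("testStatistics"))

#' @rdname FdrResult-accessors
#' @param x an object.
#' @export
setGeneric("rejected", function(x) standardGeneric("rejected"))

#' @rdname FdrResult-accessors
#' @export
setGeneric("uStar", function(x) standardGeneric("uStar"))

#' @rdname FdrResult-accessors
#' @export
setGeneric("pi0Hat", function(x) standardGeneric("pi0Hat"))

#' @rdname FdrResult-accessors
#' @export
setGeneric("qvalues", function(x) standardGeneric("qvalues"))

#' @rdname BiasTestReport-accessors
#' @param x an object.
#' @export
setGeneric("finalPvalue", function(x) standardGeneric("finalPvalue"))

#' @rdname BiasTestReport-accessors
#' @export
setGeneric("permPvalues", function(x) standardGeneric("permPvalues"))
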