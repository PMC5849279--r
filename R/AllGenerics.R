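#' @rdname imputeMissing
#' @export
setGeneric("imputeMissing", function(x, panel = NULL, ...)
    standardGeneric("imputeMissing"))

#' @rdname computeGrs
#' @export
setGeneric("computeGrs", function(x, panel, ...)
    standardGeneric("computeGrs"))

#' @rdname assignQuantiles
#' @export
setGeneric("assignQuantiles", function(x, k, ...)
    standardGeneric("assignQuantiles"))

#' @rdname GrsVector-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname GrsVector-accessors
#' @export
setGeneric("quintiles", function(x) standardGeneric("quintiles"))

#' @rdname GrsVector-accessors
#' @export
setGeneric("tertiles", function(x) standardGeneric("tertiles"))

#' @rdname GrsVector-accessors
#' @export
setGeneric("quantileBounds", function(x, k = 5L) standardGeneric("quantileBounds"))

#' @rdname AfCohort-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname AfCohort-accessors
#' @export
setGeneric("snpPanel", function(x) standardGeneric("snpPanel"))

#' @rdname AfCohort-accessors
#' @export
setGeneric("covariateTable", function(x) standardGeneric("covariateTable"))

#' @rdname AfCohort-accessors
#' @export
setGeneric("afEvents", function(x) standardGeneric("afEvents"))
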