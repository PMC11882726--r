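#' @rdname SumStats-class
#' @param x,object a package object.
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))

#' @rdname SumStats-class
#' @export
setGeneric("ssData", function(x) standardGeneric("ssData"))

#' @rdname CovarianceStack-class
#' @export
setGeneric("gcov", function(x) standardGeneric("gcov"))

#' @rdname CovarianceStack-class
#' @export
setGeneric("sampCov", function(x) standardGeneric("sampCov"))

#' @rdname CovarianceStack-class
#' @export
setGeneric("stackLabels", function(x) standardGeneric("stackLabels"))

#' @rdname CovarianceStack-class
#' @export
setGeneric("ldscIntercepts", function(x) standardGeneric("ldscIntercepts"))

#' @rdname CovarianceStack-class
#' @export
setGeneric("h2Z", function(x) standardGeneric("h2Z"))

#' @rdname FitResult-class
#' @export
setGeneric("fitEstimates", function(x) standardGeneric("fitEstimates"))

#' @rdname LatentGwasResult-class
#' @export
setGeneric("gwasResults", function(x) standardGeneric("gwasResults"))

#' @rdname LatentGwasResult-class
#' @export
setGeneric("gwasReport", function(x) standardGeneric("gwasReport"))
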