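#' @rdname FeatureTable-class
#' @param x a \linkS4class{FeatureTable}
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname FeatureTable-class
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname FeatureTable-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname FeatureTable-class
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname SelectionResult-class
#' @param x a \linkS4class{SelectionResult}
#' @export
setGeneric("bestSubset", function(x) standardGeneric("bestSubset"))

#' @rdname SelectionResult-class
#' @export
setGeneric("bestScore", function(x) standardGeneric("bestScore"))

#' @rdname SelectionResult-class
#' @export
setGeneric("scoreHistory", function(x) standardGeneric("scoreHistory"))

#' @rdname SelectionResult-class
#' @export
setGeneric("finalPheromone", function(x) standardGeneric("finalPheromone"))
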