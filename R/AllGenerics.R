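#' @include AllClasses.R
NULL

#' @rdname Interactome-class
#' @param x an object.
#' @param ... passed to methods.
#' @export
setGeneric("interactomeGenes", function(x, ...)
    standardGeneric("interactomeGenes"))

#' @rdname Interactome-class
#' @export
setGeneric("geneDegree", function(x, ...) standardGeneric("geneDegree"))

#' @rdname Interactome-class
#' @export
setGeneric("numInteractions", function(x) standardGeneric("numInteractions"))

#' @rdname SampleCohort-class
#' @param x an object.
#' @param ... passed to methods.
#' @export
setGeneric("sampleInfo", function(x, ...) standardGeneric("sampleInfo"))

#' @rdname SampleCohort-class
#' @export
setGeneric("upregulatedGenes", function(x, ...)
    standardGeneric("upregulatedGenes"))

#' @rdname SampleCohort-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname PCADecomposition-class
#' @param x an object.
#' @param ... passed to methods.
#' @export
setGeneric("varianceProportions", function(x, ...)
    standardGeneric("varianceProportions"))

#' @rdname PCADecomposition-class
#' @export
setGeneric("pcaLoadings", function(x, ...) standardGeneric("pcaLoadings"))

#' @rdname PCADecomposition-class
#' @export
setGeneric("sampleCoordinates", function(x, ...)
    standardGeneric("sampleCoordinates"))

#' @rdname RFClassResult-class
#' @param x an object.
#' @param ... passed to methods.
#' @export
setGeneric("confusionMatrix", function(x, ...)
    standardGeneric("confusionMatrix"))

#' @rdname RFClassResult-class
#' @export
setGeneric("oobError", function(x, ...) standardGeneric("oobError"))

#' @rdname RFClassResult-class
#' @export
setGeneric("giniImportance", function(x, ...)
    standardGeneric("giniImportance"))

#' @rdname SubNetwork-class
#' @param x an object.
#' @param ... passed to methods.
#' @export
setGeneric("networkGenes", function(x, ...) standardGeneric("networkGenes"))

#' @rdname SubNetwork-class
#' @export
setGeneric("majorComponent", function(x, ...)
    standardGeneric("majorComponent"))

#' @rdname SubNetwork-class
#' @export
setGeneric("componentSizes", function(x, ...)
    standardGeneric("componentSizes"))

#' @rdname SubNetwork-class
#' @export
setGeneric("nodeInfo", function(x, ...) standardGeneric("nodeInfo"))

#' @rdname HubBoundary-class
#' @param x an object.
#' @param ... passed to methods.
#' @export
setGeneric("boundaryGenes", function(x, ...)
    standardGeneric("boundaryGenes"))
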