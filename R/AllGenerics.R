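#' @include AllClasses.R
NULL

#' Accessors for metaboclust objects
#'
#' @param x a metaboclust object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("processingState", function(x) standardGeneric("processingState"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("traitLabels", function(x) standardGeneric("traitLabels"))

#' @rdname accessors
#' @export
setGeneric("covariateData", function(x) standardGeneric("covariateData"))

#' @rdname accessors
#' @export
setGeneric("structureIds", function(x) standardGeneric("structureIds"))

#' @rdname accessors
#' @export
setGeneric("fingerprints", function(x) standardGeneric("fingerprints"))

#' @rdname accessors
#' @export
setGeneric("rejects", function(x) standardGeneric("rejects"))

#' @rdname accessors
#' @export
setGeneric("keyIndices", function(x) standardGeneric("keyIndices"))

#' @rdname accessors
#' @export
setGeneric("distanceIds", function(x) standardGeneric("distanceIds"))

#' @rdname accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("numberOfClusters", function(x) standardGeneric("numberOfClusters"))

#' @rdname accessors
#' @export
setGeneric("averageSilhouetteWidth",
           function(x) standardGeneric("averageSilhouetteWidth"))

#' @rdname accessors
#' @export
setGeneric("silhouetteValues", function(x) standardGeneric("silhouetteValues"))

#' @rdname accessors
#' @export
setGeneric("linkageTree", function(x) standardGeneric("linkageTree"))

#' @rdname accessors
#' @export
setGeneric("internalMetrics", function(x) standardGeneric("internalMetrics"))

#' @rdname accessors
#' @export
setGeneric("externalMetrics", function(x) standardGeneric("externalMetrics"))

#' @rdname accessors
#' @export
setGeneric("probabilityThreshold",
           function(x) standardGeneric("probabilityThreshold"))
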