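#' @rdname CompoundSet-accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("rawSmiles", function(x) standardGeneric("rawSmiles"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("curationFlags", function(x) standardGeneric("curationFlags"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' @rdname EndpointDataset-accessors
#' @export
setGeneric("endpointName", function(x) standardGeneric("endpointName"))

#' @rdname EndpointDataset-accessors
#' @export
setGeneric("nPos", function(x) standardGeneric("nPos"))

#' @rdname EndpointDataset-accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' @rdname EndpointDataset-accessors
#' @export
setGeneric("labels01", function(x) standardGeneric("labels01"))

#' @rdname EndpointDataset-accessors
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname TrainTestSplit-accessors
#' @export
setGeneric("trainSet", function(x) standardGeneric("trainSet"))

#' @rdname TrainTestSplit-accessors
#' @export
setGeneric("testSet", function(x) standardGeneric("testSet"))

#' @rdname EndpointModel-accessors
#' @export
setGeneric("modelMetrics", function(x) standardGeneric("modelMetrics"))

#' @rdname EndpointModel-accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname EndpointModel-accessors
#' @export
setGeneric("featureScheme", function(x) standardGeneric("featureScheme"))

#' @rdname MetabolitePanel-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname MetabolitePanel-accessors
#' @export
setGeneric("metaboliteSmiles", function(x) standardGeneric("metaboliteSmiles"))
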