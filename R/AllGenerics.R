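#' Accessors for ddifusion objects
#'
#' Small accessor generics used across the package: `nDrugs()` and
#' `drugIds()` for anything carrying a drug ordering, `eventTable()` and
#' `featureViews()` for datasets, `embedding()` and `attentionWeights()`
#' for fused embeddings, `modelConfig()` and `trainingHistory()` for fits.
#'
#' @param object a ddifusion S4 object.
#' @return the corresponding slot content (see each method).
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("nDrugs", function(object) standardGeneric("nDrugs"))

#' @rdname accessors
#' @export
setGeneric("drugIds", function(object) standardGeneric("drugIds"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("featureViews", function(object) standardGeneric("featureViews"))

#' @rdname accessors
#' @export
setGeneric("communities", function(object) standardGeneric("communities"))

#' @rdname accessors
#' @export
setGeneric("embedding", function(object) standardGeneric("embedding"))

#' @rdname accessors
#' @export
setGeneric("attentionWeights", function(object) standardGeneric("attentionWeights"))

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))

#' @rdname accessors
setMethod("nDrugs", "DDIDataset", function(object) length(object@drugIds))
#' @rdname accessors
setMethod("nDrugs", "DrugFeatureTable", function(object) nrow(object@X))
#' @rdname accessors
setMethod("drugIds", "DDIDataset", function(object) object@drugIds)
#' @rdname accessors
setMethod("drugIds", "DrugFeatureTable", function(object) object@drugIds)
#' @rdname accessors
setMethod("drugIds", "FusionFit", function(object) object@drugIds)
#' @rdname accessors
setMethod("eventTable", "DDIDataset", function(object) object@events)
#' @rdname accessors
setMethod("featureViews", "DDIDataset", function(object) object@views)
#' @rdname accessors
setMethod("communities", "DDIDataset", function(object) object@communities)
#' @rdname accessors
setMethod("embedding", "FusedEmbedding", function(object) object@E)
#' @rdname accessors
setMethod("attentionWeights", "FusedEmbedding", function(object)
  data.frame(attZ = object@attZ, attH = object@attH))
#' @rdname accessors
setMethod("modelConfig", "FusionFit", function(object) object@config)
#' @rdname accessors
setMethod("trainingHistory", "FusionFit", function(object) object@history)
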