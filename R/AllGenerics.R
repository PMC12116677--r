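#' @name coresel-accessors
#' @title Accessors for coresel classes
#' @description Slot access goes through these accessors rather than `@`.
#' @param x,object an object of the documented class
#' @return the corresponding component
NULL

#' @rdname coresel-accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname coresel-accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname coresel-accessors
#' @export
setGeneric("embDim", function(x) standardGeneric("embDim"))

#' @rdname coresel-accessors
#' @export
setGeneric("embMatrix", function(x) standardGeneric("embMatrix"))

#' @rdname coresel-accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname coresel-accessors
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @rdname coresel-accessors
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))

#' @rdname coresel-accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname coresel-accessors
#' @export
setGeneric("inertia", function(object) standardGeneric("inertia"))

#' @rdname coresel-accessors
#' @export
setGeneric("selectedIds", function(object) standardGeneric("selectedIds"))

#' @rdname coresel-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
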