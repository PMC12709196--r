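#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: node names,
#' roles, the underlying \pkg{igraph}, and the components of a
#' regularized network score.
#'
#' @param x an object.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname accessors
#' @export
setGeneric("nodeRoles", function(x) standardGeneric("nodeRoles"))

#' @rdname accessors
#' @export
setGeneric("sourceNodes", function(x) standardGeneric("sourceNodes"))

#' @rdname accessors
#' @export
setGeneric("targetNodes", function(x) standardGeneric("targetNodes"))

#' @rdname accessors
#' @export
setGeneric("internalNodes", function(x) standardGeneric("internalNodes"))

#' @rdname accessors
#' @export
setGeneric("nodeWeights", function(x) standardGeneric("nodeWeights"))

#' @rdname accessors
#' @export
setGeneric("pathCount", function(x) standardGeneric("pathCount"))

#' @rdname accessors
#' @export
setGeneric("retainedPaths", function(x) standardGeneric("retainedPaths"))

#' @rdname accessors
#' @export
setGeneric("networkScore", function(x) standardGeneric("networkScore"))

#' @rdname accessors
#' @export
setGeneric("scoreTerm", function(x) standardGeneric("scoreTerm"))

#' @rdname accessors
#' @export
setGeneric("avgDegree", function(x) standardGeneric("avgDegree"))

#' @rdname accessors
#' @export
setGeneric("lambdaValue", function(x) standardGeneric("lambdaValue"))

#' @rdname accessors
#' @export
setGeneric("implantedNodes", function(x) standardGeneric("implantedNodes"))
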