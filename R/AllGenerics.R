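#' @title Generics for sparse series containers
#' @description Accessor and pipeline generics shared by
#'   \linkS4class{SparseSeriesSet} and \linkS4class{SymbolicSeriesSet}.
#' @param x a container object
#' @param object a container object (for \code{classLabels})
#' @param feature a feature identifier
#' @param ... passed to methods
#' @name sshapelet-generics
NULL

#' @rdname sshapelet-generics
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname sshapelet-generics
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname sshapelet-generics
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname sshapelet-generics
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname sshapelet-generics
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname sshapelet-generics
#' @export
setGeneric("records", function(x, feature) standardGeneric("records"))

#' @rdname sshapelet-generics
#' @export
setGeneric("sparsityFraction", function(x, feature) standardGeneric("sparsityFraction"))

#' @rdname sshapelet-generics
#' @export
setGeneric("discretize", function(x, ...) standardGeneric("discretize"))
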