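#' Accessors for cbnDiff classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a cbnDiff object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variables", function(object) standardGeneric("variables"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' @rdname accessors
#' @export
setGeneric("noiseSd", function(object) standardGeneric("noiseSd"))

#' @rdname accessors
#' @export
setGeneric("dagOf", function(object) standardGeneric("dagOf"))

#' @rdname accessors
#' @export
setGeneric("graph1", function(object) standardGeneric("graph1"))

#' @rdname accessors
#' @export
setGeneric("graph2", function(object) standardGeneric("graph2"))

#' @rdname accessors
#' @export
setGeneric("deletedEdges", function(object) standardGeneric("deletedEdges"))

#' @rdname accessors
#' @export
setGeneric("addedEdges", function(object) standardGeneric("addedEdges"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("scoreMode", function(object) standardGeneric("scoreMode"))

#' @rdname accessors
#' @export
setGeneric("scoreMethod", function(object) standardGeneric("scoreMethod"))

#' @rdname accessors
#' @export
setGeneric("resampleCount", function(object) standardGeneric("resampleCount"))
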