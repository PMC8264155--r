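#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("nodeSeqs", function(x) standardGeneric("nodeSeqs"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("graphPaths", function(x) standardGeneric("graphPaths"))
#' @rdname accessors
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("edgeClasses", function(x) standardGeneric("edgeClasses"))

#' Accessors for BidirectedGraph and Linearization
#'
#' \code{nodeIds}, \code{nodeSeqs}, \code{graphEdges} and \code{graphPaths}
#' extract the components of a \linkS4class{BidirectedGraph};
#' \code{orientations}, \code{positions} and \code{edgeClasses} extract those
#' of a \linkS4class{Linearization}.
#'
#' @param x a \linkS4class{BidirectedGraph} or \linkS4class{Linearization}.
#' @return The requested component (vector, data.frame or list).
#' @name accessors
#' @aliases nodeIds nodeSeqs graphEdges graphPaths orientations positions
#'   edgeClasses
NULL

#' @rdname accessors
setMethod("nodeIds", "BidirectedGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("nodeSeqs", "BidirectedGraph",
          function(x) stats::setNames(x@sequences, x@nodes))
#' @rdname accessors
setMethod("graphEdges", "BidirectedGraph", function(x) x@edges)
#' @rdname accessors
setMethod("graphPaths", "BidirectedGraph", function(x) x@paths)
#' @rdname accessors
setMethod("orientations", "Linearization", function(x) x@orientation)
#' @rdname accessors
setMethod("positions", "Linearization", function(x) x@position)
#' @rdname accessors
setMethod("edgeClasses", "Linearization", function(x) x@edgeClasses)
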