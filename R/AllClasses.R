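#' @import methods
NULL

# Canonical edge table columns. Sides are "L"/"R"; an edge is stored once, with
# endpoint (from, fromSide) <= (to, toSide) under C-locale ordering.
.edgeCols <- c("from", "fromSide", "to", "toSide", "weight")

.emptyEdges <- function() {
  data.frame(from = character(), fromSide = character(),
             to = character(), toSide = character(),
             weight = numeric(), stringsAsFactors = FALSE)
}

#' BidirectedGraph: a genome sequence graph
#'
#' A bidirected graph in which every node has a left and a right side
#' (the 5' and 3' ends of its DNA label) and each edge endpoint attaches to
#' one specific side. Genome paths traverse nodes with a strand, entering on
#' one side and leaving on the other; edge weights count path traversals.
#'
#' @slot nodes character vector of node identifiers, in input order.
#' @slot sequences character vector of DNA labels parallel to \code{nodes}
#'   (may be empty strings for weight-only analyses).
#' @slot edges data.frame with columns \code{from, fromSide, to, toSide,
#'   weight}; one row per canonical edge, sides in \code{c("L","R")}.
#' @slot paths list of genome paths; each a list with elements \code{name},
#'   \code{nodes} (character) and \code{strands} (\code{"+"}/\code{"-"}).
#' @slot metadata free-form list (e.g. segment coordinates for simulated
#'   graphs).
#'
#' @exportClass BidirectedGraph
setClass("BidirectedGraph",
  representation(nodes = "character", sequences = "character",
                 edges = "data.frame", paths = "list", metadata = "list"),
  prototype(nodes = character(), sequences = character(),
            edges = .emptyEdges(), paths = list(), metadata = list()))

setValidity("BidirectedGraph", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "node ids must be unique")
  if (length(object@sequences) != length(object@nodes))
    msg <- c(msg, "sequences must be parallel to nodes")
  e <- object@edges
  if (!all(.edgeCols %in% names(e)))
    msg <- c(msg, "edges must have columns from, fromSide, to, toSide, weight")
  else {
    if (nrow(e)) {
      if (!all(c(e$fromSide, e$toSide) %in% c("L", "R")))
        msg <- c(msg, "edge sides must be 'L' or 'R'")
      if (!all(c(e$from, e$to) %in% object@nodes))
        msg <- c(msg, "edge endpoints must reference declared nodes")
      if (any(e$weight < 0)) msg <- c(msg, "edge weights must be non-negative")
      keys <- .edgeKeys(e)
      if (anyDuplicated(keys)) msg <- c(msg, "duplicate canonical edges")
      ka <- paste(e$from, e$fromSide, sep = "\t")
      kb <- paste(e$to, e$toSide, sep = "\t")
      if (any(.radixGreater(ka, kb)))
        msg <- c(msg, "edges must be stored in canonical endpoint order")
    }
  }
  for (p in object@paths) {
    if (!all(c("name", "nodes", "strands") %in% names(p))) {
      msg <- c(msg, "each path needs name, nodes, strands"); next
    }
    if (!all(p$nodes %in% object@nodes))
      msg <- c(msg, sprintf("path '%s' visits undeclared nodes", p$name))
    if (length(p$nodes) != length(p$strands) ||
        !all(p$strands %in% c("+", "-")))
      msg <- c(msg, sprintf("path '%s' has malformed strands", p$name))
  }
  if (length(msg)) msg else TRUE
})

#' Linearization of a bidirected graph
#'
#' A joint orientation and ordering of graph nodes: \code{orientation} maps
#' each node to +1/-1 (which strand of its label is primary, hence which side
#' is the in-side), and \code{position} is a bijection onto 1..|V|. Each edge
#' is classified, relative to (orientation, position), as a forward arc, a
#' feedback arc or a reversing join.
#'
#' @slot orientation named integer vector in \{-1, 1\}, one entry per node.
#' @slot position named integer vector; a bijection onto 1..|V|.
#' @slot edgeClasses character vector named by canonical edge keys, values in
#'   \code{c("forward_arc","feedback_arc","reversing_join")}.
#' @slot crossComponent logical vector parallel to \code{edgeClasses}: whether
#'   the edge bridged two components at its insertion moment (only meaningful
#'   for linearizations produced incrementally; empty otherwise).
#'
#' @exportClass Linearization
setClass("Linearization",
  representation(orientation = "integer", position = "integer",
                 edgeClasses = "character", crossComponent = "logical"),
  prototype(orientation = integer(), position = integer(),
            edgeClasses = character(), crossComponent = logical()))

setValidity("Linearization", function(object) {
  msg <- character()
  n <- length(object@orientation)
  if (length(object@position) != n)
    msg <- c(msg, "orientation and position must cover the same nodes")
  if (n) {
    if (is.null(names(object@orientation)) || is.null(names(object@position)))
      msg <- c(msg, "orientation and position must be named")
    else if (!setequal(names(object@orientation), names(object@position)))
      msg <- c(msg, "orientation and position names must agree")
    if (!all(object@orientation %in% c(-1L, 1L)))
      msg <- c(msg, "orientations must be -1 or 1")
    if (!identical(sort(as.integer(object@position)), seq_len(n)))
      msg <- c(msg, "positions must be a bijection onto 1..|V|")
  }
  if (length(object@crossComponent) &&
      length(object@crossComponent) != length(object@edgeClasses))
    msg <- c(msg, "crossComponent must be parallel to edgeClasses")
  bad <- setdiff(unique(object@edgeClasses),
                 c("forward_arc", "feedback_arc", "reversing_join"))
  if (length(bad)) msg <- c(msg, "unknown edge class")
  if (length(msg)) msg else TRUE
})

#' Construct a BidirectedGraph
#'
#' @param nodes character vector of node ids.
#' @param sequences DNA labels parallel to \code{nodes}; defaults to empty.
#' @param edges data.frame with columns \code{from, fromSide, to, toSide} and
#'   optionally \code{weight}; rows are canonicalized and duplicates collapsed.
#' @param paths list of paths (\code{name}, \code{nodes}, \code{strands}).
#' @param metadata optional list.
#' @return A \linkS4class{BidirectedGraph}.
#' @export
BidirectedGraph <- function(nodes, sequences = NULL, edges = NULL,
                            paths = list(), metadata = list()) {
  nodes <- as.character(nodes)
  if (is.null(sequences)) sequences <- rep("", length(nodes))
  if (is.null(edges) || !nrow(edges)) edges <- .emptyEdges()
  else {
    if (is.null(edges$weight)) edges$weight <- 1
    edges <- canonicalEdges(edges)
  }
  new("BidirectedGraph", nodes = nodes, sequences = as.character(sequences),
      edges = edges, paths = paths, metadata = metadata)
}

#' Construct a Linearization
#'
#' @param orientation named vector of +1/-1 per node.
#' @param position named vector of 1-based positions per node.
#' @param edgeClasses optional named character vector of edge classes.
#' @param crossComponent optional logical vector parallel to edgeClasses.
#' @return A \linkS4class{Linearization}.
#' @export
Linearization <- function(orientation, position, edgeClasses = character(),
                          crossComponent = logical()) {
  new("Linearization",
      orientation = stats::setNames(as.integer(orientation),
                                    names(orientation)),
      position = stats::setNames(as.integer(position), names(position)),
      edgeClasses = edgeClasses, crossComponent = crossComponent)
}

setMethod("show", "BidirectedGraph", function(object) {
  cat(sprintf("BidirectedGraph: %d nodes, %d edges, %d paths\n",
              length(object@nodes), nrow(object@edges),
              length(object@paths)))
  if (nrow(object@edges))
    cat(sprintf("  total edge weight: %g\n", sum(object@edges$weight)))
})

setMethod("show", "Linearization", function(object) {
  cat(sprintf("Linearization of %d nodes\n", length(object@position)))
  if (length(object@edgeClasses)) {
    tab <- table(factor(object@edgeClasses,
                        levels = c("forward_arc", "feedback_arc",
                                   "reversing_join")))
    cat(sprintf("  forward: %d, feedback: %d, reversing: %d\n",
                tab[[1]], tab[[2]], tab[[3]]))
  }
})
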