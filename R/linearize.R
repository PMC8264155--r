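# Side sign: right side = +1, left side = -1.  An edge endpoint attached to
# side s of a node with actual orientation A is an out-side endpoint iff
# sign(s) * A == +1 (orientation +1 labels the right side as out-side).
.sideSign <- function(side) ifelse(side == "R", 1L, -1L)

#' Deterministic processing order of edges
#'
#' Edges sorted by descending weight; ties broken by the canonical edge key
#' in ascending C-collation order, so the order is stable across runs and
#' platforms.
#'
#' @param graph a \linkS4class{BidirectedGraph} with weights assigned.
#' @return Integer vector of row indices into \code{graphEdges(graph)}.
#' @export
sortEdges <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) return(integer())
  order(-e$weight, .edgeKeys(e), method = "radix")
}

# Depth-first search over forward arcs restricted to a position window.
# direction "out": nodes reachable from start via outgoing forward arcs with
# position <= posHi (the affected-region forward set); direction "in": nodes
# reaching start via forward arcs, position >= posLo (the backward set).
# Never expands a node outside [posLo, posHi].  A node's outgoing arcs are
# those attached to its current out-side (right side iff its actual
# orientation is +1); incoming arcs sit on the other side.  If `abortAt` is
# reached the search stops immediately and `aborted` is TRUE (used to detect
# that the in-side node can reach the out-side node, forcing a feedback arc).
forwardDfsRegion <- function(st, start, posLo, posHi, direction = c("out", "in"),
                             abortAt = NA_integer_) {
  direction <- match.arg(direction)
  visited <- integer(0)
  seen <- new.env(parent = emptyenv())
  stack <- start
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    key <- as.character(v)
    if (!is.null(seen[[key]])) next
    f <- linStateFind(st, v)
    if (f$pos < posLo || f$pos > posHi) next
    seen[[key]] <- TRUE
    if (!is.na(abortAt) && v == abortAt)
      return(list(nodes = visited, aborted = TRUE))
    visited <- c(visited, v)
    useRight <- if (direction == "out") f$orient == 1L else f$orient == -1L
    nb <- if (useRight) st$adjR[[v]] else st$adjL[[v]]
    if (length(nb)) stack <- c(stack, nb)
  }
  list(nodes = visited, aborted = FALSE)
}

# Dynamic topological repair for a new arc out(v2) -> in(v1) where v1
# currently precedes v2.  Computes the forward set V_F (nodes forward-
# reachable from v1 within the affected position window) and the backward
# set V_B (nodes reaching v2 within the window), then pools their positions
# and reassigns them so that all V_B-nodes precede all V_F-nodes with the
# original relative order preserved inside each set.  Positions of all other
# nodes are untouched.  If v2 turns out to be forward-reachable from v1 the
# new arc closes a cycle: the state is left unchanged and "feedback" is
# returned.
pearceKellyReorder <- function(st, v1, v2) {
  f1 <- linStateFind(st, v1); f2 <- linStateFind(st, v2)
  if (f1$root != f2$root) stop("nodes must share a component")
  if (f1$pos >= f2$pos) stop("expected ord(v1) < ord(v2)")
  lo <- f1$pos; hi <- f2$pos
  fwd <- forwardDfsRegion(st, v1, lo, hi, "out", abortAt = v2)
  if (fwd$aborted) return("feedback")
  VF <- fwd$nodes
  VB <- forwardDfsRegion(st, v2, lo, hi, "in")$nodes
  posF <- vapply(VF, function(v) linStateFind(st, v)$pos, 0)
  posB <- vapply(VB, function(v) linStateFind(st, v)$pos, 0)
  VF <- VF[order(posF)]; posF <- sort(posF)
  VB <- VB[order(posB)]; posB <- sort(posB)
  pooled <- sort(c(posF, posB))
  linStateReposition(st, c(VB, VF), pooled)
  "reordered"
}

# Insert one edge into the incremental state, classify it, and update the
# forest / forward adjacency.  Endpoints are internal node indices with
# sides "L"/"R" in canonical order.  Returns list(class, crossComponent).
addEdge <- function(st, from, fromSide, to, toSide) {
  record <- function() {   # attach the new forward arc by endpoint side
    if (fromSide == "R") st$adjR[[from]] <- c(st$adjR[[from]], to)
    else st$adjL[[from]] <- c(st$adjL[[from]], to)
    if (toSide == "R") st$adjR[[to]] <- c(st$adjR[[to]], from)
    else st$adjL[[to]] <- c(st$adjL[[to]], from)
  }
  fa <- linStateFind(st, from)
  fb <- linStateFind(st, to)
  outA <- .sideSign(fromSide) * fa$orient == 1L
  outB <- .sideSign(toSide) * fb$orient == 1L

  if (fa$root != fb$root) {
    nA <- st$csize[fa$root]; nB <- st$csize[fb$root]
    if (outA != outB) {
      # rule 1a: out-side node's component precedes, nothing reversed
      if (outA)
        linStateUnion(st, fa$root, fb$root, 1, 0, 1, nA)
      else
        linStateUnion(st, fb$root, fa$root, 1, 0, 1, nB)
    } else {
      # rule 1b: reverse the canonical second endpoint's component, then
      # merge with the out-side node's component first
      if (outA)           # both out: `to` reversed becomes in; `from` first
        linStateUnion(st, fa$root, fb$root, 1, 0, -1, nA + nB + 1)
      else                # both in: `to` reversed becomes out; it goes first
        linStateUnion(st, fb$root, fa$root, -1, nB + 1, 1, nB)
    }
    record()
    return(list(class = "forward_arc", crossComponent = TRUE))
  }

  # same component
  if (outA == outB)
    return(list(class = "reversing_join", crossComponent = FALSE))
  x <- if (outA) from else to    # out-side node
  y <- if (outA) to else from    # in-side node
  if (x == y)                    # out/in self-edge: ord(x) < ord(x) impossible
    return(list(class = "feedback_arc", crossComponent = FALSE))
  px <- if (outA) fa$pos else fb$pos
  py <- if (outA) fb$pos else fa$pos
  if (px < py) {
    record()
    return(list(class = "forward_arc", crossComponent = FALSE))
  }
  # in-side node precedes the out-side node: try to reorder
  if (pearceKellyReorder(st, y, x) == "feedback")
    return(list(class = "feedback_arc", crossComponent = FALSE))
  record()
  list(class = "forward_arc", crossComponent = FALSE)
}

# Concatenate per-component orders into one global layout: components are
# placed in order of their smallest node index (parse order), singletons
# included.
.globalLayout <- function(root, pos) {
  comps <- split(seq_along(root), root)
  minIdx <- vapply(comps, min, 0L)
  comps <- comps[order(minIdx)]
  offset <- 0
  out <- numeric(length(root))
  for (members in comps) {
    out[members] <- offset + pos[members]
    offset <- offset + length(members)
  }
  out
}

#' Linearize a genome sequence graph incrementally
#'
#' Builds the linearized graph by inserting edges in decreasing weight order
#' (ties broken deterministically, see \code{\link{sortEdges}}). Each edge is
#' classified on insertion: edges bridging two components are always made
#' forward arcs (reversing one component when it joins two like sides);
#' within a component, like-sided edges become reversing joins, an out-to-in
#' edge pointing forward is a forward arc, one whose target already reaches
#' its source through forward arcs is a feedback arc, and otherwise the
#' component is locally reordered (dynamic topological repair) so the edge
#' becomes forward. Earlier classifications are never invalidated by later
#' insertions. Components are finally concatenated in order of their smallest
#' node index.
#'
#' @param graph a \linkS4class{BidirectedGraph} with weights assigned.
#' @return A \linkS4class{Linearization} with per-edge classes (named by
#'   canonical edge keys) and the cross-component flag recorded at each
#'   edge's insertion moment.
#' @export
linearizeGraph <- function(graph) {
  n <- length(graph@nodes)
  if (!n) stop("cannot linearize an empty graph")
  st <- linStateNew(graph@nodes)
  e <- graph@edges
  ord <- sortEdges(graph)
  classes <- character(nrow(e))
  cross <- logical(nrow(e))
  if (nrow(e)) {
    fromIdx <- match(e$from, graph@nodes)
    toIdx <- match(e$to, graph@nodes)
    for (i in ord) {
      res <- addEdge(st, fromIdx[i], e$fromSide[i], toIdx[i], e$toSide[i])
      classes[i] <- res$class
      cross[i] <- res$crossComponent
    }
  }
  obs <- linStateAll(st)
  gpos <- .globalLayout(obs$root, obs$pos)
  keys <- .edgeKeys(e)
  Linearization(
    orientation = stats::setNames(obs$orient, graph@nodes),
    position = stats::setNames(as.integer(gpos), graph@nodes),
    edgeClasses = stats::setNames(classes, keys),
    crossComponent = stats::setNames(cross, keys))
}
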