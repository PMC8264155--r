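# Reference implementations used by the test-suite only (not exported).
#
# naiveGreedy transcribes the incremental insertion rules over explicit
# orientation/position arrays, with whole-component rewrites at every merge
# and explicit breadth-first reachability for the reordering case; it must
# match linearizeGraph() bit for bit when given the same edge order.
# exhaustiveBest enumerates every orientation and order of a tiny graph and
# returns the optimum, the ground truth the greedy heuristic is compared
# against.

naiveGreedy <- function(graph, edgeOrder = sortEdges(graph)) {
  n <- length(graph@nodes)
  if (!n) stop("cannot linearize an empty graph")
  e <- graph@edges
  comp <- seq_len(n)
  orient <- rep(1L, n)
  pos <- rep(1, n)
  adjL <- vector("list", n)     # forward arcs by attachment side
  adjR <- vector("list", n)
  classes <- character(nrow(e))
  cross <- logical(nrow(e))
  fromIdx <- match(e$from, graph@nodes)
  toIdx <- match(e$to, graph@nodes)

  record <- function(i) {       # attach edge i's endpoints by side
    if (e$fromSide[i] == "R")
      adjR[[fromIdx[i]]] <<- c(adjR[[fromIdx[i]]], toIdx[i])
    else adjL[[fromIdx[i]]] <<- c(adjL[[fromIdx[i]]], toIdx[i])
    if (e$toSide[i] == "R")
      adjR[[toIdx[i]]] <<- c(adjR[[toIdx[i]]], fromIdx[i])
    else adjL[[toIdx[i]]] <<- c(adjL[[toIdx[i]]], fromIdx[i])
  }
  reach <- function(start, lo, hi, dirOut, stopAt = NA_integer_) {
    seen <- rep(FALSE, n)
    stack <- start
    found <- integer(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[v] || pos[v] < lo || pos[v] > hi) next
      seen[v] <- TRUE
      if (!is.na(stopAt) && v == stopAt)
        return(list(nodes = found, aborted = TRUE))
      found <- c(found, v)
      useRight <- if (dirOut) orient[v] == 1L else orient[v] == -1L
      stack <- c(stack, if (useRight) adjR[[v]] else adjL[[v]])
    }
    list(nodes = found, aborted = FALSE)
  }

  for (i in edgeOrder) {
    u <- fromIdx[i]; v <- toIdx[i]
    outU <- .sideSign(e$fromSide[i]) * orient[u] == 1L
    outV <- .sideSign(e$toSide[i]) * orient[v] == 1L
    if (comp[u] != comp[v]) {
      mA <- which(comp == comp[u]); mB <- which(comp == comp[v])
      nA <- length(mA); nB <- length(mB)
      if (outU != outV) {
        if (outU) pos[mB] <- pos[mB] + nA else pos[mA] <- pos[mA] + nB
      } else if (outU) {          # both out: reverse `to`'s component, after
        pos[mB] <- nA + nB + 1 - pos[mB]
        orient[mB] <- -orient[mB]
      } else {                    # both in: reverse `to`'s component, first
        pos[mB] <- nB + 1 - pos[mB]
        orient[mB] <- -orient[mB]
        pos[mA] <- pos[mA] + nB
      }
      comp[mB] <- comp[u][1L]
      record(i)
      classes[i] <- "forward_arc"; cross[i] <- TRUE
      next
    }
    if (outU == outV) { classes[i] <- "reversing_join"; next }
    x <- if (outU) u else v       # out-side node
    y <- if (outU) v else u       # in-side node
    if (x == y) { classes[i] <- "feedback_arc"; next }
    if (pos[x] < pos[y]) {
      record(i)
      classes[i] <- "forward_arc"
      next
    }
    lo <- pos[y]; hi <- pos[x]
    fwd <- reach(y, lo, hi, dirOut = TRUE, stopAt = x)
    if (fwd$aborted) { classes[i] <- "feedback_arc"; next }
    VF <- fwd$nodes
    VB <- reach(x, lo, hi, dirOut = FALSE)$nodes
    VF <- VF[order(pos[VF])]
    VB <- VB[order(pos[VB])]
    pooled <- sort(pos[c(VF, VB)])
    pos[c(VB, VF)] <- pooled
    record(i)
    classes[i] <- "forward_arc"
  }

  gpos <- .globalLayout(comp, pos)
  keys <- .edgeKeys(e)
  Linearization(
    orientation = stats::setNames(orient, graph@nodes),
    position = stats::setNames(as.integer(gpos), graph@nodes),
    edgeClasses = stats::setNames(classes, keys),
    crossComponent = stats::setNames(cross, keys))
}

# All permutations of 1..n, rows in lexicographic order.
.permsLex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permsLex(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Exhaustive optimal linearization of a tiny graph (|V| <= 8).  Enumerates
# 2^(|V|-1) orientations (the first node is fixed to +1: all metrics are
# invariant under global reversal) times |V|! orders; returns the minimum of
# the requested objective with deterministic enumeration-order tie-breaking.
exhaustiveBest <- function(graph, objective = c("sum", "lex")) {
  objective <- match.arg(objective)
  n <- length(graph@nodes)
  if (n > 8L) stop("exhaustive search is guarded to |V| <= 8")
  e <- graph@edges
  w <- e$weight
  fromIdx <- match(e$from, graph@nodes)
  toIdx <- match(e$to, graph@nodes)
  sFrom <- .sideSign(e$fromSide); sTo <- .sideSign(e$toSide)
  perms <- .permsLex(n)                 # row r: position of node j
  best <- NULL
  for (b in seq_len(2^(n - 1L)) - 1L) {
    a <- rep(1L, n)
    if (n > 1L)
      a[-1L] <- ifelse(bitwAnd(b, 2L^(seq_len(n - 1L) - 1L)) > 0L, -1L, 1L)
    outFrom <- sFrom * a[fromIdx] == 1L
    outTo <- sTo * a[toIdx] == 1L
    rj <- outFrom == outTo
    wrj0 <- sum(w[rj])
    selfFb <- !rj & fromIdx == toIdx
    wfa0 <- sum(w[selfFb])
    d <- which(!rj & fromIdx != toIdx)
    if (length(d)) {
      o <- ifelse(outFrom[d], fromIdx[d], toIdx[d])
      i2 <- ifelse(outFrom[d], toIdx[d], fromIdx[d])
      fb <- perms[, o, drop = FALSE] > perms[, i2, drop = FALSE]
      wfaVec <- as.numeric(fb %*% w[d]) + wfa0
    } else wfaVec <- rep(wfa0, nrow(perms))
    r <- which.min(wfaVec)              # first minimum = enumeration order
    cand <- list(wrj = wrj0, wfa = wfaVec[r], a = a, pos = perms[r, ])
    if (is.null(best) || .betterScore(cand, best, objective)) best <- cand
  }
  lin <- Linearization(
    orientation = stats::setNames(best$a, graph@nodes),
    position = stats::setNames(as.integer(best$pos), graph@nodes))
  lin@edgeClasses <- classifyEdges(graph, lin)
  list(lin = lin, wrj = best$wrj, wfa = best$wfa)
}

.betterScore <- function(cand, best, objective) {
  if (objective == "sum")
    return(cand$wrj + cand$wfa < best$wrj + best$wfa)
  cand$wrj < best$wrj || (cand$wrj == best$wrj && cand$wfa < best$wfa)
}
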