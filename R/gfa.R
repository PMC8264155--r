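# Locale-independent string comparison (C collation via radix ordering):
# returns a > b elementwise. Radix order is stable, so ties (a == b) land
# in input order and compare as not-greater.
.radixGreater <- function(a, b) {
  n <- length(a)
  if (!n) return(logical())
  x <- c(a, b)
  o <- order(x, method = "radix")
  r <- integer(2L * n)
  r[o] <- seq_len(2L * n)
  r[seq_len(n)] > r[n + seq_len(n)]
}

.edgeKeys <- function(e) paste(e$from, e$fromSide, e$to, e$toSide, sep = "\t")

#' Canonicalize an edge table
#'
#' Sorts each edge's endpoints by (node id, side) under C collation so that
#' \code{(v,s,v',s')} and \code{(v',s',v,s)} are the same edge, and collapses
#' duplicate rows (keeping the first).
#'
#' @param edges data.frame with columns \code{from, fromSide, to, toSide} and
#'   optionally \code{weight}.
#' @return The canonical data.frame, duplicates removed, input order kept.
#' @export
canonicalEdges <- function(edges) {
  if (!nrow(edges)) return(.emptyEdges())
  if (is.null(edges$weight)) edges$weight <- 1
  edges$weight <- as.numeric(edges$weight)
  ka <- paste(edges$from, edges$fromSide, sep = "\t")
  kb <- paste(edges$to, edges$toSide, sep = "\t")
  swap <- .radixGreater(ka, kb)
  if (any(swap)) {
    tmpN <- edges$from[swap]; tmpS <- edges$fromSide[swap]
    edges$from[swap] <- edges$to[swap]
    edges$fromSide[swap] <- edges$toSide[swap]
    edges$to[swap] <- tmpN; edges$toSide[swap] <- tmpS
  }
  edges <- edges[!duplicated(.edgeKeys(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  edges[, .edgeCols]
}

#' Reverse complement of a DNA sequence
#'
#' Complement (A<->T, C<->G, N unchanged) and reverse; case-insensitive input,
#' upper-case output. An involution: \code{revComp(revComp(s)) == s}.
#'
#' @param seq a single DNA string over \{A,C,G,T,N\}.
#' @return The reverse complement string.
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return("")
  bad <- regexpr("[^ACGTNacgtn]", seq)
  if (bad > 0L)
    stop(sprintf("illegal character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(seq))))
}

# Side convention tying GFA strands to bidirected sides: a path leaves a
# '+' visit on the right side and enters it on the left (and conversely for
# '-'). An L line "from fs to ts" therefore attaches to the right of `from`
# when fs == '+' (left when '-') and to the left of `to` when ts == '+'.
.linkSides <- function(fromStrand, toStrand) {
  list(fromSide = ifelse(fromStrand == "+", "R", "L"),
       toSide   = ifelse(toStrand == "+", "L", "R"))
}

# Canonical edge keys induced by consecutive path visits.
.pathAdjacencyKeys <- function(p) {
  k <- length(p$nodes)
  if (k < 2L) return(character())
  i <- seq_len(k - 1L)
  s <- .linkSides(p$strands[i], p$strands[i + 1L])
  e <- data.frame(from = p$nodes[i], fromSide = s$fromSide,
                  to = p$nodes[i + 1L], toSide = s$toSide,
                  weight = 1, stringsAsFactors = FALSE)
  ka <- paste(e$from, e$fromSide, sep = "\t")
  kb <- paste(e$to, e$toSide, sep = "\t")
  swap <- .radixGreater(ka, kb)
  key <- ifelse(swap, paste(kb, ka, sep = "\t"), paste(ka, kb, sep = "\t"))
  key
}

#' Derive edge weights from path traversals
#'
#' Sets each edge's weight to the number of times it is traversed by the
#' graph's paths (either direction of the same bidirected edge counts). When
#' the graph has no paths at all, every edge gets weight 1; when paths exist,
#' edges traversed by no path get weight 0.
#'
#' @param graph a \linkS4class{BidirectedGraph}.
#' @return The graph with updated edge weights.
#' @export
computeEdgeWeights <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) return(graph)
  if (!length(graph@paths)) {
    e$weight <- 1
    graph@edges <- e
    return(graph)
  }
  keys <- .edgeKeys(e)
  adj <- unlist(lapply(graph@paths, .pathAdjacencyKeys), use.names = FALSE)
  miss <- setdiff(unique(adj), keys)
  if (length(miss))
    stop("path adjacencies with no matching edge: ",
         paste(gsub("\t", ":", miss), collapse = ", "))
  tab <- table(factor(adj, levels = keys))
  e$weight <- as.numeric(tab)
  graph@edges <- e
  graph
}

#' Read a GFA1 genome sequence graph
#'
#' Parses S (segment), L (link) and P (path) lines. Links are canonicalized
#' into bidirected edges (duplicates collapse); edge weights are derived from
#' path traversals via \code{\link{computeEdgeWeights}} unless a numeric link
#' tag is designated through \code{weightTag}. GFA2 documents and W lines are
#' rejected; other record types are skipped with a warning.
#'
#' @param file path to a GFA1 file.
#' @param text optional character vector of GFA lines (overrides \code{file}).
#' @param weightTag optional name of a numeric L-line tag (e.g. \code{"RC"})
#'   whose values override path-derived weights.
#' @return A \linkS4class{BidirectedGraph}.
#' @export
readGFA <- function(file, text = NULL, weightTag = NULL) {
  lines <- if (is.null(text)) readLines(file) else text
  lines <- lines[nzchar(lines)]
  recs <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(recs, `[`, "", 1L)

  if (any(types == "W"))
    stop("W lines are GFA1.1 walks; only GFA1 S/L/P records are supported")
  for (i in which(types == "H")) {
    if (any(grepl("^VN:Z:2", recs[[i]][-1L])))
      stop("GFA2 input is not supported; provide GFA1 (S/L/P)")
  }
  if (any(types %in% c("E", "G", "F", "O", "U")))
    stop("GFA2 record types found; only GFA1 S/L/P records are supported")
  other <- setdiff(unique(types), c("S", "L", "P", "H"))
  if (length(other))
    warning("skipping unsupported GFA record types: ",
            paste(other, collapse = ", "))

  sIdx <- which(types == "S")
  nodes <- character(length(sIdx)); seqs <- character(length(sIdx))
  for (j in seq_along(sIdx)) {
    f <- recs[[sIdx[j]]]
    if (length(f) < 3L)
      stop(sprintf("malformed S line %d: expected 'S\tid\tseq'", sIdx[j]))
    nodes[j] <- f[2L]
    seqs[j] <- if (f[3L] == "*") "" else toupper(f[3L])
  }
  if (anyDuplicated(nodes)) stop("duplicate segment ids in S lines")
  known <- stats::setNames(rep(TRUE, length(nodes)), nodes)

  lIdx <- which(types == "L")
  ef <- et <- efs <- ets <- character(length(lIdx))
  ew <- rep(NA_real_, length(lIdx))
  for (j in seq_along(lIdx)) {
    f <- recs[[lIdx[j]]]
    if (length(f) < 5L)
      stop(sprintf("malformed L line %d: expected at least 5 fields", lIdx[j]))
    if (!f[3L] %in% c("+", "-") || !f[5L] %in% c("+", "-"))
      stop(sprintf("malformed strand symbol on L line %d", lIdx[j]))
    if (is.na(known[f[2L]]) || is.na(known[f[4L]]))
      stop(sprintf("L line %d references unknown segment '%s'", lIdx[j],
                   if (is.na(known[f[2L]])) f[2L] else f[4L]))
    ef[j] <- f[2L]; et[j] <- f[4L]
    s <- .linkSides(f[3L], f[5L])
    efs[j] <- s$fromSide; ets[j] <- s$toSide
    if (!is.null(weightTag) && length(f) > 5L) {
      hit <- grep(paste0("^", weightTag, ":i:"), f[-seq_len(5L)], value = TRUE)
      if (length(hit))
        ew[j] <- as.numeric(sub(paste0("^", weightTag, ":i:"), "", hit[1L]))
    }
  }
  edges <- canonicalEdges(data.frame(
    from = ef, fromSide = efs, to = et, toSide = ets,
    weight = ifelse(is.na(ew), 1, ew), stringsAsFactors = FALSE))

  paths <- list()
  for (i in which(types == "P")) {
    f <- recs[[i]]
    if (length(f) < 3L)
      stop(sprintf("malformed P line %d", i))
    vis <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
    strands <- substring(vis, nchar(vis))
    ids <- substring(vis, 1L, nchar(vis) - 1L)
    if (!all(strands %in% c("+", "-")))
      stop(sprintf("malformed strand symbol on P line %d", i))
    if (any(is.na(known[ids])))
      stop(sprintf("P line %d references unknown segment '%s'", i,
                   ids[which(is.na(known[ids]))[1L]]))
    paths[[length(paths) + 1L]] <-
      list(name = f[2L], nodes = ids, strands = strands)
  }

  g <- new("BidirectedGraph", nodes = nodes, sequences = seqs,
           edges = edges, paths = paths, metadata = list())
  useTag <- !is.null(weightTag) && length(lIdx) && all(!is.na(ew))
  if (useTag) g else computeEdgeWeights(g)
}

#' Write a graph as GFA1, optionally applying a linearization
#'
#' Without \code{lin}, records are emitted in input order. With \code{lin},
#' S lines are emitted in increasing position; nodes with orientation -1 are
#' written with reverse-complemented sequence and every L/P reference to them
#' has its strand flipped, so each path spells the identical DNA string before
#' and after rewriting.
#'
#' @param graph a \linkS4class{BidirectedGraph}.
#' @param file optional output path; when NULL the lines are returned.
#' @param lin optional \linkS4class{Linearization} covering all nodes.
#' @return Invisibly (or visibly when \code{file} is NULL), the GFA lines.
#' @export
writeGFA <- function(graph, file = NULL, lin = NULL) {
  nodes <- graph@nodes; seqs <- graph@sequences
  flip <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  ord <- seq_along(nodes)
  if (!is.null(lin)) {
    miss <- setdiff(nodes, names(lin@position))
    if (length(miss))
      stop("linearization missing nodes: ", paste(miss, collapse = ", "))
    flip[nodes] <- lin@orientation[nodes] == -1L
    ord <- order(lin@position[nodes])
  }
  sLines <- vapply(ord, function(i) {
    s <- if (flip[i]) revComp(seqs[i]) else seqs[i]
    paste("S", nodes[i], if (nzchar(s)) s else "*", sep = "\t")
  }, "")

  e <- graph@edges
  lLines <- character(nrow(e))
  if (nrow(e)) {
    fs <- e$fromSide; ts <- e$toSide
    fs[flip[e$from]] <- ifelse(fs[flip[e$from]] == "L", "R", "L")
    ts[flip[e$to]] <- ifelse(ts[flip[e$to]] == "L", "R", "L")
    lLines <- paste("L", e$from, ifelse(fs == "R", "+", "-"),
                    e$to, ifelse(ts == "L", "+", "-"), "0M", sep = "\t")
  }
  pLines <- vapply(graph@paths, function(p) {
    st <- p$strands
    f <- flip[p$nodes]
    st[f] <- ifelse(st[f] == "+", "-", "+")
    paste("P", p$name, paste0(p$nodes, st, collapse = ","), "*", sep = "\t")
  }, "")
  out <- c("H\tVN:Z:1.0", sLines, lLines, pLines)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Spell the DNA sequence represented by a genome path
#'
#' Concatenates node labels along the path, reverse-complementing nodes
#' visited on the '-' strand.
#'
#' @param graph a \linkS4class{BidirectedGraph} with node sequences.
#' @param path a path list (\code{nodes}, \code{strands}), a path name, or an
#'   index into \code{graphPaths(graph)}.
#' @return The spelled DNA string.
#' @export
spellPath <- function(graph, path) {
  if (is.character(path) && length(path) == 1L) {
    hit <- which(vapply(graph@paths, function(p) p$name == path, NA))
    if (!length(hit)) stop("no path named '", path, "'")
    path <- graph@paths[[hit[1L]]]
  } else if (is.numeric(path)) path <- graph@paths[[path]]
  seqs <- stats::setNames(graph@sequences, graph@nodes)
  pieces <- vapply(seq_along(path$nodes), function(i) {
    s <- seqs[[path$nodes[i]]]
    if (path$strands[i] == "-") revComp(s) else s
  }, "")
  paste(pieces, collapse = "")
}
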