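.randomDNA <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Simulate structural variants over a random reference fragment
#'
#' Draws a uniform random DNA reference and, independently for each genome,
#' places \code{variantsPerType} variants of each type (deletion, insertion,
#' inversion, tandem duplication) at uniform non-overlapping reference loci.
#' Default dimensions mirror a typical pangenome simulation protocol: a
#' 37287 bp fragment, event lengths 20/20/200/500 bp, and 10 genomes.
#'
#' @param refLength reference length in bp.
#' @param variantsPerType number of variants of each type per genome.
#' @param nGenomes number of rearranged genomes.
#' @param lengths named lengths (bp) for deletion, insertion, inversion,
#'   duplication events.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param maxTries placement attempts per variant before giving up.
#' @return list with \code{reference} (string) and \code{variants} (one
#'   data.frame per genome with columns kind, refStart, length, seq; an
#'   insertion's \code{refStart} is the base before which its sequence is
#'   inserted and \code{seq} its inserted sequence).
#' @export
simulateGenomes <- function(refLength = 37287, variantsPerType = 5,
                            nGenomes = 10,
                            lengths = c(deletion = 20, insertion = 20,
                                        inversion = 200, duplication = 500),
                            seed = NULL, maxTries = 1000) {
  stopifnot(refLength > 0, variantsPerType >= 0, nGenomes > 0,
            all(lengths > 0))
  if (!is.null(seed)) set.seed(seed)
  reference <- .randomDNA(refLength)
  types <- c("deletion", "insertion", "inversion", "duplication")
  variants <- vector("list", nGenomes)
  for (g in seq_len(nGenomes)) {
    todo <- rep(types, each = variantsPerType)
    if (length(todo)) todo <- sample(todo)
    iv <- matrix(numeric(0), ncol = 2)     # occupied base intervals
    insAt <- numeric(0)                    # insertion breakpoints (before base)
    rows <- list()
    for (kind in todo) {
      len <- lengths[[kind]]
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        if (kind == "insertion") {
          s <- sample(2:refLength, 1L)
          # conflicts: breakpoint inside or at the start of an interval
          # (a shared refStart would leave the event order ambiguous), or
          # a repeated breakpoint
          if (any(iv[, 1] <= s & s <= iv[, 2]) || any(insAt == s)) next
          insAt <- c(insAt, s)
          rows[[length(rows) + 1L]] <- data.frame(
            kind = kind, refStart = s, length = len,
            seq = .randomDNA(len), stringsAsFactors = FALSE)
        } else {
          if (refLength < len) break
          s <- sample(refLength - len + 1L, 1L)
          e <- s + len - 1
          if (any(pmax(iv[, 1], s) <= pmin(iv[, 2], e)) ||
              any(s <= insAt & insAt <= e)) next
          iv <- rbind(iv, c(s, e))
          rows[[length(rows) + 1L]] <- data.frame(
            kind = kind, refStart = s, length = len, seq = NA_character_,
            stringsAsFactors = FALSE)
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place all variants without overlap; ",
             "reduce variantsPerType or event lengths")
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(kind = character(), refStart = numeric(),
                 length = numeric(), seq = character(),
                 stringsAsFactors = FALSE)
    variants[[g]] <- df[order(df$refStart), , drop = FALSE]
    rownames(variants[[g]]) <- NULL
  }
  list(reference = reference, variants = variants)
}

#' Apply structural variant specs to a reference sequence
#'
#' @param reference reference DNA string.
#' @param specs data.frame with columns kind, refStart, length, seq (as
#'   produced by \code{\link{simulateGenomes}}); loci must not overlap.
#' @return The rearranged genome string.
#' @export
applyVariants <- function(reference, specs) {
  s <- specs[order(specs$refStart, decreasing = TRUE), , drop = FALSE]
  out <- reference
  for (i in seq_len(nrow(s))) {
    st <- s$refStart[i]; len <- s$length[i]
    pre <- substr(out, 1L, st - 1L)
    switch(s$kind[i],
      deletion = { out <- paste0(pre, substring(out, st + len)) },
      insertion = { out <- paste0(pre, s$seq[i], substring(out, st)) },
      inversion = {
        out <- paste0(pre, revComp(substr(out, st, st + len - 1L)),
                      substring(out, st + len))
      },
      duplication = {
        out <- paste0(substr(out, 1L, st + len - 1L), substring(out, st))
      },
      stop("unknown variant kind: ", s$kind[i]))
  }
  out
}

#' Build the exact pangenome graph implied by known variant breakpoints
#'
#' Segments the reference at the union of all genomes' breakpoints (plus a
#' regular grid every \code{maxNodeLength} bp, emulating the node-length
#' capping of practical graph constructors); creates one node per segment and
#' one per insertion event; and threads one genome path per input genome:
#' deletions skip segments, inversions traverse their segments in reverse
#' order on the '-' strand, duplications revisit their segments (a tandem
#' back edge), insertions visit their own node. Edges are exactly the path
#' adjacencies, weighted by traversal counts, so every edge is covered.
#'
#' @param reference reference DNA string.
#' @param variants list of per-genome spec data.frames.
#' @param includeReference also thread the reference itself as a path
#'   (contributing to edge weights).
#' @param maxNodeLength segment length cap in bp (NA to disable).
#' @return A \linkS4class{BidirectedGraph}; \code{metadata} holds the segment
#'   coordinate table and the insertion node table.
#' @export
buildVariantGraph <- function(reference, variants, includeReference = TRUE,
                              maxNodeLength = 1000) {
  L <- nchar(reference)
  cuts <- numeric(0)
  if (!is.na(maxNodeLength) && maxNodeLength < L)
    cuts <- seq(maxNodeLength, L - 1, by = maxNodeLength)
  for (specs in variants) {
    for (i in seq_len(nrow(specs))) {
      st <- specs$refStart[i]; len <- specs$length[i]
      cuts <- c(cuts, st - 1,
                if (specs$kind[i] != "insertion") st + len - 1)
    }
  }
  cuts <- sort(unique(cuts[cuts >= 1 & cuts <= L - 1]))
  bounds <- c(0, cuts, L)
  segStart <- bounds[-length(bounds)] + 1
  segEnd <- bounds[-1]
  m <- length(segStart)
  segIds <- paste0("s", seq_len(m))
  segSeqs <- substring(reference, segStart, segEnd)

  segsIn <- function(a, b) which(segStart >= a & segEnd <= b)

  nodes <- segIds; seqs <- segSeqs
  insTable <- data.frame(node = character(), genome = integer(),
                         refStart = numeric(), length = numeric(),
                         stringsAsFactors = FALSE)
  paths <- list()
  if (includeReference)
    paths[[1L]] <- list(name = "ref", nodes = segIds,
                        strands = rep("+", m))
  for (g in seq_along(variants)) {
    specs <- variants[[g]]
    vnodes <- character(0); vstr <- character(0)
    cursor <- 1
    emit <- function(a, b) {
      if (b >= a) {
        idx <- segsIn(a, b)
        vnodes <<- c(vnodes, segIds[idx])
        vstr <<- c(vstr, rep("+", length(idx)))
      }
    }
    nIns <- 0L
    for (i in seq_len(nrow(specs))) {
      st <- specs$refStart[i]; len <- specs$length[i]
      emit(cursor, st - 1)
      switch(specs$kind[i],
        deletion = { cursor <- st + len },
        insertion = {
          nIns <- nIns + 1L
          id <- paste0("i", g, "_", nIns)
          nodes <- c(nodes, id)
          seqs <- c(seqs, specs$seq[i])
          insTable <- rbind(insTable, data.frame(
            node = id, genome = g, refStart = st, length = len,
            stringsAsFactors = FALSE))
          vnodes <- c(vnodes, id); vstr <- c(vstr, "+")
          cursor <- st
        },
        inversion = {
          idx <- rev(segsIn(st, st + len - 1))
          vnodes <- c(vnodes, segIds[idx])
          vstr <- c(vstr, rep("-", length(idx)))
          cursor <- st + len
        },
        duplication = {
          idx <- segsIn(st, st + len - 1)
          vnodes <- c(vnodes, segIds[idx], segIds[idx])
          vstr <- c(vstr, rep("+", 2L * length(idx)))
          cursor <- st + len
        })
    }
    emit(cursor, L)
    paths[[length(paths) + 1L]] <-
      list(name = paste0("g", g), nodes = vnodes, strands = vstr)
  }

  adj <- lapply(paths, function(p) {
    k <- length(p$nodes)
    if (k < 2L) return(NULL)
    i <- seq_len(k - 1L)
    s <- .linkSides(p$strands[i], p$strands[i + 1L])
    data.frame(from = p$nodes[i], fromSide = s$fromSide,
               to = p$nodes[i + 1L], toSide = s$toSide,
               weight = 1, stringsAsFactors = FALSE)
  })
  edges <- canonicalEdges(do.call(rbind, adj))
  g <- new("BidirectedGraph", nodes = nodes, sequences = seqs,
           edges = edges, paths = paths,
           metadata = list(
             segments = data.frame(node = segIds, start = segStart,
                                   end = segEnd, stringsAsFactors = FALSE),
             insertions = insTable))
  computeEdgeWeights(g)
}

#' Random bidirected graph for fuzz testing
#'
#' Uniform random endpoints and sides, canonical-collapsed (so the realized
#' edge count can be below \code{nEdges}); no paths.
#'
#' @param nNodes number of nodes.
#' @param nEdges number of edge draws before collapsing.
#' @param weights \code{"unit"} for all-1 weights or \code{"random"} for
#'   integer weights in 1..10.
#' @param seed integer seed.
#' @param allowSelf permit self-edges.
#' @return A \linkS4class{BidirectedGraph}.
#' @export
randomBidirectedGraph <- function(nNodes, nEdges, weights = c("unit", "random"),
                                  seed = NULL, allowSelf = FALSE) {
  weights <- match.arg(weights)
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("n", seq_len(nNodes))
  if (nEdges == 0)
    return(new("BidirectedGraph", nodes = ids,
               sequences = rep("", nNodes), edges = .emptyEdges(),
               paths = list(), metadata = list()))
  u <- sample(nNodes, nEdges, replace = TRUE)
  v <- sample(nNodes, nEdges, replace = TRUE)
  if (!allowSelf) {
    while (any(u == v)) {
      k <- which(u == v)
      v[k] <- sample(nNodes, length(k), replace = TRUE)
    }
  }
  e <- data.frame(from = ids[u],
                  fromSide = sample(c("L", "R"), nEdges, replace = TRUE),
                  to = ids[v],
                  toSide = sample(c("L", "R"), nEdges, replace = TRUE),
                  weight = if (weights == "unit") 1 else
                    sample(10L, nEdges, replace = TRUE),
                  stringsAsFactors = FALSE)
  new("BidirectedGraph", nodes = ids, sequences = rep("", nNodes),
      edges = canonicalEdges(e), paths = list(), metadata = list())
}
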