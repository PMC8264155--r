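# Small graph builders used across the suite.  All fixtures are built in
# code; no files.

# Chain 1 -> 2 -> ... -> n: each edge joins the right side of i to the left
# side of i+1 (a consistently directed path).
chainGraph <- function(n, weight = 1, ids = paste0("c", seq_len(n))) {
  if (n < 2) return(BidirectedGraph(ids))
  BidirectedGraph(ids, edges = data.frame(
    from = ids[-n], fromSide = "R", to = ids[-1], toSide = "L",
    weight = weight, stringsAsFactors = FALSE))
}

# Directed cycle 1 -> 2 -> ... -> n -> 1 with given edge weights; optional
# per-node strand flips (flipping a node swaps the sides its incident cycle
# edges attach to, so the cycle is still consistently traversable).
cycleGraph <- function(weights, strands = NULL) {
  n <- length(weights)
  ids <- paste0("y", seq_len(n))
  if (is.null(strands)) strands <- rep("+", n)
  nxt <- c(seq_len(n)[-1], 1L)
  BidirectedGraph(ids, edges = data.frame(
    from = ids, fromSide = ifelse(strands == "+", "R", "L"),
    to = ids[nxt], toSide = ifelse(strands[nxt] == "+", "L", "R"),
    weight = weights, stringsAsFactors = FALSE))
}

# Random spanning tree over n nodes with random sides on both endpoints.
randomTreeGraph <- function(n, seed) {
  set.seed(seed)
  ids <- paste0("t", seq_len(n))
  if (n < 2) return(BidirectedGraph(ids))
  par <- vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L)
  BidirectedGraph(ids, edges = data.frame(
    from = ids[par], fromSide = sample(c("L", "R"), n - 1, replace = TRUE),
    to = ids[2:n], toSide = sample(c("L", "R"), n - 1, replace = TRUE),
    weight = sample(10L, n - 1, replace = TRUE), stringsAsFactors = FALSE))
}

# Shadow model of the linearization state: explicit component / orientation /
# position arrays, updated by whole-array rewrites.  The forest under test
# must reproduce its observations exactly.
shadowNew <- function(n)
  list(comp = seq_len(n), orient = rep(1L, n), pos = rep(1, n))

shadowUnion <- function(sh, membersA, membersB, reverseB) {
  nA <- length(membersA); nB <- length(membersB)
  if (reverseB) {
    sh$pos[membersB] <- nA + nB + 1 - sh$pos[membersB]
    sh$orient[membersB] <- -sh$orient[membersB]
  } else {
    sh$pos[membersB] <- sh$pos[membersB] + nA
  }
  sh$comp[membersB] <- sh$comp[membersA[1]]
  sh
}

# Compare every observation of the forest against the shadow; also check the
# per-component position-contiguity invariant.
expectStateMatchesShadow <- function(st, sh) {
  obs <- alibi:::linStateAll(st)
  expect_identical(as.integer(obs$orient), as.integer(sh$orient))
  expect_identical(as.numeric(obs$pos), as.numeric(sh$pos))
  for (cc in unique(sh$comp)) {
    m <- sh$comp == cc
    expect_setequal(sh$pos[m], seq_len(sum(m)))
    expect_length(unique(obs$root[m]), 1L)
  }
  invisible(NULL)
}

# One randomized operation sequence against the shadow model.  Returns the
# trace of (orient, pos) snapshots so runs with and without extra finds can
# be compared.
runStateFuzz <- function(n, nOps, seed, extraFinds = FALSE,
                         checkEvery = TRUE) {
  set.seed(seed)
  st <- alibi:::linStateNew(paste0("v", seq_len(n)))
  sh <- shadowNew(n)
  trace <- vector("list", nOps)
  for (op in seq_len(nOps)) {
    kind <- sample(c("union", "repos", "find"), 1)
    if (extraFinds)   # deterministic target: keeps the RNG stream aligned
      invisible(alibi:::linStateFind(st, (op * 7L) %% n + 1L))
    if (kind == "union") {
      roots <- unique(sh$comp)
      if (length(roots) >= 2) {
        cs <- roots[sample.int(length(roots), 2L)]
        mA <- which(sh$comp == cs[1]); mB <- which(sh$comp == cs[2])
        rev <- sample(c(TRUE, FALSE), 1)
        rootA <- alibi:::linStateFind(st, mA[1])$root
        rootB <- alibi:::linStateFind(st, mB[1])$root
        if (rev)
          alibi:::linStateUnion(st, rootA, rootB, 1, 0, -1,
                                length(mA) + length(mB) + 1)
        else
          alibi:::linStateUnion(st, rootA, rootB, 1, 0, 1, length(mA))
        sh <- shadowUnion(sh, mA, mB, rev)
      }
    } else if (kind == "repos") {
      roots <- unique(sh$comp)
      cc <- roots[sample.int(length(roots), 1L)]
      mm <- which(sh$comp == cc)
      k <- sample.int(length(mm), 1L)
      sel <- mm[sample.int(length(mm), k)]
      newp <- sh$pos[sel][sample.int(k)]
      alibi:::linStateReposition(st, sel, newp)
      sh$pos[sel] <- newp
    } else {
      invisible(alibi:::linStateFind(st, sample.int(n, 1L)))
    }
    if (checkEvery) expectStateMatchesShadow(st, sh)
    obs <- alibi:::linStateAll(st)
    trace[[op]] <- list(orient = obs$orient, pos = obs$pos)
  }
  trace
}
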