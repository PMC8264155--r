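# Augmented disjoint-set forest for incremental linearization.
#
# Each entry stores, relative to its parent in the component tree:
#   orient  - orientation (+1 same as parent, -1 opposite),
#   shift   - preliminary position offset, inherited by descendants,
#   rshift  - final position offset relative to the preliminary position,
#             NOT inherited by descendants.
# The actual orientation A(v) is the product of orient over v and its
# ancestors; the actual position is
#   P(v) = sum over strict ancestors u of shift(u) * A(u)
#        + (shift(v) + rshift(v)) * A(v).
# The inheritable prefix S(v) = P(v) - rshift(v) * A(v) satisfies
#   S(child) = S(parent) + shift(child) * A(child),
# which is what path compression and union must preserve.  Re-parenting a
# node x under a root r while keeping A(x) and S(x) fixed requires
#   orient'(x) = A(x) * A(r),
#   shift'(x)  = (S(x) - shift(r) * A(r)) * A(x),
# the closed-form composition used below (all factors are +/-1, so division
# equals multiplication).
#
# Positions are stored as doubles (exact integers well below 2^53); shifts
# may be negative internally.

linStateNew <- function(ids) {
  if (!length(ids)) stop("cannot build a linearization state over zero nodes")
  if (anyDuplicated(ids)) stop("duplicate node ids")
  n <- length(ids)
  st <- new.env(parent = emptyenv())
  st$ids <- as.character(ids)
  st$n <- n
  st$parent <- seq_len(n)
  st$rnk <- integer(n)
  st$orient <- rep(1L, n)
  st$shift <- rep(1, n)        # singleton root at position 1
  st$rshift <- rep(0, n)
  st$csize <- rep(1, n)        # valid at roots only
  # Forward arcs are stored by the side they attach to, not by direction:
  # reversing a component flips all its orientations, which reverses the
  # direction of every internal forward arc, while the attachment sides are
  # fixed.  A node's current out-neighbors are the arcs on its out-side
  # (right side when its actual orientation is +1, left side otherwise).
  st$adjL <- vector("list", n)
  st$adjR <- vector("list", n)
  st$unionWrites <- 0L         # entries touched by union attribute edits
  st$compressionSteps <- 0L    # nodes re-parented during path compression
  st
}

# FIND with path compression.  Returns list(root, orient, pos).  Observable
# (orientation, position) of every node is unchanged by the call; attributes
# are rewritten to compensate for the re-parenting.
linStateFind <- function(st, v) {
  if (is.na(v) || v < 1L || v > st$n) stop("unknown node index")
  parent <- st$parent
  chain <- integer(0)
  x <- v
  while (parent[x] != x) {
    chain <- c(chain, x)
    x <- parent[x]
  }
  root <- x
  Aroot <- st$orient[root]
  Sroot <- st$shift[root] * Aroot
  A <- Aroot; S <- Sroot
  if (length(chain)) {
    # walk root-ward chain from top to v, computing each node's A and S
    As <- numeric(length(chain)); Ss <- numeric(length(chain))
    for (k in rev(seq_along(chain))) {
      u <- chain[k]
      A <- A * st$orient[u]       # A here is the parent's A on entry
      S <- S + st$shift[u] * A
      As[k] <- A; Ss[k] <- S
      # loop continues with A,S of u as "parent" values for the next node
    }
    # re-parent every chain node (except direct children of root) onto root
    for (k in seq_along(chain)) {
      u <- chain[k]
      if (st$parent[u] != root) {
        st$parent[u] <- root
        st$orient[u] <- as.integer(As[k] * Aroot)
        st$shift[u] <- (Ss[k] - Sroot) * As[k]
        st$compressionSteps <- st$compressionSteps + 1L
      }
    }
    A <- As[1L]; S <- Ss[1L]   # chain[1] is v itself
  }
  list(root = root, orient = as.integer(A), pos = S + st$rshift[v] * A)
}

# Merge two components applying per-component affine transforms of the
# observable positions: P' = eps * P + delta (eps also multiplies the
# orientation).  Union by rank decides the tree parent; a constant number of
# attribute edits at the two roots realizes the transforms regardless of
# which root wins.
linStateUnion <- function(st, rootA, rootB, epsA, deltaA, epsB, deltaB) {
  if (st$parent[rootA] != rootA || st$parent[rootB] != rootB)
    stop("union requires root arguments")
  if (rootA == rootB) stop("cannot union a component with itself")
  nA <- st$csize[rootA]; nB <- st$csize[rootB]
  if (st$rnk[rootA] >= st$rnk[rootB]) {
    winner <- rootA; loser <- rootB
    epsW <- epsA; deltaW <- deltaA; epsL <- epsB; deltaL <- deltaB
    if (st$rnk[rootA] == st$rnk[rootB])
      st$rnk[rootA] <- st$rnk[rootA] + 1L
  } else {
    winner <- rootB; loser <- rootA
    epsW <- epsB; deltaW <- deltaB; epsL <- epsA; deltaL <- deltaA
  }
  # transform the winner's whole component in place at its root
  Aw <- st$orient[winner]
  if (epsW != 1 || deltaW != 0) {
    st$shift[winner] <- st$shift[winner] + deltaW * epsW * Aw
    st$orient[winner] <- as.integer(epsW * Aw)
    st$unionWrites <- st$unionWrites + 1L
  }
  AwNew <- st$orient[winner]
  SwNew <- st$shift[winner] * AwNew
  # attach the loser root under the winner, with its own transform
  Al <- st$orient[loser]
  AlNew <- as.integer(epsL * Al)
  st$orient[loser] <- AlNew * AwNew
  st$shift[loser] <- (epsL * st$shift[loser] * Al + deltaL - SwNew) * AlNew
  st$parent[loser] <- winner
  st$unionWrites <- st$unionWrites + 1L
  st$csize[winner] <- nA + nB
  winner
}

# Rewrite the actual positions of `nodes` to `newPos` through their
# (non-inherited) rshift attributes.  `newPos` must be a permutation of the
# nodes' current positions; all other nodes, including descendants of the
# listed ones, keep their positions, and no orientation changes.
linStateReposition <- function(st, nodes, newPos) {
  if (length(nodes) != length(newPos)) stop("assignment length mismatch")
  if (!length(nodes)) return(invisible(NULL))
  cur <- numeric(length(nodes)); A <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    f <- linStateFind(st, nodes[i])
    cur[i] <- f$pos; A[i] <- f$orient
  }
  if (!identical(sort(cur), sort(as.numeric(newPos))))
    stop("new positions are not a permutation of the affected positions")
  st$rshift[nodes] <- st$rshift[nodes] + (newPos - cur) * A
  invisible(NULL)
}

# Observables for every node: root, actual orientation, actual position.
linStateAll <- function(st) {
  root <- integer(st$n); A <- integer(st$n); P <- numeric(st$n)
  for (v in seq_len(st$n)) {
    f <- linStateFind(st, v)
    root[v] <- f$root; A[v] <- as.integer(f$orient); P[v] <- f$pos
  }
  list(root = root, orient = A, pos = P)
}
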