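ns <- asNamespace("alibi")

test_that("edges process in descending weight with deterministic tie-break", {
  g <- BidirectedGraph(c("a", "b", "c", "d"), edges = data.frame(
    from = c("a", "a", "b", "c"), fromSide = "R",
    to = c("b", "c", "c", "d"), toSide = "L",
    weight = c(3, 5, 2, 5)))
  e <- graphEdges(g)
  o <- sortEdges(g)
  expect_identical(e$weight[o], c(5, 5, 3, 2))
  # weight-5 tie broken by canonical key: a|R|c|L before c|R|d|L
  expect_identical(e$from[o][1:2], c("a", "c"))
  expect_identical(sortEdges(BidirectedGraph("x")), integer())
})

test_that("edge insertion realizes the six classification cases", {
  g <- function(edf) {
    ids <- c("u", "v", "w")
    st <- ns$linStateNew(ids)
    list(st = st, ids = ids)
  }
  # (i) cross-component, mixed sides: forward, out-side component first
  s <- g()
  res <- ns$addEdge(s$st, 1L, "R", 2L, "L")
  expect_identical(res$class, "forward_arc")
  expect_true(res$crossComponent)
  expect_identical(ns$linStateFind(s$st, 1L)$pos, 1)
  expect_identical(ns$linStateFind(s$st, 2L)$pos, 2)
  # (ii) cross-component, same sides: one side reversed, then forward
  s <- g()
  res <- ns$addEdge(s$st, 1L, "R", 2L, "R")
  expect_identical(res$class, "forward_arc")
  f2 <- ns$linStateFind(s$st, 2L)
  expect_identical(f2$orient, -1L)        # v reversed: out-side became in-side
  expect_identical(f2$pos, 2)
  # (iii) same component, same sides: reversing join, no state change
  before <- ns$linStateAll(s$st)
  res <- ns$addEdge(s$st, 1L, "L", 2L, "R")  # both now in-sides
  expect_identical(res$class, "reversing_join")
  expect_identical(ns$linStateAll(s$st), before)
  # (iv) same component, mixed sides, out-side already precedes: forward
  # (v's right side is its in-side now that v is reversed)
  res <- ns$addEdge(s$st, 1L, "R", 2L, "R")
  expect_identical(res$class, "forward_arc")
  # (v) forward chain u->v->w, then out(w) joined to in(u): feedback
  s <- g()
  ns$addEdge(s$st, 1L, "R", 2L, "L")
  ns$addEdge(s$st, 2L, "R", 3L, "L")
  res <- ns$addEdge(s$st, 1L, "L", 3L, "R")  # out of w into u
  expect_identical(res$class, "feedback_arc")
  # self-edges
  s <- g()
  expect_identical(ns$addEdge(s$st, 1L, "L", 1L, "R")$class, "feedback_arc")
  expect_identical(ns$addEdge(s$st, 2L, "R", 2L, "R")$class, "reversing_join")
})

test_that("region-restricted forward search matches brute-force reachability", {
  # chain a -> b -> c
  st <- ns$linStateNew(c("a", "b", "c"))
  ns$addEdge(st, 1L, "R", 2L, "L")
  ns$addEdge(st, 2L, "R", 3L, "L")
  expect_setequal(ns$forwardDfsRegion(st, 1L, 1, 3, "out")$nodes, 1:3)
  expect_setequal(ns$forwardDfsRegion(st, 1L, 1, 2, "out")$nodes, 1:2)
  expect_setequal(ns$forwardDfsRegion(st, 3L, 1, 3, "in")$nodes, 1:3)
  # random forward DAGs: compare against transitive closure within region
  for (s in 1:10) {
    set.seed(s)
    n <- sample(4:12, 1)
    st <- ns$linStateNew(paste0("n", 1:n))
    arcs <- matrix(integer(), ncol = 2)
    for (k in 1:(3 * n)) {
      u <- sample.int(n, 1); v <- sample.int(n, 1)
      if (u == v) next
      r <- ns$addEdge(st, u, "R", v, "L")
      if (r$class == "forward_arc") arcs <- rbind(arcs, c(u, v))
    }
    obs <- ns$linStateAll(st)
    # brute-force closure restricted to a random window, per start node
    lo <- sample.int(n, 1); hi <- sample(lo:n, 1)
    reachable <- function(start) {
      ok <- obs$pos >= lo & obs$pos <= hi &
        obs$root == obs$root[start]
      inset <- rep(FALSE, n); inset[start] <- ok[start]
      repeat {
        grew <- FALSE
        for (a in seq_len(nrow(arcs))) {
          u <- arcs[a, 1]; v <- arcs[a, 2]
          if (inset[u] && !inset[v] && ok[v]) { inset[v] <- TRUE; grew <- TRUE }
        }
        if (!grew) break
      }
      which(inset)
    }
    for (start in which(obs$pos >= lo & obs$pos <= hi)) {
      got <- ns$forwardDfsRegion(st, start, lo, hi, "out")$nodes
      expect_setequal(got, reachable(start))
    }
  }
})

test_that("reordering places the backward set before the forward set", {
  # two nodes merged via a heavy bridge, then an opposing edge: simple swap
  st <- ns$linStateNew(c("p", "q", "r", "s"))
  ns$addEdge(st, 1L, "R", 2L, "L")         # p(1) -> q(2)
  ns$addEdge(st, 3L, "R", 4L, "L")         # r(1) -> s(2)
  ns$addEdge(st, 2L, "R", 3L, "L")         # q -> r: one component p,q,r,s
  obs <- ns$linStateAll(st)
  expect_identical(obs$pos, c(1, 2, 3, 4))
  # new edge out(s) -> in(p) closes a cycle: feedback, no reorder
  before <- ns$linStateAll(st)
  expect_identical(ns$addEdge(st, 1L, "L", 4L, "R")$class, "feedback_arc")
  expect_identical(ns$linStateAll(st), before)
})

test_that("reordering is a minimal local permutation", {
  # a -> b and a -> c give order a(1) b(2) c(3) with b, c unrelated; the new
  # arc out(c) -> in(b) swaps exactly {b, c} (V_B = {c}, V_F = {b}) and
  # leaves a alone
  st <- ns$linStateNew(c("a", "b", "c"))
  ns$addEdge(st, 1L, "R", 2L, "L")
  ns$addEdge(st, 1L, "R", 3L, "L")
  expect_identical(ns$linStateAll(st)$pos, c(1, 2, 3))
  res <- ns$addEdge(st, 2L, "L", 3L, "R")
  expect_identical(res$class, "forward_arc")
  expect_identical(ns$linStateAll(st)$pos, c(1, 3, 2))
  expect_identical(ns$linStateAll(st)$orient, rep(1L, 3))
})

test_that("chains linearize perfectly and cycles sacrifice the lightest edge", {
  ch <- chainGraph(6)
  lin <- linearizeGraph(ch)
  expect_identical(wrj(ch, lin), 0)
  expect_identical(wfa(ch, lin), 0)
  expect_identical(unname(positions(lin)), 1:6)
  # directed 3-cycle, weights 5,3,2: the two heavy edges become forward,
  # the light one feedback
  cy <- cycleGraph(c(5, 3, 2))
  linc <- linearizeGraph(cy)
  expect_identical(wfa(cy, linc), 2)
  expect_identical(wrj(cy, linc), 0)
  cls <- edgeClasses(linc)
  e <- graphEdges(cy)
  expect_identical(unname(cls[match(2, e$weight)]), "feedback_arc")
})

test_that("edgeless and empty graphs behave per contract", {
  g0 <- BidirectedGraph(c("a", "b", "c"))
  lin <- linearizeGraph(g0)
  expect_identical(unname(orientations(lin)), rep(1L, 3))
  expect_identical(unname(positions(lin)), 1:3)  # node index order
  expect_error(linearizeGraph(BidirectedGraph(character())), "empty")
})

test_that("recorded classes stay coherent with the final linearization", {
  for (s in 1:25) {
    g <- randomBidirectedGraph(sample(2:25, 1), sample(0:60, 1),
                               weights = "random", seed = 1000 + s,
                               allowSelf = s %% 4 == 0)
    lin <- linearizeGraph(g)
    expect_identical(unname(edgeClasses(lin)),
                     unname(classifyEdges(g, lin)))
    # forward arcs are a DAG consistent with ord: every forward arc points
    # from a smaller to a larger position
    e <- graphEdges(g)
    cls <- unname(edgeClasses(lin))
    a <- orientations(lin); p <- positions(lin)
    fwd <- which(cls == "forward_arc")
    outFrom <- ns$.sideSign(e$fromSide) * a[e$from] == 1L
    po <- ifelse(outFrom, p[e$from], p[e$to])
    pi2 <- ifelse(outFrom, p[e$to], p[e$from])
    expect_true(all(po[fwd] < pi2[fwd]))
    # cross-component insertions are always forward
    expect_true(all(cls[lin@crossComponent] == "forward_arc"))
  }
})
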