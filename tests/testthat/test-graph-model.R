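test_that("minimal GFA parses into nodes, canonical edges and default weights", {
  g <- readGFA(text = c("S\t1\tACG", "S\t2\tTTT", "L\t1\t+\t2\t+\t0M"))
  expect_identical(nodeIds(g), c("1", "2"))
  expect_identical(unname(nodeSeqs(g)), c("ACG", "TTT"))
  e <- graphEdges(g)
  expect_identical(nrow(e), 1L)
  expect_identical(e$from, "1"); expect_identical(e$fromSide, "R")
  expect_identical(e$to, "2"); expect_identical(e$toSide, "L")
  expect_identical(e$weight, 1)
})

test_that("the same bidirected edge read from both strands collapses to one", {
  g <- readGFA(text = c("S\t1\t*", "S\t2\t*",
                        "L\t1\t+\t2\t+\t0M", "L\t2\t-\t1\t-\t0M"))
  e <- graphEdges(g)
  expect_identical(nrow(e), 1L)
  expect_identical(unname(unlist(e[1, 1:4])), c("1", "R", "2", "L"))
})

test_that("malformed GFA is rejected with informative errors", {
  expect_error(readGFA(text = c("S\t1\tA", "L\t1\t+\t9\t+\t0M")),
               "unknown segment '9'")
  expect_error(readGFA(text = c("S\t1\tA", "S\t2\tA", "L\t1\tx\t2\t+\t0M")),
               "strand")
  expect_error(readGFA(text = c("H\tVN:Z:2.0", "S\t1\tA")), "GFA2")
  expect_error(readGFA(text = c("S\t1\tA", "W\tsamp\t1\tchr\t0\t1\t>1")),
               "W lines")
  expect_warning(readGFA(text = c("S\t1\tA", "C\t1\t+\t1\t+\t0\t0M")),
                 "skipping")
})

test_that("edge weights count path traversals in either direction", {
  txt <- c("S\t1\tA", "S\t2\tC", "S\t3\tG",
           "L\t1\t+\t2\t+\t0M", "L\t2\t+\t3\t+\t0M",
           "P\tp1\t1+,2+\t*", "P\tp2\t1+,2+,3+\t*", "P\tp3\t2-,1-\t*")
  g <- readGFA(text = txt)
  e <- graphEdges(g)
  w <- stats::setNames(e$weight, paste(e$from, e$to))
  expect_identical(unname(w["1 2"]), 3)   # p1, p2 forward + p3 reverse strand
  expect_identical(unname(w["2 3"]), 1)
  # weight conservation: total weight == total path adjacencies
  expect_identical(sum(e$weight), 2 + 1 + 1)
})

test_that("uncovered edges get weight 0 with paths present, 1 without any", {
  withP <- readGFA(text = c("S\t1\tA", "S\t2\tC", "S\t3\tG",
                            "L\t1\t+\t2\t+\t0M", "L\t2\t+\t3\t+\t0M",
                            "P\tp\t1+,2+\t*"))
  w <- graphEdges(withP)$weight
  expect_setequal(w, c(1, 0))
  noP <- readGFA(text = c("S\t1\tA", "S\t2\tC", "S\t3\tG",
                          "L\t1\t+\t2\t+\t0M", "L\t2\t+\t3\t+\t0M",
                          "L\t1\t+\t3\t+\t0M"))
  expect_identical(graphEdges(noP)$weight, c(1, 1, 1))
})

test_that("a path adjacency with no matching edge is a validation error", {
  g <- BidirectedGraph(c("1", "2"),
                       edges = data.frame(from = "1", fromSide = "R",
                                          to = "2", toSide = "L"),
                       paths = list(list(name = "p", nodes = c("2", "1"),
                                         strands = c("+", "+"))))
  expect_error(computeEdgeWeights(g), "no matching edge")
})

test_that("reverse complement is correct, total and involutive", {
  expect_identical(revComp("ACGCGCGTAGAGAT"), "ATCTCTACGCGCGT")
  expect_identical(revComp(""), "")
  expect_identical(revComp("acgtn"), "NACGT")
  expect_error(revComp("ACXGT"), "position 3")
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(0:50, 1),
                      replace = TRUE), collapse = "")
    expect_identical(revComp(revComp(s)), s)
  }
})

test_that("parse-write-parse is the identity on the data model", {
  sim <- simulateGenomes(refLength = 800, variantsPerType = 1, nGenomes = 3,
                         lengths = c(deletion = 10, insertion = 10,
                                     inversion = 40, duplication = 60),
                         seed = 21)
  g <- buildVariantGraph(sim$reference, sim$variants, maxNodeLength = 100)
  g2 <- readGFA(text = writeGFA(g))
  expect_identical(nodeIds(g2), nodeIds(g))
  expect_identical(nodeSeqs(g2), nodeSeqs(g))
  k1 <- alibi:::.edgeKeys(graphEdges(g)); k2 <- alibi:::.edgeKeys(graphEdges(g2))
  expect_identical(graphEdges(g2)[order(k2), ], graphEdges(g)[order(k1), ],
                   ignore_attr = TRUE)
  expect_identical(graphPaths(g2), graphPaths(g))
})

test_that("linearized rewrite flips sequences and strands coherently", {
  # a node emitted with orientation -1 carries its reverse complement
  g <- BidirectedGraph(c("a", "b"), sequences = c("ACG", "TT"),
                       edges = data.frame(from = "a", fromSide = "R",
                                          to = "b", toSide = "L"))
  lin <- Linearization(c(a = -1L, b = 1L), c(a = 1L, b = 2L))
  lines <- writeGFA(g, lin = lin)
  expect_true("S\ta\tCGT" %in% lines)
  expect_true(any(grepl("^L\ta\t-\tb\t\\+", lines)))
})

test_that("every path spells identical DNA before and after linearized rewrite", {
  # three-node graph with one flipped node
  g <- BidirectedGraph(c("a", "b", "c"),
                       sequences = c("ACGT", "GG", "TACA"),
                       edges = data.frame(
                         from = c("a", "b"), fromSide = c("R", "R"),
                         to = c("b", "c"), toSide = c("L", "L")),
                       paths = list(list(name = "p",
                                         nodes = c("a", "b", "c"),
                                         strands = c("+", "+", "+"))))
  g <- computeEdgeWeights(g)
  lin <- Linearization(c(a = 1L, b = -1L, c = 1L), c(a = 1L, b = 2L, c = 3L))
  g2 <- readGFA(text = writeGFA(g, lin = lin))
  expect_identical(spellPath(g2, "p"), spellPath(g, "p"))
  # randomized graphs with random orientation flips
  for (s in 1:5) {
    sim <- simulateGenomes(refLength = 500, variantsPerType = 1, nGenomes = 2,
                           lengths = c(deletion = 10, insertion = 10,
                                       inversion = 50, duplication = 50),
                           seed = s)
    gg <- buildVariantGraph(sim$reference, sim$variants, maxNodeLength = 80)
    set.seed(s + 100)
    n <- length(nodeIds(gg))
    rlin <- Linearization(
      stats::setNames(sample(c(-1L, 1L), n, replace = TRUE), nodeIds(gg)),
      stats::setNames(sample.int(n), nodeIds(gg)))
    gg2 <- readGFA(text = writeGFA(gg, lin = rlin))
    for (p in graphPaths(gg))
      expect_identical(spellPath(gg2, p$name), spellPath(gg, p$name))
  }
})
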