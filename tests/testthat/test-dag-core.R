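test_that("acyclicity detection matches the topological-order definition", {
  expect_true(isAcyclic(matrix(integer(0), 0, 2), nNodes = 3))
  expect_false(isAcyclic(rbind(c(1, 2), c(2, 1)), nNodes = 2))
  expect_true(isAcyclic(rbind(c(1, 2), c(2, 3), c(1, 3)), nNodes = 3))
  expect_error(isAcyclic(rbind(c(1, 1)), nNodes = 2), "self-edge")
  expect_error(dagStructure(3, rbind(c(1, 2), c(2, 3), c(3, 1))), "cycle")
})

test_that("single-edge moves apply, refuse inapplicable cases, and invert", {
  d0 <- emptyDag(2)
  d1 <- applyMove(d0, edgeMove("addition", 1, 2))
  expect_equal(unname(adjacency(d1)[1, 2]), 1L)
  expect_equal(edgeCount(d0), 0L)  # input untouched
  expect_true(applyMove(d1, edgeMove("reversal", 1, 2)) ==
                dagStructure(2, rbind(c(2, 1))))
  expect_true(applyMove(d1, edgeMove("deletion", 1, 2)) == d0)
  expect_error(applyMove(d1, edgeMove("addition", 1, 2)), "existing")
  expect_error(applyMove(d0, edgeMove("deletion", 1, 2)), "missing")
  chain3 <- dagStructure(3, rbind(c(1, 2), c(2, 3)))
  expect_error(applyMove(chain3, edgeMove("addition", 3, 1)), "cycle")

  # inverse move returns the original structure, for every neighbourhood move
  set.seed(5)
  for (rep in 1:20) {
    d <- randomDag(5, 0.4)
    mv <- enumerateNeighborhood(d)
    i <- sample.int(nrow(mv), 1)
    m <- mv[i, ]
    d2 <- applyMove(d, m)
    inv <- switch(m$kind,
      addition = edgeMove("deletion", m$parent, m$child),
      deletion = edgeMove("addition", m$parent, m$child),
      reversal = edgeMove("reversal", m$child, m$parent))
    expect_true(applyMove(d2, inv) == d)
  }
})

test_that("neighbourhood enumeration matches brute-force apply-and-check", {
  e3 <- enumerateNeighborhood(emptyDag(3))
  expect_equal(nrow(e3), 6)
  expect_true(all(e3$kind == "addition"))

  cmp <- dagStructure(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  mv <- enumerateNeighborhood(cmp)
  expect_equal(nrow(mv), 5)
  expect_equal(sum(mv$kind == "deletion"), 3)
  # reversing 1->3 would create a cycle through 2; only the other two reverse
  expect_equal(mv[mv$kind == "reversal", c("parent", "child")],
               data.frame(parent = c(1L, 2L), child = c(2L, 3L)),
               ignore_attr = TRUE)

  expect_equal(nrow(enumerateNeighborhood(dagStructure(2, rbind(c(1, 2))))), 2)

  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    d <- randomDag(n, runif(1, 0.2, 0.7))
    for (fanin in c(Inf, 2)) {
      got <- enumerateNeighborhood(d, fanin)
      want <- oracleNeighborhood(d, fanin)
      expect_equal(got[order(got$kind, got$parent, got$child), ], want,
                   ignore_attr = TRUE)
      expect_equal(neighborhoodSize(d, fanin), nrow(want))
    }
  }
})

test_that("enumeration order is deterministic and sorted by kind then edge", {
  d <- dagStructure(4, rbind(c(1, 2), c(3, 4)))
  mv <- enumerateNeighborhood(d)
  expect_identical(mv, mv[order(match(mv$kind, c("addition", "deletion", "reversal")),
                                mv$parent, mv$child), ])
  expect_identical(mv, enumerateNeighborhood(d))
})

test_that("neighbourhood relation is symmetric, also under a fan-in cap", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(3:5, 1)
    d <- randomDag(n, 0.4, maxFanin = 2)
    for (fanin in c(Inf, 2)) {
      mv <- enumerateNeighborhood(d, fanin)
      for (i in seq_len(nrow(mv))) {
        nb <- applyMove(d, mv[i, ])
        back <- enumerateNeighborhood(nb, fanin)
        found <- any(vapply(seq_len(nrow(back)), function(j)
          applyMove(nb, back[j, ]) == d, logical(1)))
        expect_true(found)
      }
    }
  }
})

test_that("empty dag neighbourhood size is n(n-1)", {
  expect_equal(neighborhoodSize(emptyDag(11)), 110)
})

test_that("DAG files round-trip through edge-list, adjacency and DOT", {
  d <- dagStructure(4, rbind(c(1, 2), c(2, 4), c(1, 3)),
                    labels = c("Raf", "Mek", "Erk", "Akt"))
  f1 <- tempfile(fileext = ".tsv")
  writeDagEdgeList(d, f1)
  expect_true(readDagEdgeList(f1, labels = nodeLabels(d)) == d)

  f2 <- tempfile(fileext = ".csv")
  writeDagAdjacency(d, f2)
  expect_true(readDagAdjacency(f2) == d)

  f3 <- tempfile(fileext = ".dot")
  writeDot(d, f3)
  txt <- readLines(f3)
  expect_true(any(grepl("\"Mek\" -> \"Akt\"", txt)))

  # canonical hashing: equality is edge-set equality
  expect_identical(dagKey(d), dagKey(readDagEdgeList(f1, labels = nodeLabels(d))))
  expect_false(dagKey(d) == dagKey(emptyDag(4)))
})
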