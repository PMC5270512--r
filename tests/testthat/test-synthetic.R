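test_that("random DAGs respect density extremes, acyclicity and fan-in", {
  set.seed(51)
  expect_equal(edgeCount(randomDag(6, 0)), 0)
  full <- randomDag(6, 1)
  expect_equal(edgeCount(full), 6 * 5 / 2)  # complete under the drawn order
  for (rep in 1:200) {
    d <- randomDag(sample(2:8, 1), runif(1), maxFanin = 3)
    expect_true(oracleAcyclic(unname(adjacency(d))))
    expect_true(all(colSums(adjacency(d)) <= 3))
  }
})

test_that("random CPTs are proper, positive, and sharper at low concentration", {
  set.seed(52)
  d <- dagStructure(3, rbind(c(1, 2), c(1, 3)))
  bn <- randomCpts(d, arities = c(2, 3, 4), concentration = 0.5)
  for (v in 1:3) {
    expect_equal(rowSums(bn@cpts[[v]]), rep(1, nrow(bn@cpts[[v]])))
    expect_true(all(bn@cpts[[v]] > 0))
  }
  expect_error(randomCpts(d, concentration = 0), "positive")

  maxEntry <- function(conc) {
    mean(replicate(400, {
      bn <- randomCpts(emptyDag(1), arities = 3, concentration = conc)
      max(bn@cpts[[1]])
    }))
  }
  set.seed(53)
  expect_gt(maxEntry(0.5), maxEntry(5))
})

test_that("forward sampling follows the CPTs", {
  # single node, fixed distribution
  bn1 <- groundTruthBN(emptyDag(1), 2, list(matrix(c(0.25, 0.75), 1)))
  set.seed(54)
  d1 <- forwardSample(bn1, 100000)
  expect_equal(mean(d1@values[, 1]), 0.75, tolerance = 0.015)
  expect_false(hasInterventions(d1))

  # deterministic CPTs: child copies parent
  bn2 <- groundTruthBN(dagStructure(2, rbind(c(1, 2))), 2,
                       list(matrix(c(0.5, 0.5), 1),
                            rbind(c(1, 0), c(0, 1))))
  d2 <- forwardSample(bn2, 500)
  expect_equal(d2@values[, 1], d2@values[, 2])

  # empirical joint of a 2-node net matches the factorised closed form
  bn3 <- groundTruthBN(dagStructure(2, rbind(c(1, 2))), 2,
                       list(matrix(c(0.3, 0.7), 1),
                            rbind(c(0.9, 0.1), c(0.2, 0.8))))
  set.seed(55)
  d3 <- forwardSample(bn3, 50000)
  joint <- table(factor(d3@values[, 1], 0:1), factor(d3@values[, 2], 0:1)) / 50000
  want <- outer(c(0.3, 0.7), c(1, 1)) * rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(as.numeric(joint), as.numeric(want), tolerance = 0.02)
})

test_that("interventional sampling clamps, masks, and propagates to children", {
  bn <- groundTruthBN(dagStructure(2, rbind(c(1, 2))), 2,
                      list(matrix(c(0.99, 0.01), 1),       # parent almost surely 0
                           rbind(c(0.99, 0.01), c(0.01, 0.99))))  # child copies
  set.seed(56)
  none <- interventionalSample(bn, 200, interventionFraction = 0)
  expect_false(hasInterventions(none))

  all1 <- interventionalSample(bn, 300, interventionFraction = 1)
  expect_equal(unname(rowSums(interventionMask(all1))), rep(1, 300))

  # clamping the parent to 1 drags the child with it (not the marginal)
  set.seed(57)
  cl <- interventionalSample(bn, 2000, interventionFraction = 1,
                             targets = 1, fixedValue = 1)
  expect_true(all(cl@values[, 1] == 1))
  expect_true(all(interventionMask(cl)[, 1]))
  expect_gt(mean(cl@values[, 2]), 0.95)  # child follows the clamp
})

test_that("combined two-network datasets pool rows without provenance", {
  set.seed(58)
  a <- randomCpts(randomDag(4, 0.4), arities = 2)
  b <- randomCpts(randomDag(4, 0.4), arities = 2)
  dat <- combinedDataset(a, b, 250)
  expect_equal(nSamples(dat), 500)
  expect_equal(nVariables(dat), 4)
  expect_false(hasInterventions(dat))
  wrong <- randomCpts(randomDag(5, 0.4), arities = 2)
  expect_error(combinedDataset(a, wrong, 10), "share")
})

test_that("generators are deterministic given the seed", {
  set.seed(59); d1 <- forwardSample(randomCpts(randomDag(5, 0.4)), 50)
  set.seed(59); d2 <- forwardSample(randomCpts(randomDag(5, 0.4)), 50)
  expect_identical(d1@values, d2@values)
})

test_that("ground-truth networks round-trip through JSON", {
  set.seed(60)
  bn <- randomCpts(randomDag(4, 0.5, labels = c("a", "b", "c", "d")),
                   arities = c(2, 3, 2, 3), concentration = 1)
  f <- tempfile(fileext = ".json")
  writeGroundTruthBN(bn, f)
  back <- readGroundTruthBN(f)
  expect_true(back@structure == bn@structure)
  expect_equal(back@arities, bn@arities)
  for (v in 1:4) expect_equal(back@cpts[[v]], bn@cpts[[v]], tolerance = 1e-12)
})

test_that("the generating DAG outscores nearly all one-step neighbours", {
  set.seed(61)
  bn <- randomCpts(randomDag(5, 0.4), arities = 3, concentration = 0.5)
  dat <- interventionalSample(bn, 3000, interventionFraction = 0.3)
  g <- bn@structure
  s0 <- graphLogScore(g, dat)
  mv <- enumerateNeighborhood(g)
  worse <- vapply(seq_len(nrow(mv)), function(i)
    graphLogScore(applyMove(g, mv[i, ]), dat) < s0, logical(1))
  expect_gte(mean(worse), 0.99)
})
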