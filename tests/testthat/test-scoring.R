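test_that("family marginal likelihood matches closed-form Dirichlet integrals", {
  ds <- discreteDataset(matrix(c(1L, 1L, 1L, 0L), 4, 1), arities = 2)
  # Dirichlet(1,1) prior (ess = 2): integral of theta^3 (1-theta) = B(4, 2)
  expect_equal(familyLogScore(1, integer(0), ds, scoreSettings(ess = 2)),
               log(1 / 20))
  # BDeu ess = 1 (alpha = 1/2, 1/2): product-of-Gamma form
  expect_equal(familyLogScore(1, integer(0), ds, scoreSettings(ess = 1)),
               log(5 / 128))
  # no unmasked samples -> empty product -> log 1
  masked <- discreteDataset(matrix(c(1L, 0L), 2, 1), arities = 2,
                            mask = matrix(TRUE, 2, 1))
  expect_equal(familyLogScore(1, integer(0), masked), 0)
  empty <- discreteDataset(matrix(integer(0), 0, 2), arities = c(2, 2))
  expect_equal(graphLogScore(emptyDag(2), empty), 0)
  expect_error(familyLogScore(3, integer(0), ds), "out of range")
  expect_error(familyLogScore(1, 1, ds), "exclude")
})

test_that("graph score decomposes over families", {
  set.seed(3)
  bn <- toyBn3()
  dat <- forwardSample(bn, 120)
  expect_equal(graphLogScore(emptyDag(3), dat),
               sum(vapply(1:3, function(v)
                 familyLogScore(v, integer(0), dat), numeric(1))))
  d <- dagStructure(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(graphLogScore(d, dat),
               familyLogScore(1, integer(0), dat) +
                 familyLogScore(2, 1, dat) + familyLogScore(3, 2, dat))
  expect_error(graphLogScore(emptyDag(4), dat), "match")
})

test_that("BDeu is score-equivalent on observational data", {
  set.seed(7)
  vals <- cbind(rbinom(150, 1, 0.4), rbinom(150, 1, 0.6))
  vals[, 2] <- ifelse(runif(150) < 0.7, vals[, 1], vals[, 2])
  dat <- discreteDataset(vals)
  a <- dagStructure(2, rbind(c(1, 2)))
  b <- dagStructure(2, rbind(c(2, 1)))
  expect_equal(graphLogScore(a, dat), graphLogScore(b, dat))

  # whole Markov equivalence classes on n = 3 receive equal scores
  set.seed(8)
  bn <- toyBn3(8)
  dat3 <- forwardSample(bn, 200)
  dags <- enumerateDags(3)
  scores <- vapply(dags, graphLogScore, numeric(1), dataset = dat3)
  keys <- vapply(dags, oracleEquivalenceKey, character(1))
  for (k in unique(keys)) {
    s <- scores[keys == k]
    expect_lt(max(s) - min(s), 1e-9)
  }
})

test_that("interventions break score equivalence towards the causal direction", {
  set.seed(9)
  # u -> v nearly deterministic; half the rows clamp v to a uniform value
  n <- 400
  u <- rbinom(n, 1, 0.5)
  v <- ifelse(runif(n) < 0.95, u, 1 - u)
  clamp <- seq_len(n) <= n / 2
  v[clamp] <- rbinom(sum(clamp), 1, 0.5)
  mask <- cbind(rep(FALSE, n), clamp)
  dat <- discreteDataset(cbind(u, v), mask = mask)
  causal <- dagStructure(2, rbind(c(1, 2)))
  anticausal <- dagStructure(2, rbind(c(2, 1)))
  expect_gt(graphLogScore(causal, dat), graphLogScore(anticausal, dat))
  # without the mask the two remain score-equivalent
  noMask <- discreteDataset(cbind(u, v))
  expect_equal(graphLogScore(causal, noMask), graphLogScore(anticausal, noMask))
})

test_that("the generating DAG outscores the empty DAG with enough data", {
  set.seed(10)
  bn <- toyBn3(10)
  dat <- forwardSample(bn, 3000)
  expect_gt(graphLogScore(bn@structure, dat), graphLogScore(emptyDag(3), dat))
})

test_that("delta scoring equals the full-rescore difference", {
  set.seed(12)
  d <- randomDag(4, 0.5)
  bn <- randomCpts(d, arities = 2, concentration = 1)
  dat <- forwardSample(bn, 80)
  mv <- enumerateNeighborhood(d)
  for (i in seq_len(nrow(mv))) {
    full <- graphLogScore(applyMove(d, mv[i, ]), dat) - graphLogScore(d, dat)
    expect_equal(deltaLogScore(d, mv[i, ], dat), full, tolerance = 1e-9)
  }
  datEmpty <- forwardSample(randomCpts(emptyDag(2), arities = 2), 10)
  expect_error(deltaLogScore(emptyDag(2), edgeMove("deletion", 1, 2), datEmpty),
               "not present")
})

test_that("a fully masked family contributes nothing to a move's delta", {
  set.seed(13)
  vals <- cbind(rbinom(50, 1, 0.5), rbinom(50, 1, 0.5))
  mask <- cbind(rep(FALSE, 50), rep(TRUE, 50))  # variable 2 always clamped
  dat <- discreteDataset(vals, mask = mask)
  d <- emptyDag(2)
  expect_equal(deltaLogScore(d, edgeMove("addition", 1, 2), dat), 0)
})
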