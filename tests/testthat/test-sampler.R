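test_that("chain bookkeeping: retention, thinning, determinism, seeds", {
  set.seed(21)
  bn <- toyBn3(21)
  dat <- forwardSample(bn, 60)
  cfg <- chainConfig(sampleSize = 100, seed = 5, burnIn = 10,
                     proposal = proposalSpec(c(0.5, 0.5)))
  s <- runChain(cfg, dat)
  expect_equal(sampleSize(s), 100)
  expect_identical(runChain(cfg, dat)@states, s@states)

  cfgThin <- chainConfig(sampleSize = 100, seed = 5, thin = 10,
                         proposal = proposalSpec(c(0.5, 0.5)))
  expect_equal(sampleSize(runChain(cfgThin, dat)), 10)

  s2 <- runChain(chainConfig(sampleSize = 100, seed = 6, burnIn = 10,
                             proposal = proposalSpec(c(0.5, 0.5))), dat)
  expect_false(identical(s@states, s2@states))

  # retained log scores are re-derivable from the retained structures
  i <- c(1, 50, 100)
  expect_equal(vapply(i, function(j) graphLogScore(chainDag(s, j), dat),
                      numeric(1)),
               logScores(s)[i])
})

test_that("mhStep accepts self-returning proposals and respects the prior hook", {
  set.seed(22)
  dat <- forwardSample(toyBn3(22), 50)
  d <- emptyDag(3)
  # a proposal ending at the start has Delta = 0 and unit Hastings ratio;
  # any uniform draw accepts it
  for (rep in 1:50) {
    st <- mhStep(d, dat, proposalSpec(c(0, 1)))
    if (st$walk@end == d) expect_true(st$accepted)
  }
  # prior hook: an overwhelming prior on the empty graph pins the chain
  pin <- function(g) if (edgeCount(g) == 0) 0 else -1e6
  set.seed(23)
  cur <- d; sc <- NULL
  for (rep in 1:30) {
    st <- mhStep(cur, dat, proposalSpec(1), scoreSettings(logPrior = pin),
                 logScore = sc)
    cur <- st$dag; sc <- st$logScore
  }
  expect_true(cur == d)
})

test_that("with a flat target the acceptance probability is min(1, q(G)/q(G'))", {
  empty <- discreteDataset(matrix(integer(0), 0, 3), arities = c(2, 2, 2))
  d <- dagStructure(3, rbind(c(1, 2)))
  qG <- neighborhoodSize(d)
  m <- neighborhoodAcceptanceMap(d, empty)
  for (i in seq_len(nrow(m))) {
    nb <- applyMove(d, m[i, c("kind", "parent", "child")])
    expect_equal(m$acceptProb[i], min(1, qG / neighborhoodSize(nb)))
  }
})

test_that("long-run state frequencies satisfy detailed balance", {
  set.seed(24)
  dat <- forwardSample(toyBn3(24), 100)
  post <- exactPosterior(dat)
  cfg <- chainConfig(sampleSize = 60000, seed = 9, burnIn = 2000,
                     proposal = proposalSpec(c(0.5, 0.5)))
  s <- runChain(cfg, dat)
  idx <- mcmcDag:::cppMatchRows(s@states, post@states)
  steps <- cbind(idx[-length(idx)], idx[-1])
  steps <- steps[steps[, 1] != steps[, 2], , drop = FALSE]
  tab <- table(paste(steps[, 1], steps[, 2]))
  # the three most travelled ordered transitions vs their reverses
  top <- names(sort(tab, decreasing = TRUE))[1:3]
  for (key in top) {
    ij <- strsplit(key, " ")[[1]]
    fwd <- tab[key]
    rev <- tab[paste(ij[2], ij[1])]
    if (is.na(rev)) rev <- 0
    expect_lt(abs(fwd - rev), 3 * sqrt(fwd + rev))
  }
})

test_that("ensembles are independent, pooled correctly, and warn on reused seeds", {
  set.seed(25)
  dat <- forwardSample(toyBn3(25), 40)
  cfgs <- lapply(1:2, function(j)
    chainConfig(sampleSize = 50, seed = j, proposal = proposalSpec(1)))
  ss <- runChainEnsemble(cfgs, dat)
  expect_length(ss, 2)
  expect_false(identical(ss[[1]]@states, ss[[2]]@states))

  pooled <- poolChains(ss)
  expect_equal(sampleSize(pooled), 100)
  epPool <- as.matrix(edgePosteriors(pooled))
  epAvg <- (as.matrix(edgePosteriors(ss[[1]])) +
              as.matrix(edgePosteriors(ss[[2]]))) / 2
  expect_equal(epPool, epAvg)

  cfgs[[2]] <- chainConfig(sampleSize = 50, seed = 1, proposal = proposalSpec(1))
  expect_warning(runChainEnsemble(cfgs, dat), "duplicate")
})

test_that("invalid configurations fail before any compute", {
  expect_error(chainConfig(sampleSize = 0, seed = 1), "sampleSize")
  expect_error(chainConfig(sampleSize = 10, seed = 1, thin = 0), "thin")
  expect_error(chainConfig(sampleSize = 10, seed = 1, burnIn = -1), "burnIn")
  dat <- discreteDataset(matrix(0:1, 2, 2), arities = c(2, 2))
  cfg <- chainConfig(sampleSize = 10, seed = 1,
                     score = scoreSettings(logPrior = function(g) 0))
  expect_error(runChain(cfg, dat), "uniform")
})
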