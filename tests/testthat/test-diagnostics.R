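# build a ChainSample by hand from a list of DAGs (equal nNodes)
sampleFromDags <- function(dags, scores = NULL) {
  n <- nNodes(dags[[1]])
  states <- do.call(rbind, lapply(dags, function(d)
    as.raw(as.integer(t(d@adjacency)))))
  if (is.null(scores)) scores <- rep(0, length(dags))
  new("ChainSample", states = states, nNodes = as.integer(n),
      labels = dags[[1]]@labels, logScores = scores,
      acceptCounts = 0L, proposalCounts = 0L, config = NULL)
}

test_that("edge posteriors are indicator means over the retained sample", {
  d <- dagStructure(3, rbind(c(1, 2), c(2, 3)))
  s1 <- sampleFromDags(list(d))
  expect_equal(unname(as.matrix(edgePosteriors(s1))),
               unname(adjacency(d)) + 0)

  d2 <- applyMove(d, edgeMove("deletion", 2, 3))
  s2 <- sampleFromDags(list(d, d2, d, d2))
  ep <- unname(as.matrix(edgePosteriors(s2)))
  expect_equal(ep[2, 3], 0.5)
  expect_equal(ep[1, 2], 1)
  expect_true(all(ep %in% c(0, 0.5, 1)))
  emptySample <- new("ChainSample", states = matrix(raw(0), 0, 9),
                     nNodes = 3L, labels = d@labels, logScores = numeric(0),
                     acceptCounts = 0L, proposalCounts = 0L, config = NULL)
  expect_error(edgePosteriors(emptySample), "empty")
})

test_that("SSD is a squared distance", {
  a <- matrix(runif(9), 3, 3); diag(a) <- 0
  b <- a; b[1, 2] <- a[1, 2] + 0.1
  expect_equal(edgePosteriorSSD(a, a), 0)
  expect_equal(edgePosteriorSSD(a, b), 0.01)
  expect_equal(edgePosteriorSSD(a, b), edgePosteriorSSD(b, a))
  one <- matrix(0, 2, 2); two <- one; two[1, 2] <- 1
  expect_equal(edgePosteriorSSD(one, two), 1)
  expect_error(edgePosteriorSSD(one, matrix(0, 3, 3)), "shape")
})

test_that("best-converged pair is the SSD argmin with low-index ties", {
  d <- dagStructure(3, rbind(c(1, 2)))
  e <- emptyDag(3)
  sA <- sampleFromDags(list(d, d))
  sB <- sampleFromDags(list(e, e))
  sC <- sampleFromDags(list(d, d))
  res <- bestConvergedPair(list(sA, sB, sC))
  expect_equal(res$pair, c(1, 3))
  expect_equal(res$ssd, 0)
  # matches a naive double loop
  eps <- lapply(list(sA, sB, sC), edgePosteriors)
  naive <- Inf; naivePair <- NULL
  for (i in 1:2) for (j in (i + 1):3) {
    v <- edgePosteriorSSD(eps[[i]], eps[[j]])
    if (v < naive) { naive <- v; naivePair <- c(i, j) }
  }
  expect_equal(res$pair, naivePair)
  expect_equal(res$ssd, naive)
  expect_error(bestConvergedPair(list(sA)), "two")
})

test_that("unique-DAG counting and MAP selection work on retained states", {
  d <- dagStructure(3, rbind(c(1, 2)))
  e <- emptyDag(3)
  osc <- sampleFromDags(list(d, e, d, e, d), scores = c(-5, -3, -5, -3, -5))
  expect_equal(uniqueDagCount(osc), 2)
  expect_equal(uniqueDagCount(sampleFromDags(list(d, d, d))), 1)
  m <- mapDag(osc)
  expect_true(m$dag == e)
  expect_equal(m$logScore, -3)
  expect_equal(m$index, 2)  # first encountered among ties
})

test_that("consensus graphs threshold strictly and flag cycles", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- 1; p[2, 3] <- 0.5
  epm <- new("EdgePosteriorMatrix", probs = p, provenance = list())
  expect_equal(nrow(consensusGraph(epm, 1.0)$edges), 0)  # strict >
  g <- consensusGraph(epm, 0.85)
  expect_equal(g$edges[, c("parent", "child")],
               data.frame(parent = 1L, child = 2L), ignore_attr = TRUE)
  g0 <- consensusGraph(epm, 0)
  expect_equal(nrow(g0$edges), 2)
  expect_true(g0$acyclic)

  cyc <- matrix(0, 2, 2); cyc[1, 2] <- 0.9; cyc[2, 1] <- 0.9
  gc <- consensusGraph(new("EdgePosteriorMatrix", probs = cyc,
                           provenance = list()), 0.85)
  expect_false(gc$acyclic)
  expect_equal(nrow(gc$edges), 2)
})

test_that("the acceptance map matches directly computed MH probabilities", {
  set.seed(41)
  dat <- forwardSample(toyBn3(41), 120)
  d <- dagStructure(3, rbind(c(1, 2)))
  m <- neighborhoodAcceptanceMap(d, dat)
  expect_equal(nrow(m), neighborhoodSize(d))
  for (i in seq_len(nrow(m))) {
    nb <- applyMove(d, m[i, c("kind", "parent", "child")])
    want <- min(1, exp(graphLogScore(nb, dat) - graphLogScore(d, dat)) *
                  neighborhoodSize(d) / neighborhoodSize(nb))
    expect_equal(m$acceptProb[i], want, tolerance = 1e-12)
  }
  # reporting cutoff drops improbable exits
  cut <- neighborhoodAcceptanceMap(d, dat, cutoff = 1e-4)
  expect_true(all(cut$acceptProb >= 1e-4))
  expect_lte(nrow(cut), nrow(m))
})

test_that("score traces slice the retained sequence and clip with a warning", {
  d <- dagStructure(3, rbind(c(1, 2)))
  s <- sampleFromDags(rep(list(d), 5), scores = c(-1, -2, -3, -4, -5))
  expect_equal(scoreTrace(s)$logScore, c(-1, -2, -3, -4, -5))
  tail2 <- scoreTrace(s, 2)
  expect_equal(tail2$index, c(4, 5))
  expect_equal(tail2$logScore, c(-4, -5))
  expect_warning(full <- scoreTrace(s, 10), "clip|full")
  expect_equal(nrow(full), 5)
})
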