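# Negative sampling, the ranking loss, the training loop, and the
# Hits@10 / AUC-PR evaluation protocol.

test_that("sampleNegatives returns filtered, reproducible corruptions", {
  g <- knowledgeGraph(c("a", "b", "c"), "r", rbind(c(1, 1, 2)))
  for (i in 1:10) {
    neg <- sampleNegatives(c(1L, 1L, 2L), g, 1L, seed = i)
    expect_true(neg[1, 3] %in% c(1L, 3L))  # never the true tail
  }
  g2 <- knowledgeGraph(paste0("e", 1:100), "r", rbind(c(1, 1, 2)))
  neg <- sampleNegatives(c(1L, 1L, 2L), g2, 5L, seed = 42L)
  expect_equal(nrow(neg), 5L)
  expect_false(any(neg[, 3L] == 2L))
  expect_identical(neg, sampleNegatives(c(1L, 1L, 2L), g2, 5L, seed = 42L))
  # extra truth triples are filtered as well
  truth <- cbind(1L, 1L, 3:50)
  neg2 <- sampleNegatives(c(1L, 1L, 2L), g2, 20L, seed = 1L, truth = truth)
  expect_false(any(neg2[, 3L] %in% 2:50))
  # degenerate graph: every tail is true
  g3 <- knowledgeGraph(c("a", "b"), "r", rbind(c(1, 1, 2)))
  expect_error(sampleNegatives(c(1L, 1L, 2L), g3, 1L, seed = 1L,
                               truth = cbind(1L, 1L, 1L)), "degenerate")
})

test_that("ranking loss matches hand evaluation and is monotone", {
  expect_equal(rankingLoss(0.5, 0.5), 2 * log(2), tolerance = 1e-9)
  expect_lt(rankingLoss(1 - 1e-9, rep(1e-9, 4)), 1e-5)
  expect_error(rankingLoss(0.5, numeric(0)), "at least one")
  # decreasing in p_pos, increasing in each p_neg
  h <- 1e-4
  for (p in c(0.2, 0.5, 0.9)) {
    expect_lt(rankingLoss(p + h, c(0.3, 0.6)), rankingLoss(p, c(0.3, 0.6)))
    expect_gt(rankingLoss(0.5, c(p + h, 0.4)), rankingLoss(0.5, c(p, 0.4)))
  }
})

test_that("rankTail uses the pessimistic tie policy", {
  expect_equal(rankTail(5L, c(5L, 2L, 3L), c(0.9, 0.5, 0.1)), 1L)
  expect_equal(rankTail(1L, 1:51, rep(0.5, 51)), 51L)
  expect_equal(rankTail(7L, c(7L, 2L, 3L, 4L), c(0.8, 0.9, 0.8, 0.1)), 3L)
  expect_error(rankTail(9L, c(1L, 2L), c(0.1, 0.2)), "missing")
})

test_that("hitsAtK counts ranks at or below the cutoff", {
  expect_equal(hitsAtK(1L, 10L), 1)
  expect_equal(hitsAtK(c(1L, 11L, 3L), 10L), 2 / 3)
  expect_equal(hitsAtK(c(12L, 40L), 10L), 0)
  expect_error(hitsAtK(integer(0)), "at least one")
  # non-decreasing in k
  set.seed(8)
  ranks <- sample.int(40, 25, replace = TRUE)
  hs <- vapply(1:40, function(k) hitsAtK(ranks, k), 0)
  expect_true(all(diff(hs) >= 0))
})

test_that("aucPR matches hand-computed PR curves", {
  expect_equal(aucPR(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucPR(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)  # ties: prevalence
  expect_equal(aucPR(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6, tolerance = 1e-12)
  expect_error(aucPR(c(0.1, 0.2), c(1, 1)), "single-class")
})

test_that("hitsAtK and aucPR agree with brute-force reimplementations", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    ranks <- sample.int(60, n, replace = TRUE)
    k <- sample.int(20, 1)
    expect_identical(hitsAtK(ranks, k), bruteHits(ranks, k))
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))  # both classes present
    scores <- round(runif(n), 2)              # rounding forces ties
    expect_equal(aucPR(scores, labels), bruteAP(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("training produces a history and learns on a toy split", {
  split <- tinyBenchmark(seed = 42L)
  expect_error(trainConfig(epochs = 0L))
  mc <- modelConfig(dim = 8L, nHeads = 2L, nTotalLayers = 3L,
                    nBaseGnnLayers = 1L, normalizeGlobal = TRUE, seed = 42L)
  tc1 <- trainConfig(nNegatives = 8L, batchSize = 8L, epochs = 1L,
                     seed = 42L)
  fit1 <- trainModel(split, mc, tc1)
  expect_equal(nrow(fit1$history), 1L)
  tc <- trainConfig(nNegatives = 8L, batchSize = 8L, epochs = 6L,
                    learningRate = 1e-2, seed = 42L)
  fit <- trainModel(split, mc, tc)
  expect_lt(fit$history$loss[6], fit$history$loss[1])
})

test_that("training is bitwise deterministic for a fixed seed", {
  split <- tinyBenchmark(seed = 42L)
  mc <- modelConfig(dim = 8L, nHeads = 2L, nTotalLayers = 2L,
                    nBaseGnnLayers = 1L, seed = 7L)
  tc <- trainConfig(nNegatives = 4L, batchSize = 8L, epochs = 2L, seed = 7L)
  f1 <- trainModel(split, mc, tc)
  f2 <- trainModel(split, mc, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params$par, f2$params$par)
})

test_that("the oracle scorer achieves perfect metrics under the protocol", {
  split <- tinyBenchmark(seed = 42L)
  rep <- evaluateModel(split, NULL, nCandidates = 20L, seed = 1L,
                       oracle = TRUE)
  expect_equal(hitsAt10(rep), 1)
  expect_equal(aucPRValue(rep), 1)
})

test_that("a constant scorer scores zero Hits@10 under pessimistic ties", {
  split <- tinyBenchmark(seed = 42L)
  mc <- modelConfig(dim = 8L, nHeads = 2L, nTotalLayers = 2L,
                    nBaseGnnLayers = 1L, seed = 7L)
  mp <- initParams(mc, numRelations(trainGraph(split)))
  mp$par[] <- 0   # every triple scores sigmoid(0) = 0.5
  rep <- evaluateModel(split, mp, nCandidates = 51L, seed = 1L)
  expect_equal(hitsAt10(rep), 0)
})

test_that("evaluation reports are reproducible and well-formed", {
  split <- tinyBenchmark(seed = 42L)
  mc <- modelConfig(dim = 8L, nHeads = 2L, nTotalLayers = 3L,
                    nBaseGnnLayers = 1L, seed = 7L)
  mp <- initParams(mc, numRelations(trainGraph(split)))
  r1 <- evaluateModel(split, mp, seed = 5L)
  r2 <- evaluateModel(split, mp, seed = 5L)
  expect_equal(hitsAt10(r1), hitsAt10(r2))
  expect_equal(aucPRValue(r1), aucPRValue(r2))
  expect_true(hitsAt10(r1) >= 0 && hitsAt10(r1) <= 1)
  expect_true(aucPRValue(r1) > 0 && aucPRValue(r1) <= 1)
  expect_equal(r1@nCandidatesPerQuery, 50L)
  expect_output(show(r1), "EvalReport")
})
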