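# Per-layer operations of the dual-channel network, the compiled engine
# against the R op-composition oracle, and analytic gradients against
# finite differences.

mkParams <- function(graph, ...) {
  mc <- do.call(modelConfig,
                utils::modifyList(list(dim = 8L, nHeads = 2L,
                                       nTotalLayers = 3L,
                                       nBaseGnnLayers = 1L, seed = 11L),
                                  list(...)))
  initParams(mc, numRelations(graph))
}

test_that("kernelPhi is ELU(x)+1 and strictly positive", {
  expect_equal(kernelPhi(0), 1)
  expect_equal(kernelPhi(2), 3)
  expect_equal(kernelPhi(-20), exp(-20), tolerance = 1e-12)
  x <- matrix(seq(-5, 5, length.out = 12), 3)
  expect_equal(dim(kernelPhi(x)), dim(x))
  expect_true(all(kernelPhi(seq(-50, 50, by = 0.25)) > 0))
})

test_that("globalHead matches hand cases and the quadratic oracle", {
  set.seed(2)
  d <- 6L; dh <- 3L
  Wq <- matrix(rnorm(d * dh), d); Wk <- matrix(rnorm(d * dh), d)
  Wv <- matrix(rnorm(d * dh), d)
  # zero input stays zero (phi(K)^T V = 0)
  expect_equal(globalHead(matrix(0, 4, d), Wq, Wk, Wv),
               matrix(0, 4, dh))
  # a single entity: (phi(q) . phi(k)) v
  e <- matrix(rnorm(d), 1)
  q <- kernelPhi(e %*% Wq); k <- kernelPhi(e %*% Wk); v <- e %*% Wv
  expect_equal(globalHead(e, Wq, Wk, Wv), sum(q * k) * v,
               tolerance = 1e-12)
  # linear order of association equals the explicit |E| x |E| computation
  for (norm in c(FALSE, TRUE)) {
    E <- matrix(rnorm(5 * d), 5)
    expect_equal(globalHead(E, Wq, Wk, Wv, normalize = norm),
                 quadraticAttentionOracle(E, Wq, Wk, Wv, normalize = norm),
                 tolerance = 1e-6)
  }
})

test_that("globalModule concatenates heads and projects", {
  g <- toyGraph()
  set.seed(4)
  E <- matrix(rnorm(numEntities(g) * 8), ncol = 8)
  mp <- mkParams(g, nHeads = 1L)
  lp <- layerParams(mp, 2L)
  expect_equal(globalModule(E, lp, 1L),
               globalHead(E, lp$Wq, lp$Wk, lp$Wv) %*% lp$Wm)
  expect_equal(globalModule(matrix(0, 3, 8), lp, 1L), matrix(0, 3, 8))
  # identical per-head parameters make head order irrelevant
  lp2 <- lp
  lp2$Wq <- cbind(lp$Wq[, 1:4], lp$Wq[, 1:4])
  lp2$Wk <- cbind(lp$Wk[, 1:4], lp$Wk[, 1:4])
  lp2$Wv <- cbind(lp$Wv[, 1:4], lp$Wv[, 1:4])
  swapped <- lp2
  swapped$Wq <- swapped$Wq[, c(5:8, 1:4)]
  swapped$Wk <- swapped$Wk[, c(5:8, 1:4)]
  swapped$Wv <- swapped$Wv[, c(5:8, 1:4)]
  expect_equal(globalModule(E, lp2, 2L), globalModule(E, swapped, 2L),
               tolerance = 1e-12)
})

test_that("messageFun composes neighbor and relation additively", {
  E <- rbind(c(1, 0), c(0, 0))
  R <- rbind(c(0, 1))
  expect_equal(messageFun(2, 1, 2, E, R, diag(2) * 0), c(0, 0))
  expect_equal(messageFun(2, 1, 1, E, R, diag(2)), c(1, 1))
  W <- rbind(c(2, 0), c(0, 3))
  expect_equal(messageFun(2, 1, 1, E, R, W), c(2, 3))
})

test_that("localModule softmax-weights messages over each neighborhood", {
  d <- 4L
  # one neighbor: beta = 1, output equals the message
  g1 <- knowledgeGraph(c("a", "b"), "r", rbind(c(1, 1, 2)))
  set.seed(7)
  E <- matrix(rnorm(2 * d), 2)
  R <- matrix(rnorm(2 * d), 2)
  lp <- list(Wphi = matrix(rnorm(d * d), d), a = rnorm(d))
  out <- localModule(E, R, g1, lp)
  expect_equal(out[1, ], messageFun(1, 1, 2, E, R, lp$Wphi),
               tolerance = 1e-12)
  # two identical messages: weights are (1/2, 1/2)
  g2 <- knowledgeGraph(c("a", "b", "c"), "r", rbind(c(1, 1, 2), c(1, 1, 3)))
  E2 <- rbind(rnorm(d), c(1, 2, 3, 4), c(1, 2, 3, 4))
  R2 <- matrix(rnorm(2 * d), 2)
  out2 <- localModule(E2, R2, g2, lp)
  expect_equal(out2[1, ], messageFun(1, 1, 2, E2, R2, lp$Wphi),
               tolerance = 1e-12)
  # hand softmax: logits (ln 2, 0) -> weights (2/3, 1/3)
  expect_equal(exp(log(2)) / (exp(log(2)) + 1), 2 / 3)
  # isolated nodes get a zero row
  g3 <- knowledgeGraph(c("a", "b", "z"), "r", rbind(c(1, 1, 2)))
  out3 <- localModule(matrix(rnorm(3 * d), 3), R, g3, lp)
  expect_equal(out3[3, ], rep(0, d))
})

test_that("local attention weights reproduce a hand-computed softmax", {
  # engineer gamma = (ln 2, 0) over a 2-edge neighborhood via Wphi and a
  d <- 2L
  g <- knowledgeGraph(c("u", "v", "w"), "r", rbind(c(1, 1, 2), c(1, 1, 3)))
  E <- rbind(c(0, 0), c(log(2), 0), c(0, 0))
  R <- matrix(0, 2, d)
  lp <- list(Wphi = diag(d), a = c(1, 0))
  # messages: (ln2, 0) and (0, 0); gammas ln2 and 0 -> betas 2/3, 1/3
  out <- localModule(E, R, g, lp)
  expect_equal(out[1, ], (2 / 3) * c(log(2), 0) + (1 / 3) * c(0, 0),
               tolerance = 1e-12)
})

test_that("fusion weights form a softmax over active branches", {
  d <- 4L
  e <- rnorm(d)
  w <- rnorm(d)
  # identical branches fuse to themselves with weights 1/3 each
  expect_equal(fuseFeatures(e, e, e, w), e, tolerance = 1e-12)
  # zero fusion vector gives uniform weights
  a <- rnorm(d); b <- rnorm(d); cc <- rnorm(d)
  expect_equal(fuseFeatures(a, b, cc, rep(0, d)), (a + b + cc) / 3,
               tolerance = 1e-12)
  # hand case: scores (ln 2, 0, 0) -> alpha (1/2, 1/4, 1/4)
  es <- c(log(2), 0); eg <- c(0, 0); el <- c(0, 0)
  expect_equal(fuseFeatures(es, eg, el, c(1, 0)),
               0.5 * es + 0.25 * eg + 0.25 * el, tolerance = 1e-12)
  # ablation zeroes a branch and renormalizes over the rest
  expect_equal(fuseFeatures(e, 100 * e, e, w, ablateGlobal = TRUE), e,
               tolerance = 1e-12)
  # sum and concat comparators
  expect_equal(fuseFeatures(a, b, cc, w, mode = "sum"), a + b + cc)
  Wc <- matrix(rnorm(3 * d * d), 3 * d, d)
  expect_equal(fuseFeatures(a, b, cc, w, mode = "concat", Wc = Wc),
               as.vector(c(a, b, cc) %*% Wc))
})

test_that("relationUpdate supports shared and layer-independent schemes", {
  R <- rbind(c(1, 2), c(3, 4))
  expect_equal(relationUpdate(R, Wrel = diag(2)), R)
  expect_equal(relationUpdate(matrix(0, 2, 2), Wrel = matrix(rnorm(4), 2)),
               matrix(0, 2, 2))
  expect_equal(relationUpdate(rbind(c(1, 2)), Wrel = rbind(c(0, 1), c(1, 0))),
               rbind(c(2, 1)))
  free <- matrix(rnorm(4), 2)
  expect_equal(relationUpdate(R, relTab = free, layerIndependent = TRUE),
               free)
})

test_that("query-conditioned initialization marks exactly the head row", {
  g <- toyGraph()
  R <- matrix(rnorm(6 * 4), 6)
  E <- initNodeStates(g, c(3L, 2L), R)
  expect_equal(E[3, ], R[2, ])
  expect_equal(sum(rowSums(abs(E)) > 0), 1L)
  expect_equal(initNodeStates(g, c(3L, 2L), matrix(0, 6, 4)),
               matrix(0, numEntities(g), 4))
  expect_error(initNodeStates(g, c(99L, 1L), R), "out of range")
})

test_that("scoreTriple is a sigmoid MLP with hidden width 64", {
  d <- 4L
  zero <- list(W1 = matrix(0, 3 * d, 64), b1 = rep(0, 64),
               w2 = rep(0, 64), b2 = 0)
  expect_equal(scoreTriple(rnorm(d), rnorm(d), rnorm(d), zero), 0.5)
  # engineered pre-activation ln 3 -> sigmoid(ln 3) = 3/4
  sc <- zero
  sc$W1[1, 1] <- 1; sc$w2[1] <- 1; sc$b2 <- 0
  eH <- c(log(3), 0, 0, 0)
  expect_equal(scoreTriple(eH, rep(0, d), rep(0, d), sc), 0.75)
  # strictly inside (0, 1) for random finite inputs
  set.seed(9)
  rp <- list(W1 = matrix(rnorm(3 * d * 64, sd = 0.2), 3 * d),
             b1 = rnorm(64, sd = 0.2),
             w2 = rnorm(64, sd = 0.2), b2 = rnorm(1, sd = 0.2))
  p <- scoreTriple(rnorm(d), rnorm(d), matrix(rnorm(10 * d), 10), rp)
  expect_length(p, 10L)
  expect_true(all(p > 0 & p < 1))
})

test_that("engine forward equals the composed per-layer operations", {
  g <- toyGraph(3L)
  variants <- list(
    list(), list(normalizeGlobal = TRUE), list(fusionMode = "sum"),
    list(fusionMode = "concat"), list(ablateGlobal = TRUE),
    list(ablateLocal = TRUE), list(layerIndependentRelations = TRUE),
    list(nTotalLayers = 1L, nBaseGnnLayers = 0L),
    list(nTotalLayers = 4L, nBaseGnnLayers = 4L))
  for (v in variants) {
    mp <- do.call(mkParams, c(list(g), v))
    eng <- forwardPass(g, c(2L, 1L), mp)
    ref <- chainForwardR(g, c(2L, 1L), mp)
    expect_lt(max(abs(eng$nodes - ref$nodes)), 1e-6)
    expect_lt(max(abs(eng$relations - ref$relations)), 1e-6)
  }
})

test_that("engine gradients match central finite differences", {
  g <- toyGraph()
  ed <- PlantKGR:::messageEdges(g)
  for (v in list(list(), list(normalizeGlobal = TRUE),
                 list(fusionMode = "concat"),
                 list(layerIndependentRelations = TRUE))) {
    mp <- do.call(mkParams, c(list(g), v))
    ecfg <- PlantKGR:::engineConfig(mp$config, mp$nRelations)
    stepLoss <- function(par) {
      PlantKGR:::engine_step(ed$dst - 1L, ed$rel - 1L, ed$src - 1L,
                             numEntities(g), par, ecfg,
                             1L, 0L, 5L, c(2L, 3L, 6L))
    }
    res <- stepLoss(mp$par)
    set.seed(31)
    idx <- sample(length(mp$par), 25L)
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      p1 <- mp$par; p1[i] <- p1[i] + eps
      p2 <- mp$par; p2[i] <- p2[i] - eps
      (stepLoss(p1)$loss - stepLoss(p2)$loss) / (2 * eps)
    }, 0)
    ana <- res$grad[idx]
    expect_lt(max(abs(num - ana) / pmax(1e-4, abs(num) + abs(ana))), 1e-3)
  }
})

test_that("all-zero weights propagate zero states through a full layer", {
  g <- toyGraph()
  mp <- mkParams(g, nTotalLayers = 1L, nBaseGnnLayers = 0L)
  mp$par[] <- 0
  fw <- forwardPass(g, c(1L, 1L), mp)
  expect_equal(max(abs(fw$nodes)), 0)
})

test_that("global ablation equals removing the global branch entirely", {
  g <- toyGraph(2L)
  mp <- mkParams(g, ablateGlobal = TRUE)
  fw <- forwardPass(g, c(1L, 2L), mp)
  # reference: chain with the global module physically absent
  cfg <- mp$config
  R <- relationTable(mp)
  E <- initNodeStates(g, c(1L, 2L), R)
  for (l in seq_len(cfg@nTotalLayers)) {
    lp <- layerParams(mp, l)
    El <- localModule(E, R, g, lp)
    E <- if (l <= cfg@nBaseGnnLayers) El else
      fuseFeatures(E, matrix(0, nrow(E), ncol(E)), El, lp$w,
                   ablateGlobal = TRUE)
    if (l < cfg@nTotalLayers) R <- relationUpdate(R, Wrel = lp$Wrel)
  }
  expect_lt(max(abs(fw$nodes - E)), 1e-9)
})

test_that("scoring is invariant to entity relabeling", {
  g <- toyGraph(5L)
  mp <- mkParams(g, normalizeGlobal = TRUE)
  scorer <- scorerParams(mp)
  fw <- forwardPass(g, c(2L, 1L), mp)
  p0 <- scoreTriple(fw$nodes[2, ], fw$relations[1, ], fw$nodes[6, ], scorer)
  tr <- tripleMatrix(g)
  set.seed(21)
  for (i in 1:5) {
    perm <- sample(numEntities(g))
    gP <- knowledgeGraph(entityLabels(g)[order(perm)], relationLabels(g),
                         cbind(perm[tr[, 1]], tr[, 2], perm[tr[, 3]]))
    fwP <- forwardPass(gP, c(perm[2L], 1L), mp)
    pP <- scoreTriple(fwP$nodes[perm[2L], ], fwP$relations[1, ],
                      fwP$nodes[perm[6L], ], scorer)
    expect_equal(pP, p0, tolerance = 1e-9)
  }
})

test_that("global-module cost grows linearly in the entity count", {
  d <- 32L
  mc <- modelConfig(dim = d, nHeads = 4L, seed = 3L)
  mp <- initParams(mc, 4L)
  lp <- layerParams(mp, 3L)
  set.seed(12)
  macs <- vapply(c(64L, 128L, 256L, 512L), function(n) {
    E <- matrix(rnorm(n * d), n)
    globalModuleOps <- PlantKGR:::globalModuleOps
    globalModuleOps(E, lp, 4L)$macs
  }, 0)
  ratios <- macs[-1] / macs[-length(macs)]
  expect_true(all(ratios <= 2.2))
})

test_that("pre-trained relation embeddings can be imported", {
  g <- toyGraph()
  mp <- mkParams(g)
  f <- tempfile()
  v <- round(rnorm(8), 3)
  writeLines(c(paste0("r2\t", paste(v, collapse = ",")),
               paste0("r1#inv\t", paste(rev(v), collapse = ","))), f)
  mp2 <- importRelationEmbeddings(mp, f, relationLabels(g))
  expect_equal(relationTable(mp2)[2, ], v)
  expect_equal(relationTable(mp2)[numRelations(g) + 1L, ], rev(v))
  expect_error(importRelationEmbeddings(mp, {
    f2 <- tempfile(); writeLines("nope\t1,2", f2); f2
  }, relationLabels(g)), "unknown relation")
})
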