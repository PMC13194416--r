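# Independent oracles and small fixture builders shared across test files.

# Compose the exported per-layer operations in plain R: the reference
# implementation of the full forward pass, kept independent of the compiled
# engine it is used to check.
chainForwardR <- function(graph, query, mp) {
  cfg <- mp$config
  R <- relationTable(mp)
  E <- initNodeStates(graph, query, R)
  L <- cfg@nTotalLayers
  for (l in seq_len(L)) {
    lp <- layerParams(mp, l)
    if (l <= cfg@nBaseGnnLayers && cfg@ablateLocal) {
      # the base GNN is the local channel; ablating it idles the base stage
      if (l < L)
        R <- relationUpdate(R, Wrel = lp$Wrel, relTab = lp$relTab,
                            layerIndependent = cfg@layerIndependentRelations)
      next
    }
    El <- localModule(E, R, graph, lp)
    if (l <= cfg@nBaseGnnLayers) {
      E <- El
    } else {
      Eg <- if (cfg@ablateGlobal) matrix(0, nrow(E), ncol(E))
            else globalModule(E, lp, cfg@nHeads, cfg@normalizeGlobal)
      if (cfg@ablateLocal) El <- matrix(0, nrow(E), ncol(E))
      E <- fuseFeatures(E, Eg, El, lp$w, cfg@fusionMode,
                        cfg@ablateGlobal, cfg@ablateLocal, Wc = lp$Wc)
    }
    if (l < L)
      R <- relationUpdate(R, Wrel = lp$Wrel, relTab = lp$relTab,
                          layerIndependent = cfg@layerIndependentRelations)
  }
  list(nodes = E, relations = R)
}

# Quadratic-order attention oracle: materializes the full |E| x |E| kernel
# score matrix instead of using associativity.
quadraticAttentionOracle <- function(E, Wq, Wk, Wv, normalize = FALSE) {
  P <- kernelPhi(E %*% Wq)
  S <- kernelPhi(E %*% Wk)
  V <- E %*% Wv
  A <- P %*% t(S)              # |E| x |E|
  out <- A %*% V
  if (normalize) out <- out / pmax(rowSums(A), 1e-12)
  out
}

# Brute-force Hits@k: literal counting.
bruteHits <- function(ranks, k) sum(ranks <= k) / length(ranks)

# Brute-force average precision: walk the descending-score list one
# distinct threshold at a time and accumulate precision at each recall step.
bruteAP <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels == 1)
  ap <- 0
  prevTP <- 0
  for (s in thr) {
    sel <- scores >= s
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    ap <- ap + (tp - prevTP) / nPos * prec
    prevTP <- tp
  }
  ap
}

# Line-by-line triple-file reader independent of readTriples.
rawTripleSet <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  sort(unique(vapply(strsplit(lines, "\t"), function(p)
    paste(p[1:3], collapse = "\30"), "")))
}

# A small multi-relational graph with branches, a cycle and an isolated-ish
# tail, used throughout the model tests.
toyGraph <- function(nExtra = 0L) {
  ents <- c(paste0("n", 1:7), if (nExtra > 0L) paste0("x", seq_len(nExtra)))
  tr <- rbind(c(1, 1, 2), c(2, 1, 3), c(3, 2, 4), c(4, 1, 5), c(5, 2, 6),
              c(2, 3, 6), c(7, 1, 1), c(3, 3, 7))
  if (nExtra > 1L) {
    xs <- 7L + seq_len(nExtra)
    tr <- rbind(tr, cbind(xs[-length(xs)], 1L, xs[-1L]), c(1L, 2L, xs[1L]))
  }
  knowledgeGraph(ents, c("r1", "r2", "r3"), tr)
}

# A small but trainable synthetic benchmark for fast train/eval tests.
tinyBenchmark <- function(seed = 42L) {
  cfg <- generatorConfig(nGroups = 5L, nOrders = 3L, nFamiliesPerOrder = 1L,
                         nGeneraPerFamily = 1L, nSpeciesPerGenus = 2L,
                         nEcoChains = 4L, ecoChainLength = 4L,
                         noiseEdgeRate = 0.1, seed = seed)
  gen <- generatePlantKG(cfg)
  makeInductiveBenchmark(gen$graph, gen$ruleInstances,
                         partitionConfig(seed = seed))
}
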