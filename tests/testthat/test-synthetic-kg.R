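# Synthetic plant-KG generator and random-walk inductive partitioning.

test_that("minimal config emits one full 4-hop taxonomy chain", {
  cfg <- generatorConfig(nGroups = 1L, nOrders = 1L, nFamiliesPerOrder = 1L,
                         nGeneraPerFamily = 1L, nSpeciesPerGenus = 2L,
                         nEcoChains = 0L, noiseEdgeRate = 0, seed = 1L)
  gen <- generatePlantKG(cfg)
  g <- gen$graph
  # 2 species + genus + family + order + class root
  expect_equal(numEntities(g), 6L)
  sp <- grep("^species_", entityLabels(g))
  cl <- grep("^class_", entityLabels(g))
  D <- igraph::distances(PlantKGR:::asUndirectedIgraph(g))
  expect_equal(unname(D[sp, cl]), c(4, 4))
  # one 4-hop rule instance per species, tail = class root
  expect_equal(nrow(gen$ruleInstances), 2L)
  expect_true(all(gen$ruleInstances[, 3L] == cl))
})

test_that("without noise every triple matches a schema signature", {
  cfg <- generatorConfig(nGroups = 2L, nOrders = 3L, nSpeciesPerGenus = 2L,
                         nEcoChains = 2L, ecoChainLength = 4L,
                         noiseEdgeRate = 0, seed = 3L)
  g <- generatePlantKG(cfg)$graph
  tr <- tripleMatrix(g)
  labs <- entityLabels(g)
  lvl <- function(i) sub("_.*", "", labs[i])
  relName <- relationLabels(g)[tr[, 2L]]
  expected <- list(
    in_genus = c("species", "genus"), in_family = c("genus", "family"),
    in_order = c("family", "order"), in_class = c("order", "class"))
  for (i in seq_len(nrow(tr))) {
    rn <- relName[i]
    if (rn %in% names(expected)) {
      expect_equal(c(lvl(tr[i, 1L]), lvl(tr[i, 3L])), expected[[rn]])
    } else {
      # eco-chain edges: head is a species (chain start) or an eco node
      expect_true(lvl(tr[i, 1L]) %in% c("species", "eco"))
    }
  }
})

test_that("generation is seed-deterministic down to file bytes", {
  cfg <- presetGeneratorConfig("taxo-deep", seed = 42L)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  writeTriples(generatePlantKG(cfg)$graph, f1)
  writeTriples(generatePlantKG(cfg)$graph, f2)
  writeTriples(generatePlantKG(presetGeneratorConfig("taxo-deep",
                                                     seed = 7L))$graph, f3)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(f3))))
})

test_that("decoy clades share the class-root type signature", {
  cfg <- generatorConfig(nGroups = 2L, nOrders = 2L, decoyClasses = TRUE,
                         nEcoChains = 0L, noiseEdgeRate = 0, seed = 5L)
  g <- generatePlantKG(cfg)$graph
  labs <- entityLabels(g)
  clades <- grep("^clade_", labs)
  expect_length(clades, 4L)
  inClass <- match("in_class", relationLabels(g))
  for (cl in clades) {
    nb <- PlantKGR:::buildAdjacency(numEntities(g), tripleMatrix(g))[[cl]]
    # a clade's only incident edge is an inbound in_class link (leaf)
    expect_equal(nrow(nb), 1L)
    expect_equal(unname(nb[1L, "rel"]), inClass)
    expect_equal(unname(nb[1L, "dir"]), 2L)
  }
  # clades are never rule-instance tails
  gen <- generatePlantKG(cfg)
  expect_false(any(gen$ruleInstances[, 3L] %in% clades))
})

test_that("restart probability 1 confines every walk to its start", {
  g <- toyGraph(3L)
  subs <- randomWalkPartition(g, partitionConfig(restartProbability = 1,
                                                 seed = 42L))
  expect_true(all(lengths(subs) == 1L))
  expect_equal(sort(unlist(subs)), seq_len(numEntities(g)))
})

test_that("a single-edge graph merges into one two-node subgraph", {
  g <- knowledgeGraph(c("a", "b"), "r", rbind(c(1, 1, 2)))
  subs <- randomWalkPartition(g, partitionConfig(seed = 42L))
  expect_equal(subs, list(c(1L, 2L)))
})

test_that("partition subsets are pairwise disjoint and components never mix", {
  gen <- generatePlantKG(presetGeneratorConfig("taxo-deep", seed = 42L))
  comp <- igraph::components(PlantKGR:::asUndirectedIgraph(gen$graph))
  for (sd in c(42L, 123L, 456L, 789L)) {
    subs <- randomWalkPartition(gen$graph, partitionConfig(seed = sd))
    all_nodes <- unlist(subs)
    expect_equal(anyDuplicated(all_nodes), 0L)
    for (s in subs) expect_length(unique(comp$membership[s]), 1L)
  }
})

test_that("subgraph assignment follows the floor(trainFraction * n) rule", {
  # eight separate two-node components -> eight subgraphs -> 6/2 split
  tr <- cbind(seq(1, 15, by = 2), 1L, seq(2, 16, by = 2))
  g <- knowledgeGraph(paste0("n", 1:16), "r", tr)
  subs <- randomWalkPartition(g, partitionConfig(seed = 42L))
  expect_length(subs, 8L)
  rules <- cbind(seq(1, 15, by = 2), 1L, seq(2, 16, by = 2))
  # use a separate query relation so queries are not message edges
  g2 <- knowledgeGraph(paste0("n", 1:16), c("r", "linked"), tr)
  rules[, 2L] <- 2L
  split <- makeInductiveBenchmark(g2, rules, partitionConfig(seed = 42L))
  expect_equal(numEntities(trainGraph(split)), 12L)  # 6 of 8 subgraphs
  expect_equal(numEntities(testGraph(split)), 4L)
})

test_that("inductive splits are entity-disjoint with no query leakage", {
  gen <- generatePlantKG(presetGeneratorConfig("taxo-deep", seed = 42L))
  for (sd in c(42L, 456L)) {
    split <- makeInductiveBenchmark(gen$graph, gen$ruleInstances,
                                    partitionConfig(seed = sd))
    expect_length(intersect(entityLabels(trainGraph(split)),
                            entityLabels(testGraph(split))), 0L)
    key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])
    expect_false(any(key(testQueries(split)) %in%
                     key(tripleMatrix(testGraph(split)))))
  }
})

test_that("every test query has its full proof path in the test graph", {
  gen <- generatePlantKG(presetGeneratorConfig("taxo-deep", seed = 42L))
  split <- makeInductiveBenchmark(gen$graph, gen$ruleInstances,
                                  partitionConfig(seed = 42L))
  k <- 4L
  tg <- testGraph(split)
  D <- igraph::distances(PlantKGR:::asUndirectedIgraph(tg))
  q <- testQueries(split)
  expect_gt(nrow(q), 0L)
  for (i in seq_len(nrow(q))) {
    expect_lte(D[q[i, 1L], q[i, 3L]], k)  # provable within k hops
  }
})

test_that("benchmark construction is reproducible from config + seed", {
  s1 <- tinyBenchmark(seed = 11L)
  s2 <- tinyBenchmark(seed = 11L)
  expect_identical(tripleMatrix(trainGraph(s1)), tripleMatrix(trainGraph(s2)))
  expect_identical(tripleMatrix(testGraph(s1)), tripleMatrix(testGraph(s2)))
  expect_identical(testQueries(s1), testQueries(s2))
  expect_identical(validQueries(s1), validQueries(s2))
})

test_that("preset splits reproduce the two average-distance regimes", {
  for (preset in c("taxo-deep", "eco-dense")) {
    gen <- generatePlantKG(presetGeneratorConfig(preset, seed = 42L))
    split <- makeInductiveBenchmark(gen$graph, gen$ruleInstances,
                                    partitionConfig(seed = 42L))
    dTrain <- avgReachableDistance(trainGraph(split))
    dTest <- avgReachableDistance(testGraph(split))
    if (preset == "taxo-deep") expect_gt(dTest, dTrain)
    else expect_lt(dTest, dTrain)
    # both presets sit in the few-hop regime reported for real plant KGs
    expect_true(all(c(dTrain, dTest) > 3 & c(dTrain, dTest) < 8))
  }
})

test_that("degenerate partitions are rejected with guidance", {
  g <- knowledgeGraph(c("a", "b"), c("r", "t"), rbind(c(1, 1, 2)))
  expect_error(
    makeInductiveBenchmark(g, cbind(1L, 2L, 2L), partitionConfig(seed = 1L)),
    "need >= 2")
})
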