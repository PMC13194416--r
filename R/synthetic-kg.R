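#' @include kg-core.R
NULL

# Fixed relation schema of the generator.  Four taxonomy levels above the
# species tier and five ecological association relations; the held-out
# compositional target relations are part of the vocabulary but never occur
# as graph edges (they are the prediction targets).
TAXO_RELATIONS <- c("in_genus", "in_family", "in_order", "in_class")
ECO_RELATIONS  <- c("infected_by", "vector_of", "natural_enemy_of",
                    "grows_in", "companion_of")

#' Generate a synthetic plant-style knowledge graph
#'
#' The graph consists of `nGroups` connected components.  Each group holds
#' `nOrders` taxonomy trees (species, genus, family, order, and one
#' class-level root per order, so every species sits at the end of a 4-hop
#' chain), bridged into one component by companion-plant edges between
#' consecutive orders' species.  Ecological association chains of
#' `ecoChainLength` hops hang off seeded species, and random intra-group
#' noise edges whose relation types follow a power law emulate the
#' imbalanced relation frequencies of real plant KGs.
#'
#' Alongside the graph, the generator returns the rule instances of the
#' held-out compositional target relation: every
#' `(species, taxon_ancestor_k, ancestor)` pair implied by composing exactly
#' `targetRelationHops` taxonomy edges, plus `(species, eco_assoc_k, node)`
#' endpoint pairs for the ecological chains.  These triples are prediction
#' targets and are never edges of the graph.  Because every order carries
#' its own class-level root, each component offers many nodes with the same
#' local type signature as the true answer; ranking the correct ancestor
#' requires composing the full path, not recognizing the node type.
#'
#' @param config a [GeneratorConfig-class].
#' @return A list with elements `graph` (a [KnowledgeGraph-class]) and
#'   `ruleInstances` (integer triple matrix; `attr(, "support")` holds, per
#'   instance, the entity-index path that proves it).
#' @export
generatePlantKG <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  k <- config@targetRelationHops

  ents <- character(0)
  entId <- function(lab) match(lab, ents)
  heads <- integer(0); rels <- integer(0); tails <- integer(0)

  relLabels <- c(TAXO_RELATIONS, ECO_RELATIONS)
  taxoTarget <- paste0("taxon_ancestor_", k)
  ecoTarget <- paste0("eco_assoc_", k)
  hasEcoRules <- config@nEcoChains > 0L && config@ecoChainLength >= k
  relLabels <- c(relLabels, taxoTarget, if (hasEcoRules) ecoTarget)
  relId <- function(lab) match(lab, relLabels)

  nG <- config@nGroups
  groupEntities <- vector("list", nG)   # entity ids per group
  groupSpecies <- vector("list", nG)
  speciesPaths <- list()                # species -> class-root chains
  bridgeEnds <- vector("list", nG)      # one species per order, for bridges

  # --- taxonomy trees: nOrders per group, one class root per order ---------
  for (gp in seq_len(nG)) {
    nOrd <- if (gp == 1L) {
      as.integer(round(config@nOrders * config@megaGroupFactor))
    } else config@nOrders
    gEnts <- integer(0); gSpecies <- integer(0); ends <- integer(0)
    for (o in seq_len(nOrd)) {
      classLab <- sprintf("class_%02d_%02d", gp, o)
      orderLab <- sprintf("order_%02d_%02d", gp, o)
      ents <- c(ents, classLab, orderLab)
      gEnts <- c(gEnts, entId(classLab), entId(orderLab))
      heads <- c(heads, entId(orderLab)); rels <- c(rels, relId("in_class"))
      tails <- c(tails, entId(classLab))
      for (f in seq_len(config@nFamiliesPerOrder)) {
        famLab <- sprintf("family_%02d_%02d_%02d", gp, o, f)
        ents <- c(ents, famLab); gEnts <- c(gEnts, entId(famLab))
        heads <- c(heads, entId(famLab)); rels <- c(rels, relId("in_order"))
        tails <- c(tails, entId(orderLab))
        for (g in seq_len(config@nGeneraPerFamily)) {
          genLab <- sprintf("genus_%02d_%02d_%02d_%02d", gp, o, f, g)
          ents <- c(ents, genLab); gEnts <- c(gEnts, entId(genLab))
          heads <- c(heads, entId(genLab))
          rels <- c(rels, relId("in_family"))
          tails <- c(tails, entId(famLab))
          for (s in seq_len(config@nSpeciesPerGenus)) {
            spLab <- sprintf("species_%02d_%02d_%02d_%02d_%02d",
                             gp, o, f, g, s)
            ents <- c(ents, spLab)
            spId <- entId(spLab)
            gEnts <- c(gEnts, spId); gSpecies <- c(gSpecies, spId)
            heads <- c(heads, spId); rels <- c(rels, relId("in_genus"))
            tails <- c(tails, entId(genLab))
            speciesPaths[[length(speciesPaths) + 1L]] <-
              c(spId, entId(genLab), entId(famLab), entId(orderLab),
                entId(classLab))
          }
        }
      }
      if (config@decoyClasses) {
        # unranked clade leaf: same local type signature as a class root,
        # but hanging off the family level -- a distractor for models that
        # recognize node types instead of composing the 4-hop path
        cladeLab <- sprintf("clade_%02d_%02d", gp, o)
        ents <- c(ents, cladeLab)
        gEnts <- c(gEnts, entId(cladeLab))
        firstFam <- entId(sprintf("family_%02d_%02d_%02d", gp, o, 1L))
        heads <- c(heads, firstFam); rels <- c(rels, relId("in_class"))
        tails <- c(tails, entId(cladeLab))
      }
      ends <- c(ends, gSpecies[length(gSpecies)])  # last species of order o
    }
    # companion-plant bridges stitch the group's order trees together:
    # in series (deep paths) or as a star (dense hub) for the dominant group
    if (nOrd > 1L) {
      star <- gp == 1L && config@megaGroupFactor > 1 &&
        config@megaGroupStyle == "dense"
      for (o in seq_len(nOrd - 1L)) {
        from <- if (star) ends[1L] else ends[o]
        heads <- c(heads, from); rels <- c(rels, relId("companion_of"))
        tails <- c(tails, ends[o + 1L])
      }
    }
    groupEntities[[gp]] <- gEnts
    groupSpecies[[gp]] <- gSpecies
    bridgeEnds[[gp]] <- ends
  }
  if (length(ents) < 2L) stopData("config implies fewer than 2 entities")

  # --- ecological association chains --------------------------------------
  chainPaths <- list()
  if (config@nEcoChains > 0L) {
    # chains cycle over the homogeneous groups; a dominant group (if any)
    # keeps its pure taxonomic structure
    chainGroups <- if (config@megaGroupFactor > 1 && nG > 1L) {
      2L + ((seq_len(config@nEcoChains) - 1L) %% (nG - 1L))
    } else {
      1L + ((seq_len(config@nEcoChains) - 1L) %% nG)
    }
    startPick <- withSeed(deriveSeed(config@seed, "eco-starts"), {
      vapply(seq_len(config@nEcoChains), function(cc) {
        sp <- groupSpecies[[chainGroups[cc]]]
        sp[sample.int(length(sp), 1L)]
      }, integer(1))
    })
    for (cc in seq_len(config@nEcoChains)) {
      gp <- chainGroups[cc]
      prev <- startPick[cc]
      path <- prev
      for (pos in seq_len(config@ecoChainLength)) {
        lab <- sprintf("eco_%02d_%03d_%02d", gp, cc, pos)
        ents <- c(ents, lab)
        nd <- entId(lab)
        groupEntities[[gp]] <- c(groupEntities[[gp]], nd)
        rel <- ECO_RELATIONS[((pos - 1L) %% length(ECO_RELATIONS)) + 1L]
        heads <- c(heads, prev); rels <- c(rels, relId(rel))
        tails <- c(tails, nd)
        prev <- nd
        path <- c(path, nd)
      }
      chainPaths[[cc]] <- path
    }
  }

  nSchema <- length(heads)

  # --- noise edges: intra-group, power-law relation frequencies ------------
  nNoise <- round(config@noiseEdgeRate * nSchema)
  if (nNoise > 0L) {
    # power-law relation frequencies, upper taxonomy levels first: spurious
    # links concentrate at the coarse levels, so class-level type signatures
    # alone cannot identify an ancestor -- only the composed path can
    graphRels <- c(rev(TAXO_RELATIONS), ECO_RELATIONS)
    relWeights <- seq_along(graphRels)^(-1.5)
    sizes <- lengths(groupEntities)
    grpWeights <- switch(config@noiseAllocation,
      "uniform" = rep(1, nG),
      "by-size" = sizes * (sizes - 1) / 2,
      "inverse-size" = 1 / sizes)
    noise <- withSeed(deriveSeed(config@seed, "noise"), {
      grp <- sample.int(nG, nNoise, replace = TRUE, prob = grpWeights)
      rl <- sample.int(length(graphRels), nNoise, replace = TRUE,
                       prob = relWeights)
      ep <- t(vapply(grp, function(gp) {
        ge <- groupEntities[[gp]]
        ge[sample.int(length(ge), 2L)]
      }, integer(2)))
      cbind(ep[, 1L], rl, ep[, 2L])
    })
    heads <- c(heads, noise[, 1L])
    rels <- c(rels, noise[, 2L])
    tails <- c(tails, noise[, 3L])
  }

  graph <- knowledgeGraph(ents, relLabels, cbind(heads, rels, tails))

  # --- held-out rule instances ---------------------------------------------
  ruleH <- integer(0); ruleR <- integer(0); ruleT <- integer(0)
  support <- list()
  for (p in speciesPaths) {
    ruleH <- c(ruleH, p[1L]); ruleR <- c(ruleR, relId(taxoTarget))
    ruleT <- c(ruleT, p[k + 1L])
    support[[length(support) + 1L]] <- p[seq_len(k + 1L)]
  }
  if (hasEcoRules) {
    for (p in chainPaths) {
      ruleH <- c(ruleH, p[1L]); ruleR <- c(ruleR, relId(ecoTarget))
      ruleT <- c(ruleT, p[k + 1L])
      support[[length(support) + 1L]] <- p[seq_len(k + 1L)]
    }
  }
  ruleInstances <- cbind(head = ruleH, relation = ruleR, tail = ruleT)
  attr(ruleInstances, "support") <- support
  logInfo("generated graph: ", length(ents), " entities, ",
          numTriples(graph), " triples, ", nrow(ruleInstances),
          " rule instances")
  list(graph = graph, ruleInstances = ruleInstances)
}

#' Preset generator configurations
#'
#' Two study regimes are provided, differing in which side of the split
#' ends up with the longer reasoning paths.  Both presets contain one
#' dominant order group (three times the usual family count) among seven
#' homogeneous groups; the random-walk partition assigns whole groups to
#' sides, and with 6 of 8 subgraphs going to training the dominant group
#' lands on the training side for most partition seeds, where its pair
#' count dominates the side's average distance.
#'
#' `"taxo-deep"` makes the dominant group locally dense (shortcut noise
#' allocated by pair count) while the small groups carry long ecological
#' chains: held-out test subgraphs then show *longer* average
#' reachable-pair distances than training.  `"eco-dense"` reverses the
#' construction — the dominant group is a pure deep taxonomy and the small
#' groups absorb the shortcut edges — so the training side shows the longer
#' distances.
#'
#' @param name `"taxo-deep"` or `"eco-dense"`.
#' @param seed integer RNG seed.
#' @return A [GeneratorConfig-class].
#' @export
presetGeneratorConfig <- function(name = c("taxo-deep", "eco-dense"),
                                  seed = 42L) {
  name <- match.arg(name)
  switch(name,
    "taxo-deep" = generatorConfig(
      nGroups = 9L, nOrders = 5L, nFamiliesPerOrder = 1L,
      nGeneraPerFamily = 1L, nSpeciesPerGenus = 1L,
      nEcoChains = 12L, ecoChainLength = 6L,
      targetRelationHops = 4L, noiseEdgeRate = 0.20,
      decoyClasses = TRUE,
      megaGroupFactor = 3, megaGroupStyle = "dense",
      noiseAllocation = "by-size", seed = seed),
    "eco-dense" = generatorConfig(
      nGroups = 9L, nOrders = 5L, nFamiliesPerOrder = 1L,
      nGeneraPerFamily = 1L, nSpeciesPerGenus = 2L,
      nEcoChains = 12L, ecoChainLength = 4L,
      targetRelationHops = 4L, noiseEdgeRate = 0.30,
      decoyClasses = TRUE,
      megaGroupFactor = 3, megaGroupStyle = "deep",
      noiseAllocation = "inverse-size", seed = seed)
  )
}

# ---------------------------------------------------------------------------
# Random-walk partitioning
# ---------------------------------------------------------------------------

#' Carve a graph into disjoint entity subsets by random walks with restart
#'
#' From every node, `walksPerNode` walks of `walkLength` steps are run on
#' the undirected view; before each step the walker teleports back to its
#' start node with probability `restartProbability`.  Each start's visited
#' set is a candidate subgraph; candidates with overlapping entity sets are
#' greedily merged (union-find) until all subgraph entity sets are disjoint.
#' Disconnected components are handled naturally: no walk crosses a
#' component boundary, so each component is processed independently.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param config a [PartitionConfig-class].
#' @return List of disjoint sorted integer vectors of entity indices whose
#'   union covers all visited nodes.
#' @export
randomWalkPartition <- function(graph, config) {
  stopifnot(is(graph, "KnowledgeGraph"), is(config, "PartitionConfig"))
  validObject(config)
  n <- length(graph@entities)
  if (n == 0L) stopData("cannot partition an empty graph")
  tr <- graph@triples
  nbrs <- vector("list", n)
  if (nrow(tr) > 0L) {
    ends <- cbind(c(tr[, 1L], tr[, 3L]), c(tr[, 3L], tr[, 1L]))
    ends <- ends[ends[, 1L] != ends[, 2L], , drop = FALSE]
    sp <- split(ends[, 2L], factor(ends[, 1L], levels = seq_len(n)))
    nbrs <- lapply(sp, function(x) unique(sort(x)))
  } else {
    for (i in seq_len(n)) nbrs[[i]] <- integer(0)
  }

  p <- config@restartProbability
  cands <- withSeed(config@seed, {
    lapply(seq_len(n), function(s) {
      vis <- logical(n)
      vis[s] <- TRUE
      if (length(nbrs[[s]]) > 0L) {
        for (w in seq_len(config@walksPerNode)) {
          cur <- s
          restart <- runif(config@walkLength) < p
          for (st in seq_len(config@walkLength)) {
            if (restart[st]) {
              cur <- s           # the teleport consumes the step
            } else {
              nb <- nbrs[[cur]]
              if (length(nb) == 0L) break
              cur <- nb[sample.int(length(nb), 1L)]
              vis[cur] <- TRUE
            }
          }
        }
      }
      which(vis)
    })
  })

  # greedy merge of overlapping candidates via union-find on first claimers
  parent <- seq_len(n + length(cands))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  uni <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  owner <- integer(n)
  for (i in seq_along(cands)) {
    ci <- n + i
    for (node in cands[[i]]) {
      if (owner[node] == 0L) owner[node] <- i else uni(n + owner[node], ci)
    }
  }
  roots <- vapply(seq_along(cands), function(i) find(n + i), integer(1))
  merged <- lapply(split(seq_along(cands), roots),
                   function(ix) sort(unique(unlist(cands[ix]))))
  merged <- unname(merged)
  merged[order(vapply(merged, min, integer(1)))]
}

# Induce the subgraph on an entity subset: triples with both endpoints
# inside, entity vocab restricted (fresh contiguous indices, original label
# order), relation vocab shared with the parent graph.
induceSide <- function(graph, entitySet) {
  entitySet <- sort(entitySet)
  keepLab <- graph@entities[entitySet]
  tr <- graph@triples
  inSide <- tr[, 1L] %in% entitySet & tr[, 3L] %in% entitySet
  tr <- tr[inSide, , drop = FALSE]
  remap <- integer(length(graph@entities))
  remap[entitySet] <- seq_along(entitySet)
  knowledgeGraph(keepLab, graph@relations,
                 cbind(remap[tr[, 1L]], tr[, 2L], remap[tr[, 3L]]))
}

#' Build an inductive train/test benchmark from a graph and rule instances
#'
#' Partitions the graph by [randomWalkPartition()], assigns
#' `floor(trainFraction * nSubgraphs)` subgraphs to the training side at
#' random (seeded) and the rest to the test side, induces each side's
#' message graph from triples with both endpoints inside the side, and
#' relabels test entities into a fresh vocabulary.  Rule instances whose
#' proof path lies wholly inside the test side become test queries; of the
#' train-side instances, a seeded 10% become validation queries and the
#' remainder training queries.  The constructed split is checked against the
#' inductive invariants (entity-disjoint sides, no query leaking into the
#' message graph).
#'
#' @param graph a [KnowledgeGraph-class].
#' @param ruleInstances integer triple matrix (with optional
#'   `attr(, "support")` proof paths, as produced by [generatePlantKG()]).
#' @param config a [PartitionConfig-class].
#' @return An [InductiveSplit-class].
#' @export
makeInductiveBenchmark <- function(graph, ruleInstances, config) {
  stopifnot(is(graph, "KnowledgeGraph"), is(config, "PartitionConfig"))
  subs <- randomWalkPartition(graph, config)
  if (length(subs) < 2L)
    stopData("partition produced ", length(subs),
             " subgraph(s); need >= 2 for an inductive split")
  nTrain <- max(1L, min(length(subs) - 1L,
                        floor(config@trainFraction * length(subs))))
  perm <- withSeed(deriveSeed(config@seed, "assign"),
                   sample.int(length(subs)))
  trainSet <- sort(unlist(subs[perm[seq_len(nTrain)]]))
  testSet <- sort(unlist(subs[perm[(nTrain + 1L):length(subs)]]))

  trainG <- induceSide(graph, trainSet)
  testG <- induceSide(graph, testSet)
  if (nrow(trainG@triples) == 0L || nrow(testG@triples) == 0L)
    stopData("a side has an empty message graph; regenerate with a larger graph")

  support <- attr(ruleInstances, "support")
  sideQueries <- function(side, sideGraph) {
    inSide <- if (is.null(support)) {
      ruleInstances[, 1L] %in% side & ruleInstances[, 3L] %in% side
    } else {
      vapply(seq_len(nrow(ruleInstances)),
             function(i) all(support[[i]] %in% side), logical(1))
    }
    q <- ruleInstances[inSide, , drop = FALSE]
    remap <- integer(length(graph@entities))
    remap[sort(side)] <- seq_along(side)
    cbind(remap[q[, 1L]], q[, 2L], remap[q[, 3L]])
  }
  trainQ <- sideQueries(trainSet, trainG)
  testQ <- sideQueries(testSet, testG)
  if (nrow(testQ) == 0L)
    stopData("no provable rule instance fell on the test side; ",
             "regenerate with a larger graph or another partition seed")
  if (nrow(trainQ) < 2L)
    stopData("too few train-side rule instances; regenerate with a larger graph")
  nValid <- max(1L, round(0.1 * nrow(trainQ)))
  vIdx <- withSeed(deriveSeed(config@seed, "valid"),
                   sort(sample.int(nrow(trainQ), nValid)))
  split <- new("InductiveSplit",
               train_graph = trainG, test_graph = testG,
               train_queries = trainQ[-vIdx, , drop = FALSE],
               valid_queries = trainQ[vIdx, , drop = FALSE],
               test_queries = testQ)
  validObject(split)
  logInfo("inductive split: ", length(subs), " subgraphs -> ",
          nTrain, " train / ", length(subs) - nTrain, " test; ",
          nrow(split@train_queries), "/", nrow(split@valid_queries), "/",
          nrow(split@test_queries), " train/valid/test queries")
  split
}
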