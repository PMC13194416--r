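#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# KnowledgeGraph
# ---------------------------------------------------------------------------

#' Knowledge graph with entity/relation vocabularies and an adjacency index
#'
#' A `KnowledgeGraph` holds the graph \eqn{G = (E, R, T)}: an ordered entity
#' vocabulary, an ordered relation vocabulary, and a duplicate-free set of
#' (head, relation, tail) triples stored as 1-based index rows.  An adjacency
#' index (built at construction) maps each entity to its incident triples and
#' backs neighborhood queries and message-passing edge lists.
#'
#' Indices are contiguous and 1-based; label/index mapping is a bijection.
#' The inverse-augmented relation index of relation `r` is `r + |R|`.
#'
#' @slot entities character vector of unique entity labels (index = position).
#' @slot relations character vector of unique relation labels.
#' @slot triples integer matrix with columns `head`, `relation`, `tail`.
#' @slot adjacency list, one integer matrix per entity with columns `rel`,
#'   `nbr`, `dir` (`dir` 1 = entity is head, 2 = entity is tail).
#'
#' @seealso [knowledgeGraph()], [readTriples()], [neighborhoodOf()]
#' @export
setClass("KnowledgeGraph",
  representation(
    entities  = "character",
    relations = "character",
    triples   = "matrix",
    adjacency = "list"
  )
)

setValidity("KnowledgeGraph", function(object) {
  msgs <- character()
  tr <- object@triples
  if (!is.integer(tr) || ncol(tr) != 3L)
    msgs <- c(msgs, "triples must be an integer matrix with 3 columns")
  if (anyDuplicated(object@entities))
    msgs <- c(msgs, "entity labels must be unique")
  if (anyDuplicated(object@relations))
    msgs <- c(msgs, "relation labels must be unique")
  if (is.integer(tr) && nrow(tr) > 0L) {
    nE <- length(object@entities); nR <- length(object@relations)
    if (any(tr[, c(1L, 3L)] < 1L) || any(tr[, c(1L, 3L)] > nE))
      msgs <- c(msgs, "entity index out of range in triples")
    if (any(tr[, 2L] < 1L) || any(tr[, 2L] > nR))
      msgs <- c(msgs, "relation index out of range in triples")
    if (anyDuplicated(tr))
      msgs <- c(msgs, "duplicate triples are not allowed")
  }
  if (length(object@adjacency) != length(object@entities))
    msgs <- c(msgs, "adjacency must have one entry per entity")
  if (length(msgs)) msgs else TRUE
})

buildAdjacency <- function(nEntities, triples) {
  adj <- vector("list", nEntities)
  empty <- matrix(integer(0), 0L, 3L,
                  dimnames = list(NULL, c("rel", "nbr", "dir")))
  for (i in seq_len(nEntities)) adj[[i]] <- empty
  if (nrow(triples) == 0L) return(adj)
  # forward rows (entity is head) and reverse rows (entity is tail)
  ent <- c(triples[, 1L], triples[, 3L])
  rel <- c(triples[, 2L], triples[, 2L])
  nbr <- c(triples[, 3L], triples[, 1L])
  dir <- rep(c(1L, 2L), each = nrow(triples))
  ord <- order(ent, dir, rel, nbr)
  ent <- ent[ord]; rel <- rel[ord]; nbr <- nbr[ord]; dir <- dir[ord]
  idx <- split(seq_along(ent), factor(ent, levels = seq_len(nEntities)))
  for (i in seq_len(nEntities)) {
    j <- idx[[i]]
    if (length(j))
      adj[[i]] <- matrix(c(rel[j], nbr[j], dir[j]), ncol = 3L,
                         dimnames = list(NULL, c("rel", "nbr", "dir")))
  }
  adj
}

#' Construct a KnowledgeGraph from vocabularies and index triples
#'
#' Exact duplicate triples are collapsed silently (set semantics of the triple
#' store); the number collapsed is logged at INFO level when
#' `options(PlantKGR.verbose = TRUE)`.
#'
#' @param entities character vector of unique entity labels.
#' @param relations character vector of unique relation labels.
#' @param triples integer matrix (`n x 3`) of 1-based `(head, relation, tail)`
#'   rows; may have zero rows.
#' @return A [KnowledgeGraph-class] object.
#' @export
knowledgeGraph <- function(entities, relations, triples) {
  triples <- matrix(as.integer(triples), ncol = 3L,
                    dimnames = list(NULL, c("head", "relation", "tail")))
  dup <- duplicated(triples)
  if (any(dup)) {
    logInfo("collapsed ", sum(dup), " duplicate triple(s)")
    triples <- triples[!dup, , drop = FALSE]
  }
  new("KnowledgeGraph",
      entities = as.character(entities),
      relations = as.character(relations),
      triples = triples,
      adjacency = buildAdjacency(length(entities), triples))
}

setMethod("show", "KnowledgeGraph", function(object) {
  cat("KnowledgeGraph with", length(object@entities), "entities,",
      length(object@relations), "relations,",
      nrow(object@triples), "triples\n")
  if (length(object@relations))
    cat("  relations:",
        paste(utils::head(object@relations, 6L), collapse = ", "),
        if (length(object@relations) > 6L) "..." else "", "\n")
})

# ---------------------------------------------------------------------------
# InductiveSplit
# ---------------------------------------------------------------------------

#' Inductive train/test benchmark split
#'
#' Couples an entity-disjoint pair of graphs with the held-out query triples
#' used for training, validation (checkpoint selection) and testing.  The
#' test graph contains only entities never seen in the training graph, so any
#' model evaluated on it must reason inductively.  Query triples are never
#' edges of their side's message-passing graph.
#'
#' @slot train_graph,test_graph [KnowledgeGraph-class] objects with disjoint
#'   entity label sets and a shared relation vocabulary.
#' @slot train_queries,valid_queries integer triple matrices over the train
#'   graph's vocabulary.
#' @slot test_queries integer triple matrix over the test graph's vocabulary.
#' @export
setClass("InductiveSplit",
  representation(
    train_graph   = "KnowledgeGraph",
    test_graph    = "KnowledgeGraph",
    train_queries = "matrix",
    valid_queries = "matrix",
    test_queries  = "matrix"
  )
)

setValidity("InductiveSplit", function(object) {
  msgs <- character()
  trG <- object@train_graph; teG <- object@test_graph
  if (length(intersect(trG@entities, teG@entities)))
    msgs <- c(msgs, "train and test entity label sets must be disjoint")
  if (!identical(trG@relations, teG@relations))
    msgs <- c(msgs, "train and test graphs must share the relation vocabulary")
  checkQ <- function(q, g, name) {
    if (nrow(q) == 0L) return(character())
    out <- character()
    if (any(q[, c(1L, 3L)] > length(g@entities)) || any(q[, c(1L, 3L)] < 1L))
      out <- c(out, paste0(name, ": entity index outside the side's vocab"))
    if (any(q[, 2L] > length(g@relations)) || any(q[, 2L] < 1L))
      out <- c(out, paste0(name, ": relation index outside the vocab"))
    out
  }
  msgs <- c(msgs,
            checkQ(object@train_queries, trG, "train_queries"),
            checkQ(object@valid_queries, trG, "valid_queries"),
            checkQ(object@test_queries, teG, "test_queries"))
  if (nrow(object@test_queries) > 0L && nrow(teG@triples) > 0L) {
    key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])
    if (any(key(object@test_queries) %in% key(teG@triples)))
      msgs <- c(msgs, "test queries must not be message edges of the test graph")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "InductiveSplit", function(object) {
  cat("InductiveSplit\n")
  cat("  train graph:", length(object@train_graph@entities), "entities,",
      nrow(object@train_graph@triples), "triples;",
      nrow(object@train_queries), "train /", nrow(object@valid_queries),
      "valid queries\n")
  cat("  test graph: ", length(object@test_graph@entities), "entities,",
      nrow(object@test_graph@triples), "triples;",
      nrow(object@test_queries), "test queries\n")
})

# ---------------------------------------------------------------------------
# Configuration objects
# ---------------------------------------------------------------------------

#' Synthetic plant-KG generator configuration
#'
#' Controls the shape of the generated taxonomy forest (orders, families,
#' genera, species), the ecological association chains appended to it, the
#' held-out compositional target relation, and the noise-edge rate.
#'
#' @slot nGroups number of connected graph components.  Each group holds
#'   `nOrders` order trees bridged by companion-plant edges between
#'   consecutive orders' species.
#' @slot nOrders,nFamiliesPerOrder,nGeneraPerFamily,nSpeciesPerGenus positive
#'   counts defining each group's taxonomy trees (one class-level root per
#'   order, so every species sits 4 hops below a root).
#' @slot nEcoChains number of ecological chains; `ecoChainLength` edges each.
#' @slot ecoChainLength chain length in hops (>= 2).
#' @slot targetRelationHops number of composed hops defining the held-out
#'   target relation (default 4, the long-range regime).
#' @slot noiseEdgeRate fraction of schema edges added as random intra-group
#'   noise edges, relation types drawn from a power law.
#' @slot megaGroupFactor multiplier (>= 1) on the order count of the first
#'   group, making it a dominant group; 1 keeps all groups homogeneous.
#' @slot decoyClasses if `TRUE`, every order tree also carries an unranked
#'   clade leaf attached at family level via an `in_class` edge.  Such
#'   leaves are locally indistinguishable from true class roots (same
#'   single-edge type signature) but are never the composed 4-hop ancestor,
#'   so node-type recognition alone cannot solve the target relation.
#' @slot megaGroupStyle internal wiring of the dominant group: `"deep"`
#'   chains its order trees in series (long reasoning paths), `"dense"`
#'   stars them around the first order (short paths, locally dense).
#' @slot noiseAllocation how noise edges are distributed over groups:
#'   `"uniform"`, `"by-size"` (proportional to the group's node-pair count,
#'   so the dominant group accumulates shortcut edges and becomes locally
#'   dense) or `"inverse-size"` (small groups absorb the shortcuts while the
#'   dominant group keeps its long chains).
#' @slot seed integer RNG seed.
#' @export
setClass("GeneratorConfig",
  representation(
    nGroups = "integer",
    nOrders = "integer", nFamiliesPerOrder = "integer",
    nGeneraPerFamily = "integer", nSpeciesPerGenus = "integer",
    nEcoChains = "integer", ecoChainLength = "integer",
    targetRelationHops = "integer", noiseEdgeRate = "numeric",
    decoyClasses = "logical",
    megaGroupFactor = "numeric", megaGroupStyle = "character",
    noiseAllocation = "character",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  counts <- c(object@nGroups, object@nOrders, object@nFamiliesPerOrder,
              object@nGeneraPerFamily, object@nSpeciesPerGenus)
  if (any(counts < 1L)) msgs <- c(msgs, "all taxonomy counts must be >= 1")
  if (object@nEcoChains < 0L) msgs <- c(msgs, "nEcoChains must be >= 0")
  if (object@nEcoChains > 0L && object@ecoChainLength < 2L)
    msgs <- c(msgs, "ecoChainLength must be >= 2")
  if (object@noiseEdgeRate < 0 || object@noiseEdgeRate > 1)
    msgs <- c(msgs, "noiseEdgeRate must be in [0, 1]")
  if (object@targetRelationHops < 1L || object@targetRelationHops > 4L)
    msgs <- c(msgs, "targetRelationHops must be between 1 and 4")
  if (object@megaGroupFactor < 1)
    msgs <- c(msgs, "megaGroupFactor must be >= 1")
  if (!object@noiseAllocation %in% c("uniform", "by-size", "inverse-size"))
    msgs <- c(msgs, "noiseAllocation must be uniform, by-size or inverse-size")
  if (!object@megaGroupStyle %in% c("deep", "dense"))
    msgs <- c(msgs, "megaGroupStyle must be deep or dense")
  if (length(msgs)) msgs else TRUE
})

#' @rdname GeneratorConfig-class
#' @param nGroups,nOrders,nFamiliesPerOrder,nGeneraPerFamily,nSpeciesPerGenus,nEcoChains,ecoChainLength,targetRelationHops,noiseEdgeRate,decoyClasses,megaGroupFactor,megaGroupStyle,noiseAllocation,seed
#'   see the class slots.
#' @return A `GeneratorConfig`.
#' @export
generatorConfig <- function(nGroups = 9L, nOrders = 5L,
                            nFamiliesPerOrder = 1L,
                            nGeneraPerFamily = 1L, nSpeciesPerGenus = 1L,
                            nEcoChains = 8L, ecoChainLength = 6L,
                            targetRelationHops = 4L, noiseEdgeRate = 0.15,
                            decoyClasses = FALSE,
                            megaGroupFactor = 1, megaGroupStyle = "deep",
                            noiseAllocation = "uniform",
                            seed = 42L) {
  new("GeneratorConfig",
      nGroups = as.integer(nGroups),
      nOrders = as.integer(nOrders),
      nFamiliesPerOrder = as.integer(nFamiliesPerOrder),
      nGeneraPerFamily = as.integer(nGeneraPerFamily),
      nSpeciesPerGenus = as.integer(nSpeciesPerGenus),
      nEcoChains = as.integer(nEcoChains),
      ecoChainLength = as.integer(ecoChainLength),
      targetRelationHops = as.integer(targetRelationHops),
      noiseEdgeRate = as.numeric(noiseEdgeRate),
      decoyClasses = isTRUE(decoyClasses),
      megaGroupFactor = as.numeric(megaGroupFactor),
      megaGroupStyle = megaGroupStyle,
      noiseAllocation = noiseAllocation,
      seed = as.integer(seed))
}

#' Random-walk partitioning configuration
#'
#' Parameters of the random-walk-with-restart sampler used to carve a graph
#' into disjoint subgraphs, and the fraction of subgraphs assigned to the
#' training side.  Defaults follow the standard inductive-benchmark protocol:
#' walk length 50, 10 walks per node, restart probability 0.3, 75% of
#' subgraphs to training.
#'
#' @slot walkLength steps per walk.
#' @slot walksPerNode walks started from each start node.
#' @slot restartProbability per-step probability of teleporting back to the
#'   walk's start node.
#' @slot trainFraction fraction of subgraphs assigned to the training side.
#' @slot seed integer RNG seed.
#' @export
setClass("PartitionConfig",
  representation(
    walkLength = "integer", walksPerNode = "integer",
    restartProbability = "numeric", trainFraction = "numeric",
    seed = "integer"
  )
)

setValidity("PartitionConfig", function(object) {
  msgs <- character()
  if (object@walkLength < 1L) msgs <- c(msgs, "walkLength must be >= 1")
  if (object@walksPerNode < 1L) msgs <- c(msgs, "walksPerNode must be >= 1")
  if (object@restartProbability <= 0 || object@restartProbability > 1)
    msgs <- c(msgs, "restartProbability must be in (0, 1]")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msgs <- c(msgs, "trainFraction must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PartitionConfig-class
#' @param walkLength,walksPerNode,restartProbability,trainFraction,seed see
#'   the class slots.
#' @return A `PartitionConfig`.
#' @export
partitionConfig <- function(walkLength = 50L, walksPerNode = 10L,
                            restartProbability = 0.3, trainFraction = 0.75,
                            seed = 42L) {
  new("PartitionConfig",
      walkLength = as.integer(walkLength),
      walksPerNode = as.integer(walksPerNode),
      restartProbability = as.numeric(restartProbability),
      trainFraction = as.numeric(trainFraction),
      seed = as.integer(seed))
}

#' Model configuration
#'
#' Hyperparameters of the dual-channel network: embedding width `dim`
#' (default 32), `nHeads` linear-attention heads, total depth `nTotalLayers`
#' (1..6) of which the first `nBaseGnnLayers` are local-only base GNN layers,
#' the attention kernel, and the feature-fusion mode.  `ablateGlobal` /
#' `ablateLocal` zero the corresponding fusion coefficient (the ablation
#' mechanism); since the base GNN stage *is* the local channel, local
#' ablation also idles the base layers, leaving a model with no access to
#' graph topology.  `normalizeGlobal` opts into the standard row
#' normalization of linear attention (off by default: the raw kernelized
#' product is used; normalization makes the channel's output scale
#' independent of graph size, which matters when transferring to test
#' graphs of a different size).
#'
#' @slot dim embedding width `d`; must be divisible by `nHeads`.
#' @slot nHeads number of attention heads `k`.
#' @slot nTotalLayers total number of layers `L` (1..6).
#' @slot nBaseGnnLayers number of initial local-only layers (<= `L`; equal to
#'   `L` only in the degenerate all-base configuration).
#' @slot kernel kernel identifier; only `"elu-plus-one"` is defined.
#' @slot normalizeGlobal logical; row-normalize the global channel.
#' @slot fusionMode one of `"attention"`, `"sum"`, `"concat"`.
#' @slot ablateGlobal,ablateLocal logical ablation switches.
#' @slot layerIndependentRelations logical; use per-layer free relation
#'   tables instead of the shared linearly-updated table.
#' @slot seed integer seed for parameter initialization.
#' @export
setClass("ModelConfig",
  representation(
    dim = "integer", nHeads = "integer", nTotalLayers = "integer",
    nBaseGnnLayers = "integer", kernel = "character",
    normalizeGlobal = "logical", fusionMode = "character",
    ablateGlobal = "logical", ablateLocal = "logical",
    layerIndependentRelations = "logical", seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (object@dim < 1L) msgs <- c(msgs, "dim must be >= 1")
  if (object@nHeads < 1L || object@dim %% object@nHeads != 0L)
    msgs <- c(msgs, "dim must be divisible by nHeads")
  if (object@nTotalLayers < 1L || object@nTotalLayers > 6L)
    msgs <- c(msgs, "nTotalLayers must be in 1..6")
  if (object@nBaseGnnLayers < 0L || object@nBaseGnnLayers > object@nTotalLayers)
    msgs <- c(msgs, "nBaseGnnLayers must be in 0..nTotalLayers")
  if (!object@kernel %in% "elu-plus-one")
    msgs <- c(msgs, "kernel must be 'elu-plus-one'")
  if (!object@fusionMode %in% c("attention", "sum", "concat"))
    msgs <- c(msgs, "fusionMode must be attention, sum or concat")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ModelConfig-class
#' @param dim,nHeads,nTotalLayers,nBaseGnnLayers,kernel,normalizeGlobal,fusionMode,ablateGlobal,ablateLocal,layerIndependentRelations,seed
#'   see the class slots.
#' @return A `ModelConfig`.
#' @export
modelConfig <- function(dim = 32L, nHeads = 4L, nTotalLayers = 5L,
                        nBaseGnnLayers = 2L, kernel = "elu-plus-one",
                        normalizeGlobal = FALSE, fusionMode = "attention",
                        ablateGlobal = FALSE, ablateLocal = FALSE,
                        layerIndependentRelations = FALSE, seed = 42L) {
  new("ModelConfig",
      dim = as.integer(dim), nHeads = as.integer(nHeads),
      nTotalLayers = as.integer(nTotalLayers),
      nBaseGnnLayers = as.integer(nBaseGnnLayers),
      kernel = kernel, normalizeGlobal = isTRUE(normalizeGlobal),
      fusionMode = fusionMode, ablateGlobal = isTRUE(ablateGlobal),
      ablateLocal = isTRUE(ablateLocal),
      layerIndependentRelations = isTRUE(layerIndependentRelations),
      seed = as.integer(seed))
}

#' Training configuration
#'
#' Negative-sampling Adam training hyperparameters.  Grids follow the
#' standard protocol: negatives per positive in {32..1024} (default 64),
#' positives per batch in {16, 32, 64} (default 32), learning rate in
#' {1e-2..1e-5} (default 1e-3), L2 weight decay in {1e-4..1e-7} (default
#' 1e-5), 20 epochs.
#'
#' @slot nNegatives negatives sampled per positive triple.
#' @slot batchSize positives per optimizer step.
#' @slot learningRate Adam learning rate.
#' @slot weightDecay L2 regularization coefficient.
#' @slot epochs training epochs (>= 1).
#' @slot seed integer RNG seed for shuffling and negative sampling.
#' @export
setClass("TrainConfig",
  representation(
    nNegatives = "integer", batchSize = "integer", learningRate = "numeric",
    weightDecay = "numeric", epochs = "integer", seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (object@nNegatives < 1L) msgs <- c(msgs, "nNegatives must be >= 1")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@weightDecay < 0) msgs <- c(msgs, "weightDecay must be >= 0")
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TrainConfig-class
#' @param nNegatives,batchSize,learningRate,weightDecay,epochs,seed see the
#'   class slots.
#' @return A `TrainConfig`.
#' @export
trainConfig <- function(nNegatives = 64L, batchSize = 32L,
                        learningRate = 1e-3, weightDecay = 1e-5,
                        epochs = 20L, seed = 42L) {
  new("TrainConfig",
      nNegatives = as.integer(nNegatives), batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay),
      epochs = as.integer(epochs), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# EvalReport
# ---------------------------------------------------------------------------

#' Evaluation report
#'
#' Hits@10 and AUC-PR together with the protocol metadata needed to
#' reproduce them: the number of queries, the candidate-set size per query
#' (true tail plus filtered negatives), the RNG seed, and how the AUC-PR
#' scores were pooled.
#'
#' @slot hitsAt10,aucPR metrics in `[0, 1]`.
#' @slot nQueries number of test queries ranked.
#' @slot nCandidatesPerQuery candidate-set size (truth + negatives).
#' @slot seed RNG seed of the evaluation run.
#' @slot pooling AUC-PR pooling scheme (`"pooled"`: scores pooled across
#'   queries with one sampled negative per positive).
#' @export
setClass("EvalReport",
  representation(
    hitsAt10 = "numeric", aucPR = "numeric", nQueries = "integer",
    nCandidatesPerQuery = "integer", seed = "integer", pooling = "character"
  )
)

setValidity("EvalReport", function(object) {
  msgs <- character()
  if (object@hitsAt10 < 0 || object@hitsAt10 > 1)
    msgs <- c(msgs, "hitsAt10 must be in [0, 1]")
  if (object@aucPR < 0 || object@aucPR > 1)
    msgs <- c(msgs, "aucPR must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: Hits@10 = %.4f, AUC-PR = %.4f\n",
              object@hitsAt10, object@aucPR))
  cat(sprintf("  %d queries, %d candidates/query, seed %d, AUC-PR %s\n",
              object@nQueries, object@nCandidatesPerQuery, object@seed,
              object@pooling))
})
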