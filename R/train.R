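#' @include model-ops.R synthetic-kg.R
NULL

# Truth index: set of "head|rel" -> known-true tails, used for filtered
# negative sampling (a corrupted tail must not form any known-true triple).
buildTruthIndex <- function(...) {
  tr <- do.call(rbind, list(...))
  if (is.null(tr) || nrow(tr) == 0L) return(list())
  key <- paste(tr[, 1L], tr[, 2L], sep = "|")
  lapply(split(tr[, 3L], key), unique)
}

#' Sample filtered negative tails for a positive triple
#'
#' Corrupts the tail of `positive` by uniform draws over the entity set,
#' rejecting the true tail and any tail that forms a known-true triple
#' (graph edges plus any extra triples in `truth`).  Reproducible from
#' `seed`.
#'
#' @param positive integer triple `(head, relation, tail)`.
#' @param graph a [KnowledgeGraph-class] (supplies the entity set and the
#'   edge truth set).
#' @param n number of negatives.
#' @param seed RNG seed.
#' @param truth optional extra triple matrix of known-true triples (e.g.
#'   held-out queries) to filter against.
#' @return Integer `n x 3` matrix of negative triples `(h, r, t')`.
#' @export
sampleNegatives <- function(positive, graph, n, seed = 42L, truth = NULL) {
  stopifnot(is(graph, "KnowledgeGraph"))
  nE <- length(graph@entities)
  if (nE < 2L) stopData("need at least 2 entities to sample negatives")
  h <- as.integer(positive[[1]]); r <- as.integer(positive[[2]])
  t <- as.integer(positive[[3]])
  idx <- buildTruthIndex(graph@triples, truth)
  banned <- unique(c(t, idx[[paste(h, r, sep = "|")]]))
  if (length(banned) >= nE)
    stopData("degenerate graph: every tail forms a true triple for (",
             h, ", ", r, ")")
  tails <- withSeed(seed, {
    out <- integer(0)
    while (length(out) < n) {
      cand <- sample.int(nE, n - length(out), replace = TRUE)
      out <- c(out, cand[!(cand %in% banned)])
    }
    out[seq_len(n)]
  })
  cbind(head = rep(h, n), relation = rep(r, n), tail = tails)
}

#' Negative-sampling ranking loss
#'
#' \eqn{-\log p^+ - \frac{1}{n}\sum_i \log(1 - p^-_i)}: binary cross
#' entropy pushing the positive triple's probability toward 1 and each
#' negative's toward 0, with the negative term averaged.  Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` to keep the logarithms finite.
#'
#' @param pPos probability of the positive triple.
#' @param pNegs vector of negative-triple probabilities (nonempty).
#' @return Non-negative scalar loss.
#' @examples
#' rankingLoss(0.5, 0.5)  # 2 * log(2)
#' @export
rankingLoss <- function(pPos, pNegs) {
  if (length(pNegs) == 0L) stopUsage("rankingLoss needs at least one negative")
  eps <- 1e-7
  pPos <- min(max(pPos, eps), 1 - eps)
  pNegs <- pmin(pmax(pNegs, eps), 1 - eps)
  -log(pPos) - mean(log(1 - pNegs))
}

# ---------------------------------------------------------------------------
# Training loop
# ---------------------------------------------------------------------------

adamInit <- function(nPar) {
  list(m = numeric(nPar), v = numeric(nPar), t = 0L)
}

adamStep <- function(par, grad, state, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  grad <- grad + weightDecay * par   # classic L2-in-gradient coupling
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the dual-channel model on an inductive split
#'
#' Per epoch, the train-side positive queries are shuffled and processed in
#' batches: for each positive, one query-conditioned forward pass over the
#' training graph scores the positive tail and `nNegatives` filtered
#' corrupted tails, the negative-sampling loss is accumulated, and Adam
#' (with L2 weight decay) steps once per batch on the averaged gradient.
#' After every epoch the validation queries are ranked (50-candidate
#' protocol) and the parameters with the best validation Hits@10 are kept
#' as the returned checkpoint.  Fully deterministic for a fixed seed
#' (single-threaded engine, seeded sampling).
#'
#' @param split an [InductiveSplit-class].
#' @param modelCfg a [ModelConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @return List with `params` (best-validation `ModelParams`), `history`
#'   (data.frame `epoch, loss, val_hits10`), `finalParams`, and `bestEpoch`.
#' @export
trainModel <- function(split, modelCfg, trainCfg) {
  stopifnot(is(split, "InductiveSplit"), is(modelCfg, "ModelConfig"),
            is(trainCfg, "TrainConfig"))
  validObject(modelCfg); validObject(trainCfg)
  graph <- split@train_graph
  queries <- split@train_queries
  if (nrow(queries) == 0L) stopData("split has no training queries")
  params <- initParams(modelCfg, numRelations(graph))
  ecfg <- engineConfig(modelCfg, params$nRelations)
  ed <- messageEdges(graph)
  dst0 <- ed$dst - 1L; rel0 <- ed$rel - 1L; src0 <- ed$src - 1L
  nE <- numEntities(graph)
  truth <- rbind(queries, split@valid_queries)

  state <- adamInit(length(params$par))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_hits10 = numeric(0))
  best <- list(hits = -Inf, par = params$par, epoch = 0L)

  for (epoch in seq_len(trainCfg@epochs)) {
    ord <- withSeed(deriveSeed(trainCfg@seed, "shuffle", epoch),
                    sample.int(nrow(queries)))
    losses <- numeric(0)
    batches <- split(ord, ceiling(seq_along(ord) / trainCfg@batchSize))
    for (bi in seq_along(batches)) {
      gacc <- numeric(length(params$par))
      bloss <- 0
      for (qi in batches[[bi]]) {
        pos <- queries[qi, ]
        negs <- sampleNegatives(pos, graph, trainCfg@nNegatives,
                                seed = deriveSeed(trainCfg@seed, "neg",
                                                  epoch, qi),
                                truth = truth)
        res <- tryCatch(
          engine_step(dst0, rel0, src0, nE, params$par, ecfg,
                      pos[[1]] - 1L, pos[[2]] - 1L, pos[[3]] - 1L,
                      as.integer(negs[, 3L]) - 1L),
          error = function(e)
            stopNumeric("training aborted at epoch ", epoch, ", batch ", bi,
                        ": ", conditionMessage(e)))
        if (!is.finite(res$loss))
          stopNumeric("non-finite loss at epoch ", epoch, ", batch ", bi)
        gacc <- gacc + res$grad
        bloss <- bloss + res$loss
      }
      nb <- length(batches[[bi]])
      upd <- adamStep(params$par, gacc / nb, state,
                      trainCfg@learningRate, trainCfg@weightDecay)
      params$par <- upd$par
      state <- upd$state
      losses <- c(losses, bloss / nb)
    }
    valHits <- if (nrow(split@valid_queries) > 0L) {
      rep <- evaluateModel(split, params, nCandidates = 50L,
                           seed = deriveSeed(trainCfg@seed, "val", epoch),
                           side = "valid")
      rep@hitsAt10
    } else NA_real_
    meanLoss <- mean(losses)
    history <- rbind(history, data.frame(epoch = epoch, loss = meanLoss,
                                         val_hits10 = valHits))
    logInfo(sprintf("epoch %d: loss %.4f, val Hits@10 %.3f",
                    epoch, meanLoss, valHits))
    # ties go to the later epoch (the lower-loss checkpoint)
    if (!is.na(valHits) && valHits >= best$hits) {
      best <- list(hits = valHits, par = params$par, epoch = epoch)
    }
  }
  bestParams <- params
  if (is.finite(best$hits)) bestParams$par <- best$par
  list(params = bestParams, history = history, finalParams = params,
       bestEpoch = best$epoch)
}
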