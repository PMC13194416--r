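#' @include train.R
NULL

#' Rank of the true tail among scored candidates
#'
#' Pessimistic tie policy: the rank is 1 plus the number of candidates
#' scoring strictly higher than the true tail plus the number of other
#' candidates tied with it.  A constant scorer therefore ranks the truth
#' last.
#'
#' @param trueTail entity index of the true tail.
#' @param candidateTails integer vector of candidate tail indices (must
#'   contain `trueTail`).
#' @param scores numeric scores aligned with `candidateTails`.
#' @return Integer rank (1-based).
#' @export
rankTail <- function(trueTail, candidateTails, scores) {
  if (length(candidateTails) != length(scores))
    stopUsage("candidateTails and scores must align")
  pos <- match(trueTail, candidateTails)
  if (is.na(pos)) stopUsage("true tail is missing from the candidate set")
  s <- scores[pos]
  others <- scores[-pos]
  1L + sum(others > s) + sum(others == s)
}

#' Fraction of ranks at or below a cutoff
#'
#' @param ranks integer vector of ranks (all >= 1, nonempty).
#' @param k cutoff (default 10).
#' @return Fraction in `[0, 1]`.
#' @export
hitsAtK <- function(ranks, k = 10L) {
  if (length(ranks) == 0L) stopUsage("hitsAtK needs at least one rank")
  if (any(ranks < 1L)) stopUsage("ranks must be >= 1")
  mean(ranks <= k)
}

#' Area under the precision-recall curve (average precision)
#'
#' Scores are sorted in decreasing order with ties grouped: precision is
#' evaluated only at tie-group boundaries, and each group contributes its
#' recall increment times the boundary precision.  Under total ties this
#' reduces to the positive prevalence.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels aligned with `scores`; both classes must occur.
#' @return Average precision in `(0, 1]`.
#' @export
aucPR <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopUsage("scores and labels must align")
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  if (nPos == 0L || nPos == length(labels))
    stopUsage("AUC-PR is undefined for single-class labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  bounds <- cumsum(rle(s)$lengths)   # tie-group boundaries
  tp <- cumsum(y)[bounds]
  n <- bounds
  prec <- tp / n
  dtp <- diff(c(0L, tp))
  sum(dtp * prec) / nPos
}

#' Rank-based evaluation of a trained model on an inductive split
#'
#' For every query on the chosen side, `nCandidates - 1` filtered negative
#' tails are sampled (uniform over the side's entities, excluding any
#' known-true tail) and pooled with the true tail; one query-conditioned
#' forward pass scores all candidates, and the true tail's pessimistic rank
#' enters Hits@10.  AUC-PR is computed over scores pooled across queries:
#' each positive contributes its score with label 1 and its first sampled
#' negative's score with label 0 (1:1 class balance).
#'
#' @param split an [InductiveSplit-class].
#' @param params a `ModelParams` checkpoint (or the list returned by
#'   [trainModel()], whose `$params` is then used).
#' @param nCandidates candidate-set size per query (default 50: truth plus
#'   49 negatives).
#' @param seed RNG seed for negative sampling.
#' @param side `"test"` (default) or `"valid"`.
#' @param oracle if `TRUE`, bypass the model and score the true tail 1 and
#'   all negatives 0 (protocol self-check).
#' @return An [EvalReport-class].
#' @export
evaluateModel <- function(split, params, nCandidates = 50L, seed = 42L,
                          side = c("test", "valid"), oracle = FALSE) {
  side <- match.arg(side)
  stopifnot(is(split, "InductiveSplit"))
  if (!inherits(params, "ModelParams") && is.list(params) &&
      inherits(params$params, "ModelParams")) {
    params <- params$params
  }
  graph <- if (side == "test") split@test_graph else split@train_graph
  queries <- if (side == "test") split@test_queries else split@valid_queries
  if (nrow(queries) == 0L) stopData("no queries on the ", side, " side")
  if (!oracle) stopifnot(inherits(params, "ModelParams"))

  ed <- messageEdges(graph)
  dst0 <- ed$dst - 1L; rel0 <- ed$rel - 1L; src0 <- ed$src - 1L
  nE <- numEntities(graph)
  truthAll <- switch(side,
    test = split@test_queries,
    valid = rbind(split@train_queries, split@valid_queries))
  if (!oracle) ecfg <- engineConfig(params$config, params$nRelations)

  ranks <- integer(nrow(queries))
  posScores <- numeric(nrow(queries))
  negScores <- numeric(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    negs <- sampleNegatives(q, graph, nCandidates - 1L,
                            seed = deriveSeed(seed, "eval", side, i),
                            truth = truthAll)
    cands <- c(q[[3]], negs[, 3L])
    scores <- if (oracle) {
      c(1, numeric(nCandidates - 1L))
    } else {
      as.numeric(engine_score_tails(dst0, rel0, src0, nE, params$par, ecfg,
                                    q[[1]] - 1L, q[[2]] - 1L,
                                    as.integer(cands) - 1L))
    }
    ranks[i] <- rankTail(q[[3]], cands, scores)
    posScores[i] <- scores[1L]
    negScores[i] <- scores[2L]
  }
  rep <- new("EvalReport",
             hitsAt10 = hitsAtK(ranks, 10L),
             aucPR = aucPR(c(posScores, negScores),
                           c(rep(1L, length(posScores)),
                             rep(0L, length(negScores)))),
             nQueries = nrow(queries),
             nCandidatesPerQuery = as.integer(nCandidates),
             seed = as.integer(seed),
             pooling = "pooled")
  validObject(rep)
  rep
}
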