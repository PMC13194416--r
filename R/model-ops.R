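#' @include params.R kg-core.R
NULL

#' Positive attention kernel
#'
#' The elementwise feature map \eqn{\phi(x) = ELU(x) + 1} that replaces
#' softmax in linear attention; strictly positive for all finite inputs
#' (\eqn{x + 1} for \eqn{x > 0}, \eqn{e^x} otherwise).
#'
#' @param x numeric vector or matrix.
#' @return Object of the same shape with `kernelPhi(x) > 0` elementwise.
#' @examples
#' kernelPhi(0)  # 1
#' kernelPhi(2)  # 3
#' @export
kernelPhi <- function(x) {
  out <- x
  neg <- x <= 0
  out[neg] <- exp(x[neg])
  out[!neg] <- x[!neg] + 1
  out
}

kernelPhiGrad <- function(x) {
  out <- x
  neg <- x <= 0
  out[neg] <- exp(x[neg])
  out[!neg] <- 1
  out
}

#' Single linear-attention head
#'
#' Computes the kernelized attention output in the linear association order
#' \eqn{\phi(Q)\,(\phi(K)^\top V)}: the \eqn{d_h \times d_h} key-value
#' summary is formed first, so the cost is linear in the number of entities
#' while the result is exactly equal to the quadratic-order computation
#' \eqn{(\phi(Q)\phi(K)^\top)V}.  With `normalize = TRUE`, row `i` is
#' divided by \eqn{\phi(Q)_i \cdot (\phi(K)^\top \mathbf{1})} (the standard
#' linear-attention denominator, opt-in).
#'
#' @param E node-state matrix (`|E| x d`).
#' @param Wq,Wk,Wv projection matrices (`d x dh`).
#' @param normalize logical row-normalization switch.
#' @return Matrix `|E| x dh`.
#' @export
globalHead <- function(E, Wq, Wk, Wv, normalize = FALSE) {
  P <- kernelPhi(E %*% Wq)
  S <- kernelPhi(E %*% Wk)
  V <- E %*% Wv
  U <- P %*% (t(S) %*% V)
  if (!all(is.finite(U)))
    stopNumeric("non-finite values in the global attention head")
  if (normalize) {
    z <- pmax(as.vector(P %*% colSums(S)), 1e-12)
    U <- U / z
  }
  U
}

#' Multi-head global information module
#'
#' Splits the layer's query/key/value projections into `nHeads` column
#' blocks, runs [globalHead()] per head, concatenates the head outputs back
#' to width `d`, and applies the post-concatenation projection `Wm`.
#'
#' @param E node-state matrix (`|E| x d`).
#' @param lp layer parameter list (as from [layerParams()]): uses `Wq`,
#'   `Wk`, `Wv`, `Wm`.
#' @param nHeads number of attention heads (must divide `d`).
#' @param normalize per-head row normalization.
#' @return Matrix `|E| x d` of globally informed node states.
#' @export
globalModule <- function(E, lp, nHeads, normalize = FALSE) {
  d <- ncol(E)
  if (d %% nHeads != 0L)
    stopUsage("embedding width ", d, " not divisible by ", nHeads, " heads")
  dh <- d %/% nHeads
  out <- matrix(0, nrow(E), d)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    out[, cols] <- globalHead(E, lp$Wq[, cols, drop = FALSE],
                              lp$Wk[, cols, drop = FALSE],
                              lp$Wv[, cols, drop = FALSE],
                              normalize = normalize)
  }
  out %*% lp$Wm
}

# Instrumented variant: same computation, plus the exact count of
# multiply-accumulate operations performed by each matrix product on the
# linear-attention path.  Used to assert the linear cost contract.
globalModuleOps <- function(E, lp, nHeads, normalize = FALSE) {
  n <- nrow(E); d <- ncol(E); dh <- d %/% nHeads
  macs <- 0
  mm <- function(A, B) {
    macs <<- macs + nrow(A) * ncol(A) * ncol(B)
    A %*% B
  }
  out <- matrix(0, n, d)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    P <- kernelPhi(mm(E, lp$Wq[, cols, drop = FALSE]))
    S <- kernelPhi(mm(E, lp$Wk[, cols, drop = FALSE]))
    V <- mm(E, lp$Wv[, cols, drop = FALSE])
    U <- mm(P, mm(t(S), V))
    if (normalize) {
      z <- pmax(as.vector(mm(P, matrix(colSums(S)))), 1e-12)
      U <- U / z
    }
    out[, cols] <- U
  }
  out <- mm(out, lp$Wm)
  list(output = out, macs = macs)
}

#' Relational message function
#'
#' The concrete message form \eqn{W_\phi (e_v + r)}: the neighbor state and
#' the relation embedding are composed additively, then linearly
#' transformed.  The receiving node `u` enters only through the attention
#' weight, not the message content.
#'
#' @param u,r,v receiving-entity, relation and source-entity indices.
#' @param E node-state matrix.
#' @param R relation-state matrix (inverse-augmented).
#' @param Wphi message transform (`d x d`).
#' @return Numeric `d`-vector.
#' @export
messageFun <- function(u, r, v, E, R, Wphi) {
  as.vector((E[v, ] + R[r, ]) %*% Wphi)
}

#' Local attentive message-passing module
#'
#' For each node `u` with a nonempty inverse-augmented neighborhood
#' \eqn{N(u)}: messages \eqn{m = W_\phi(e_v + r)} are formed for every
#' incident edge, attention logits
#' \eqn{\gamma = LeakyReLU(W_{att} m)} are softmax-normalized over
#' \eqn{N(u)} into weights \eqn{\beta}, and the new state is
#' \eqn{\sum \beta m}.  Isolated nodes receive a zero row.
#'
#' @param E node-state matrix (`|E| x d`).
#' @param R relation-state matrix (`2|R| x d`).
#' @param graph a [KnowledgeGraph-class] (supplies the message edges).
#' @param lp layer parameter list: uses `Wphi` (`d x d`) and `a`
#'   (the `1 x d` attention row, stored as a vector).
#' @param returnWeights attach the per-edge attention weights and their
#'   destinations as attributes `beta` / `dst`.
#' @return Matrix `|E| x d` of locally aggregated node states.
#' @export
localModule <- function(E, R, graph, lp, returnWeights = FALSE) {
  ed <- messageEdges(graph)
  n <- nrow(E); d <- ncol(E)
  out <- matrix(0, n, d)
  if (length(ed$dst) == 0L) return(out)
  M <- (E[ed$src, , drop = FALSE] + R[ed$rel, , drop = FALSE]) %*% lp$Wphi
  gam <- leakyRelu(as.vector(M %*% lp$a))
  grp <- factor(ed$dst, levels = sort(unique(ed$dst)))
  gmax <- as.vector(tapply(gam, grp, max))
  ex <- exp(gam - gmax[as.integer(grp)])
  den <- as.vector(tapply(ex, grp, sum))
  beta <- ex / den[as.integer(grp)]
  agg <- rowsum(beta * M, group = ed$dst)
  out[as.integer(rownames(agg)), ] <- agg
  if (returnWeights) {
    attr(out, "beta") <- beta
    attr(out, "dst") <- ed$dst
  }
  out
}

#' Adaptive fusion of self, global and local features
#'
#' In `"attention"` mode each node scores its three feature branches with
#' the fusion vector `w` through a LeakyReLU-exp softmax,
#' \eqn{\alpha_i \propto \exp(LeakyReLU(w^\top e_i))}, and returns the
#' convex combination \eqn{\alpha_1 e_{self} + \alpha_2 e_{glob} +
#' \alpha_3 e_{loc}}.  `"sum"` adds the active branches unweighted;
#' `"concat"` concatenates them to width `3d` and applies the learned
#' projection `Wc`.  Ablation flags force the corresponding coefficient to
#' zero before renormalization (the branch is removed from the fusion).
#'
#' @param eSelf,eGlobal,eLocal branch features: `d`-vectors or
#'   row-aligned `n x d` matrices.
#' @param w fusion attention `d`-vector (ignored outside attention mode).
#' @param mode `"attention"`, `"sum"` or `"concat"`.
#' @param ablateGlobal,ablateLocal drop the corresponding branch.
#' @param Wc `3d x d` projection for concat mode.
#' @param returnWeights attach the fusion coefficients as attribute
#'   `alpha` (attention mode only).
#' @return Fused features, same shape as the inputs.
#' @export
fuseFeatures <- function(eSelf, eGlobal, eLocal, w,
                         mode = c("attention", "sum", "concat"),
                         ablateGlobal = FALSE, ablateLocal = FALSE,
                         Wc = NULL, returnWeights = FALSE) {
  mode <- match.arg(mode)
  vec <- is.null(dim(eSelf))
  toM <- function(x) if (is.null(dim(x))) matrix(x, 1L) else x
  Es <- toM(eSelf); Eg <- toM(eGlobal); El <- toM(eLocal)
  if (ablateGlobal) Eg[] <- 0
  if (ablateLocal) El[] <- 0
  out <- switch(mode,
    attention = {
      s1 <- leakyRelu(as.vector(Es %*% w))
      s2 <- leakyRelu(as.vector(Eg %*% w))
      s3 <- leakyRelu(as.vector(El %*% w))
      S <- cbind(s1, s2, s3)
      active <- c(TRUE, !ablateGlobal, !ablateLocal)
      S <- S[, active, drop = FALSE]
      mx <- apply(S, 1L, max)
      F <- exp(S - mx)
      A <- F / rowSums(F)
      alpha <- matrix(0, nrow(Es), 3L)
      alpha[, active] <- A
      res <- alpha[, 1L] * Es + alpha[, 2L] * Eg + alpha[, 3L] * El
      if (returnWeights) attr(res, "alpha") <- alpha
      res
    },
    sum = Es + Eg + El,
    concat = {
      if (is.null(Wc)) stopUsage("concat fusion requires the Wc projection")
      cbind(Es, Eg, El) %*% Wc
    })
  if (vec) {
    a <- attr(out, "alpha")
    out <- as.vector(out)
    if (!is.null(a)) attr(out, "alpha") <- a
  }
  out
}

#' Per-layer relation-state update
#'
#' Default: the shared relation table is updated linearly,
#' \eqn{R^{(l+1)} = R^{(l)} W_{rel}}.  With `layerIndependent = TRUE` the
#' layer's own free relation table replaces the states instead.
#'
#' @param R current relation-state matrix.
#' @param Wrel `d x d` update matrix (shared-table mode).
#' @param relTab free per-layer relation table (layer-independent mode).
#' @param layerIndependent switch between the two schemes.
#' @return Updated relation-state matrix.
#' @export
relationUpdate <- function(R, Wrel = NULL, relTab = NULL,
                           layerIndependent = FALSE) {
  if (layerIndependent) {
    if (is.null(relTab)) stopUsage("layer-independent update needs relTab")
    relTab
  } else {
    if (is.null(Wrel)) stopUsage("shared-table update needs Wrel")
    R %*% Wrel
  }
}

#' Query-conditioned initial node states
#'
#' The head entity's row is set to the query relation's embedding; all
#' other rows are zero.  No per-entity parameters exist, which is what
#' makes the network inductive: states depend on the query and the graph
#' structure only, never on entity identity.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param query integer pair `(head index, relation index)`.
#' @param relStates relation-state matrix whose row `query[2]` seeds the
#'   head entity.
#' @return Matrix `|E| x d` with exactly one (possibly zero) nonzero row.
#' @export
initNodeStates <- function(graph, query, relStates) {
  n <- length(graph@entities)
  h <- as.integer(query[[1]]); q <- as.integer(query[[2]])
  if (is.na(h) || h < 1L || h > n)
    stopData("query head index out of range: ", h)
  if (is.na(q) || q < 1L || q > nrow(relStates))
    stopData("query relation index out of range: ", q)
  E <- matrix(0, n, ncol(relStates))
  E[h, ] <- relStates[q, ]
  E
}

#' Score a candidate triple
#'
#' Concatenates the head state, query-relation state and tail state and
#' passes them through the two-layer perceptron (hidden width 64, ReLU,
#' sigmoid output), yielding a probability in (0, 1).
#'
#' @param eH head-entity `d`-vector.
#' @param rQ query-relation `d`-vector.
#' @param eT tail-entity `d`-vector, or an `n x d` matrix of candidate
#'   tails scored against the same head and relation.
#' @param scorer scorer parameter list (as from [scorerParams()]).
#' @return Probability scalar, or vector of length `n`.
#' @export
scoreTriple <- function(eH, rQ, eT, scorer) {
  Et <- if (is.null(dim(eT))) matrix(eT, 1L) else eT
  n <- nrow(Et)
  X <- cbind(matrix(eH, n, length(eH), byrow = TRUE),
             matrix(rQ, n, length(rQ), byrow = TRUE), Et)
  H <- pmax(sweep(X %*% scorer$W1, 2L, scorer$b1, "+"), 0)
  z <- as.vector(H %*% scorer$w2) + scorer$b2
  p <- 1 / (1 + exp(-z))
  if (is.null(dim(eT))) p[[1]] else p
}

engineConfig <- function(config, nRelations) {
  list(d = config@dim, k = config@nHeads, L = config@nTotalLayers,
       n_base = config@nBaseGnnLayers,
       normalize = config@normalizeGlobal,
       fusion = match(config@fusionMode, c("attention", "sum", "concat")) - 1L,
       ablate_global = config@ablateGlobal,
       ablate_local = config@ablateLocal,
       layer_independent = config@layerIndependentRelations,
       m_aug = 2L * as.integer(nRelations),
       slope = 0.01)
}

#' Full forward pass of the dual-channel network
#'
#' Runs the query-conditioned initialization, `nBaseGnnLayers` local-only
#' base GNN layers, then the remaining full layers (global linear attention
#' and local message passing in parallel, fused per node), with the
#' relation-state update applied between consecutive layers.  Backed by the
#' compiled engine; composing the exported per-layer operations in R yields
#' the same states.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param query integer pair `(head index, relation index)`.
#' @param params a `ModelParams` object (see [initParams()]).
#' @return List with `nodes` (`|E| x d` final node states) and `relations`
#'   (`2|R| x d` final relation states, the table consumed by the scorer).
#' @export
forwardPass <- function(graph, query, params) {
  stopifnot(is(graph, "KnowledgeGraph"), inherits(params, "ModelParams"))
  if (2L * numRelations(graph) != 2L * params$nRelations)
    stopData("model was initialized for ", params$nRelations,
             " relations but the graph has ", numRelations(graph))
  ed <- messageEdges(graph)
  h <- as.integer(query[[1]]); q <- as.integer(query[[2]])
  if (h < 1L || h > numEntities(graph))
    stopData("query head index out of range: ", h)
  res <- engine_forward(ed$dst - 1L, ed$rel - 1L, ed$src - 1L,
                        numEntities(graph), params$par,
                        engineConfig(params$config, params$nRelations),
                        h - 1L, q - 1L)
  list(nodes = res$nodes, relations = res$relations)
}
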