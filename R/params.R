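#' @include AllClasses.R
NULL

# Parameter storage: all learnable tensors live in one flat numeric vector
# (column-major blocks), described by a layout computed deterministically
# from the model configuration and the relation-vocabulary size.  The flat
# form keeps the Adam update a single vectorized expression and lets the
# compiled engine map blocks without copying.
#
# Block order (must match src/engine.cpp exactly):
#   rel0 (2|R| x d)
#   per layer l = 1..L:
#     Wq, Wk, Wv, Wm, Wphi (d x d), a (d), w (d),
#     relTab (2|R| x d) if layer-independent relations else Wrel (d x d),
#     Wc (3d x d) if fusionMode == "concat"
#   scorer: W1 (3d x 64), b1 (64), w2 (64), b2 (1)

SCORER_HIDDEN <- 64L

buildParamLayout <- function(config, nRelations) {
  d <- config@dim
  mAug <- 2L * as.integer(nRelations)
  entries <- list()
  off <- 0L
  add <- function(name, nr, nc) {
    entries[[name]] <<- list(offset = off + 1L, nrow = as.integer(nr),
                             ncol = as.integer(nc))
    off <<- off + as.integer(nr) * as.integer(nc)
  }
  add("rel0", mAug, d)
  for (l in seq_len(config@nTotalLayers)) {
    p <- function(x) sprintf("L%d.%s", l, x)
    add(p("Wq"), d, d); add(p("Wk"), d, d); add(p("Wv"), d, d)
    add(p("Wm"), d, d); add(p("Wphi"), d, d)
    add(p("a"), d, 1L); add(p("w"), d, 1L)
    if (config@layerIndependentRelations) add(p("relTab"), mAug, d)
    else add(p("Wrel"), d, d)
    if (config@fusionMode == "concat") add(p("Wc"), 3L * d, d)
  }
  add("scorer.W1", 3L * d, SCORER_HIDDEN)
  add("scorer.b1", SCORER_HIDDEN, 1L)
  add("scorer.w2", SCORER_HIDDEN, 1L)
  add("scorer.b2", 1L, 1L)
  structure(entries, total = off)
}

getParam <- function(par, layout, name) {
  e <- layout[[name]]
  if (is.null(e)) stop("unknown parameter block: ", name)
  matrix(par[e$offset:(e$offset + e$nrow * e$ncol - 1L)], e$nrow, e$ncol)
}

setParam <- function(par, layout, name, value) {
  e <- layout[[name]]
  if (is.null(e)) stop("unknown parameter block: ", name)
  stopifnot(length(value) == e$nrow * e$ncol)
  par[e$offset:(e$offset + e$nrow * e$ncol - 1L)] <- as.numeric(value)
  par
}

#' Initialize model parameters
#'
#' All weight matrices are Xavier-uniform initialized (seeded from the model
#' configuration); scorer biases start at zero.  The relation table is sized
#' for the inverse-augmented vocabulary (`2 |R|` rows).
#'
#' @param config a [ModelConfig-class].
#' @param nRelations number of (non-augmented) relations in the vocabulary.
#' @return A `ModelParams` object: a list with the flat parameter vector
#'   (`par`), its `layout`, the `config` echo and `nRelations`.
#' @export
initParams <- function(config, nRelations) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  layout <- buildParamLayout(config, nRelations)
  par <- numeric(attr(layout, "total"))
  par <- withSeed(config@seed, {
    for (name in names(layout)) {
      e <- layout[[name]]
      n <- e$nrow * e$ncol
      vals <- if (name %in% c("scorer.b1", "scorer.b2")) {
        numeric(n)
      } else {
        b <- sqrt(6 / (e$nrow + e$ncol))
        runif(n, -b, b)
      }
      par[e$offset:(e$offset + n - 1L)] <- vals
    }
    par
  })
  structure(list(par = par, layout = layout, config = config,
                 nRelations = as.integer(nRelations)),
            class = "ModelParams")
}

#' @export
print.ModelParams <- function(x, ...) {
  cat("ModelParams:", length(x$par), "parameters,",
      x$config@nTotalLayers, "layers (",
      x$config@nBaseGnnLayers, "base ), dim", x$config@dim,
      ", heads", x$config@nHeads, "\n")
  invisible(x)
}

#' Learnable tensors of one layer
#'
#' @param params a `ModelParams` object.
#' @param l layer index (1-based).
#' @return Named list with `Wq`, `Wk`, `Wv`, `Wm`, `Wphi`, `a`, `w`, and
#'   either `Wrel` or `relTab`; plus `Wc` in concat fusion mode.
#' @export
layerParams <- function(params, l) {
  stopifnot(inherits(params, "ModelParams"))
  p <- function(x) sprintf("L%d.%s", l, x)
  keys <- c("Wq", "Wk", "Wv", "Wm", "Wphi", "a", "w",
            if (params$config@layerIndependentRelations) "relTab" else "Wrel",
            if (params$config@fusionMode == "concat") "Wc")
  out <- lapply(keys, function(kk) {
    m <- getParam(params$par, params$layout, p(kk))
    if (kk %in% c("a", "w")) as.vector(m) else m
  })
  names(out) <- keys
  out
}

#' Initial (layer-0) relation state table
#'
#' Rows `1..|R|` hold the forward relations, rows `|R|+1..2|R|` the
#' inverse-augmented ones.
#'
#' @param params a `ModelParams` object.
#' @return Numeric matrix `2|R| x d`.
#' @export
relationTable <- function(params) {
  getParam(params$par, params$layout, "rel0")
}

#' Triple-scorer parameters
#'
#' @param params a `ModelParams` object.
#' @return List with `W1` (`3d x 64`), `b1`, `w2`, `b2`.
#' @export
scorerParams <- function(params) {
  list(W1 = getParam(params$par, params$layout, "scorer.W1"),
       b1 = as.vector(getParam(params$par, params$layout, "scorer.b1")),
       w2 = as.vector(getParam(params$par, params$layout, "scorer.w2")),
       b2 = as.vector(getParam(params$par, params$layout, "scorer.b2")))
}

#' Import pre-trained relation embeddings from a text table
#'
#' Accepts lines `label<TAB>v1,...,vd`.  Labels must exist in the relation
#' vocabulary; matching forward rows of the initial relation table are
#' replaced (inverse-augmented rows can be addressed as `label#inv`).
#'
#' @param params a `ModelParams` object.
#' @param path text table path.
#' @param relations character vector: the relation vocabulary the rows of
#'   the table refer to.
#' @return The updated `ModelParams`.
#' @export
importRelationEmbeddings <- function(params, path, relations) {
  stopifnot(inherits(params, "ModelParams"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rel0 <- relationTable(params)
  d <- params$config@dim
  nR <- length(relations)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stopData("malformed embedding line ", i, " in ", path)
    lab <- fields[[1]]
    inv <- endsWith(lab, "#inv")
    if (inv) lab <- sub("#inv$", "", lab)
    j <- match(lab, relations)
    if (is.na(j)) stopData("unknown relation label in embeddings: ", lab)
    v <- as.numeric(strsplit(fields[[2]], ",", fixed = TRUE)[[1]])
    if (length(v) != d || anyNA(v))
      stopData("embedding for ", lab, " must have ", d, " finite values")
    rel0[j + if (inv) nR else 0L, ] <- v
  }
  params$par <- setParam(params$par, params$layout, "rel0", rel0)
  params
}
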