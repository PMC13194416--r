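#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Triple-file I/O
# ---------------------------------------------------------------------------
# Dialect: UTF-8, one `head<TAB>relation<TAB>tail` per line, extra fields
# ignored, "#"-prefixed comment lines and blank lines skipped.

#' Read a knowledge graph from a tab-separated triple file
#'
#' Vocabularies are built in first-appearance order (head before tail within
#' a line); exact duplicate lines collapse to one triple.
#'
#' @param path path to a triple TSV file.
#' @return A [KnowledgeGraph-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tr\tb", "b\tr\tc"), f)
#' g <- readTriples(f)
#' numEntities(g)  # 3
#' @export
readTriples <- function(path) {
  if (!file.exists(path)) stopData("triple file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stopData("empty triple file (no graph can be built): ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stopData("malformed triple line ", lineNo[bad], " in ", path,
             " (", nf[bad], " tab-separated field(s), need >= 3)")
  }
  h <- vapply(parts, `[[`, "", 1L)
  r <- vapply(parts, `[[`, "", 2L)
  t <- vapply(parts, `[[`, "", 3L)
  # first-appearance vocab order: heads and tails interleaved per line
  ents <- unique(as.vector(rbind(h, t)))
  rels <- unique(r)
  triples <- cbind(match(h, ents), match(r, rels), match(t, ents))
  logInfo("read ", length(lines), " line(s), ", length(ents), " entities, ",
          length(rels), " relations from ", path)
  knowledgeGraph(ents, rels, triples)
}

#' Write a knowledge graph to a tab-separated triple file
#'
#' Output order is deterministic (sorted by head, relation, tail index), so
#' byte-identical files result from any in-memory insertion order.
#'
#' @param graph a [KnowledgeGraph-class]; must contain at least one triple.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTriples <- function(graph, path) {
  stopifnot(is(graph, "KnowledgeGraph"))
  tr <- graph@triples
  if (nrow(tr) == 0L) stopData("refusing to write an empty graph")
  ord <- order(tr[, 1L], tr[, 2L], tr[, 3L])
  tr <- tr[ord, , drop = FALSE]
  lines <- paste(graph@entities[tr[, 1L]], graph@relations[tr[, 2L]],
                 graph@entities[tr[, 3L]], sep = "\t")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stopData("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  logInfo("wrote ", length(lines), " triple(s) to ", path)
  invisible(path)
}

#' Dump a vocabulary as a two-column `label<TAB>index` TSV
#'
#' @param graph a [KnowledgeGraph-class].
#' @param path output file path.
#' @param what `"entities"` or `"relations"`.
#' @return `path`, invisibly.
#' @export
writeVocab <- function(graph, path, what = c("entities", "relations")) {
  what <- match.arg(what)
  labs <- if (what == "entities") graph@entities else graph@relations
  writeLines(paste(labs, seq_along(labs), sep = "\t"), path, useBytes = TRUE)
  logInfo("wrote ", length(labs), " ", what, " to ", path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Neighborhood and message edges
# ---------------------------------------------------------------------------

#' First-order neighborhood of an entity
#'
#' With `inverse = FALSE`, returns the pairs `(r, v)` for triples where `u`
#' is the head.  With `inverse = TRUE`, additionally returns `(r + |R|, v)`
#' for triples where `u` is the tail: the inverse-augmented message edges
#' that make reachability symmetric.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param u entity index (1-based).
#' @param inverse include inverse-augmented edges.
#' @return Integer matrix with columns `rel`, `nbr` (zero rows if isolated).
#' @export
neighborhoodOf <- function(graph, u, inverse = FALSE) {
  stopifnot(is(graph, "KnowledgeGraph"))
  u <- as.integer(u)
  if (length(u) != 1L || is.na(u) || u < 1L || u > length(graph@entities))
    stopData("entity index out of range: ", u)
  adj <- graph@adjacency[[u]]
  nR <- length(graph@relations)
  fwd <- adj[adj[, "dir"] == 1L, c("rel", "nbr"), drop = FALSE]
  if (!inverse) return(fwd)
  inv <- adj[adj[, "dir"] == 2L, c("rel", "nbr"), drop = FALSE]
  inv[, "rel"] <- inv[, "rel"] + nR
  rbind(fwd, inv)
}

# Inverse-augmented message-edge list in CSR-like layout sorted by
# destination: a triple (h, r, t) yields message edges (dst = h, rel = r,
# src = t) and (dst = t, rel = r + |R|, src = h).  Consumed by the local
# message-passing module and the compiled engine.
messageEdges <- function(graph) {
  tr <- graph@triples
  nR <- length(graph@relations)
  dst <- c(tr[, 1L], tr[, 3L])
  rel <- c(tr[, 2L], tr[, 2L] + nR)
  src <- c(tr[, 3L], tr[, 1L])
  ord <- order(dst, rel, src)
  list(dst = dst[ord], rel = rel[ord], src = src[ord],
       nEntities = length(graph@entities), nRelAug = 2L * nR)
}

# ---------------------------------------------------------------------------
# Graph statistics
# ---------------------------------------------------------------------------

asUndirectedIgraph <- function(graph) {
  tr <- graph@triples
  g <- igraph::make_empty_graph(n = length(graph@entities), directed = FALSE)
  if (nrow(tr) > 0L)
    g <- igraph::add_edges(g, rbind(tr[, 1L], tr[, 3L]))
  igraph::simplify(g)
}

#' Mean shortest-path distance over reachable node pairs
#'
#' Every directed edge is treated as an undirected edge of weight 1; the
#' statistic is the mean shortest-path length over all unordered reachable
#' pairs (unreachable pairs are excluded from numerator and denominator).
#' Graphs larger than `nodeCap` are estimated from `nSources` uniformly
#' sampled BFS sources (seeded); the result then carries
#' `attr(, "estimate") = TRUE`.
#'
#' @param graph a [KnowledgeGraph-class] with at least one edge.
#' @param nodeCap exact computation up to this many entities (default 5000).
#' @param nSources BFS sources used beyond the cap (default 1000).
#' @param seed RNG seed for source sampling.
#' @return Mean distance in hops (numeric scalar).
#' @export
avgReachableDistance <- function(graph, nodeCap = 5000L, nSources = 1000L,
                                 seed = 1L) {
  stopifnot(is(graph, "KnowledgeGraph"))
  if (nrow(graph@triples) == 0L)
    stopData("average reachable distance is undefined for an edgeless graph")
  g <- asUndirectedIgraph(graph)
  n <- igraph::vcount(g)
  if (n <= nodeCap) {
    D <- igraph::distances(g)
    vals <- D[upper.tri(D)]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L)
      stopData("no reachable node pair in the graph")
    return(mean(vals))
  }
  src <- withSeed(seed, sample.int(n, min(nSources, n)))
  D <- igraph::distances(g, v = src)
  D[cbind(seq_along(src), src)] <- NA_real_   # drop self distances
  vals <- D[is.finite(D)]
  if (length(vals) == 0L) stopData("no reachable node pair in the graph")
  est <- mean(vals)
  attr(est, "estimate") <- TRUE
  logInfo("avgReachableDistance estimated from ", length(src), " sources")
  est
}

#' Basic statistics of a knowledge graph
#'
#' @param graph a [KnowledgeGraph-class].
#' @return A list with entity, relation and triple counts and (if the graph
#'   has edges) the average reachable-pair distance.
#' @export
graphStats <- function(graph) {
  stopifnot(is(graph, "KnowledgeGraph"))
  list(
    n_entities = length(graph@entities),
    n_relations = length(graph@relations),
    n_triples = nrow(graph@triples),
    avg_reachable_distance =
      if (nrow(graph@triples) > 0L) as.numeric(avgReachableDistance(graph))
      else NA_real_
  )
}
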