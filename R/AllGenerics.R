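# Accessor generics.  Slot access stays internal to the package; user code
# goes through these.

#' @rdname KnowledgeGraph-class
#' @param x a `KnowledgeGraph` or `InductiveSplit`.
#' @export
setGeneric("entityLabels", function(x) standardGeneric("entityLabels"))
#' @rdname KnowledgeGraph-class
#' @export
setGeneric("relationLabels", function(x) standardGeneric("relationLabels"))
#' @rdname KnowledgeGraph-class
#' @export
setGeneric("tripleMatrix", function(x) standardGeneric("tripleMatrix"))
#' @rdname KnowledgeGraph-class
#' @export
setGeneric("numEntities", function(x) standardGeneric("numEntities"))
#' @rdname KnowledgeGraph-class
#' @export
setGeneric("numRelations", function(x) standardGeneric("numRelations"))
#' @rdname KnowledgeGraph-class
#' @export
setGeneric("numTriples", function(x) standardGeneric("numTriples"))

#' @rdname InductiveSplit-class
#' @param x an `InductiveSplit`.
#' @export
setGeneric("trainGraph", function(x) standardGeneric("trainGraph"))
#' @rdname InductiveSplit-class
#' @export
setGeneric("testGraph", function(x) standardGeneric("testGraph"))
#' @rdname InductiveSplit-class
#' @export
setGeneric("trainQueries", function(x) standardGeneric("trainQueries"))
#' @rdname InductiveSplit-class
#' @export
setGeneric("validQueries", function(x) standardGeneric("validQueries"))
#' @rdname InductiveSplit-class
#' @export
setGeneric("testQueries", function(x) standardGeneric("testQueries"))

#' @rdname EvalReport-class
#' @param x an `EvalReport`.
#' @export
setGeneric("hitsAt10", function(x) standardGeneric("hitsAt10"))
#' @rdname EvalReport-class
#' @export
setGeneric("aucPRValue", function(x) standardGeneric("aucPRValue"))

#' @rdname KnowledgeGraph-class
setMethod("entityLabels", "KnowledgeGraph", function(x) x@entities)
#' @rdname KnowledgeGraph-class
setMethod("relationLabels", "KnowledgeGraph", function(x) x@relations)
#' @rdname KnowledgeGraph-class
setMethod("tripleMatrix", "KnowledgeGraph", function(x) x@triples)
#' @rdname KnowledgeGraph-class
setMethod("numEntities", "KnowledgeGraph", function(x) length(x@entities))
#' @rdname KnowledgeGraph-class
setMethod("numRelations", "KnowledgeGraph", function(x) length(x@relations))
#' @rdname KnowledgeGraph-class
setMethod("numTriples", "KnowledgeGraph", function(x) nrow(x@triples))

#' @rdname InductiveSplit-class
setMethod("trainGraph", "InductiveSplit", function(x) x@train_graph)
#' @rdname InductiveSplit-class
setMethod("testGraph", "InductiveSplit", function(x) x@test_graph)
#' @rdname InductiveSplit-class
setMethod("trainQueries", "InductiveSplit", function(x) x@train_queries)
#' @rdname InductiveSplit-class
setMethod("validQueries", "InductiveSplit", function(x) x@valid_queries)
#' @rdname InductiveSplit-class
setMethod("testQueries", "InductiveSplit", function(x) x@test_queries)

#' @rdname EvalReport-class
setMethod("hitsAt10", "EvalReport", function(x) x@hitsAt10)
#' @rdname EvalReport-class
setMethod("aucPRValue", "EvalReport", function(x) x@aucPR)
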