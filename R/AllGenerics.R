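#' Accessors for pciNet classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{exprValues} and \code{sampleClasses} read the matrix and labels of
#' an \linkS4class{ExpressionDataset}, \code{exprScale} its measurement
#' scale; \code{geneSets} returns the named list behind a
#' \linkS4class{GeneSetCollection}; \code{drugTargets} the named list behind
#' a \linkS4class{DrugTargetMap}; \code{networkNodes} / \code{networkEdges}
#' the pieces of a \linkS4class{PathwayNetwork}; \code{dsScores} /
#' \code{dsLabels} the pieces of a \linkS4class{DSMatrix}.
#'
#' @param x an object of the matching class.
#' @return the accessed component (matrix, character vector, list or
#'   data.frame as documented above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("sampleClasses", function(x) standardGeneric("sampleClasses"))

#' @rdname accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("drugTargets", function(x) standardGeneric("drugTargets"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("dsScores", function(x) standardGeneric("dsScores"))

#' @rdname accessors
#' @export
setGeneric("dsLabels", function(x) standardGeneric("dsLabels"))

#' @rdname accessors
setMethod("exprValues", "ExpressionDataset", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
setMethod("sampleClasses", "ExpressionDataset", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$class), colnames(x)))

#' @rdname accessors
setMethod("exprScale", "ExpressionDataset", function(x)
    S4Vectors::metadata(x)$scale)

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
setMethod("drugTargets", "DrugTargetMap", function(x) x@targets)

#' @rdname accessors
setMethod("networkNodes", "PathwayNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("networkEdges", "PathwayNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("dsScores", "DSMatrix", function(x) x@scores)

#' @rdname accessors
setMethod("dsLabels", "DSMatrix", function(x) x@labels)

setMethod("show", "ExpressionDataset", function(object) {
    cat("ExpressionDataset:", nrow(object), "genes x", ncol(object), "samples",
        sprintf("[scale: %s]\n", exprScale(object)))
    tab <- table(sampleClasses(object))
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection of", length(object@sets), "pathways",
        sprintf("[provenance: %s]\n", object@provenance))
    if (length(object@sets))
        cat("set sizes:", paste(range(lengths(object@sets)), collapse = "-"), "genes\n")
})

setMethod("show", "DrugTargetMap", function(object) {
    cat("DrugTargetMap of", length(object@targets), "drugs;",
        "target-set sizes", paste(range(lengths(object@targets)), collapse = "-"), "\n")
})

setMethod("show", "PathwayNetwork", function(object) {
    cat("PathwayNetwork:", length(object@nodes), "pathways,",
        nrow(object@edges), "cross-talk edges\n")
})

setMethod("show", "DSMatrix", function(object) {
    cat("DSMatrix:", nrow(object@scores), "samples x",
        ncol(object@scores), "pathway pairs\n")
    tab <- table(object@labels)
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname accessors
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname accessors
setMethod("names", "DrugTargetMap", function(x) names(x@targets))

#' Extract one gene set by name or position
#' @param x a \linkS4class{GeneSetCollection}
#' @param i pathway name or index
#' @return character vector of gene identifiers
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])
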