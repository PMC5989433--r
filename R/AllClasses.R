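#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats sd p.adjust fisher.test pt predict setNames rnorm
#' @importFrom utils read.delim write.table combn packageVersion
NULL

#' Labelled expression dataset
#'
#' A genes-by-samples expression matrix with a class label per sample,
#' stored as a \linkS4class{SummarizedExperiment} whose \code{colData}
#' carries a \code{class} column and whose metadata records the
#' measurement scale (\code{"counts"}, \code{"cpm"} or \code{"log2"}).
#' Downstream stages convert between scales explicitly and never guess.
#'
#' @slot ... inherits all slots from \code{SummarizedExperiment}.
#' @seealso [ExpressionDataset()], [readExpression()], [normalizeCPM()]
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) must be present and unique")
    if (!"class" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'class' column")
    else if (anyNA(SummarizedExperiment::colData(object)$class))
        msg <- c(msg, "every sample must have a class label")
    sc <- S4Vectors::metadata(object)$scale
    if (is.null(sc) || !sc %in% c("counts", "cpm", "log2"))
        msg <- c(msg, "metadata()$scale must be one of 'counts', 'cpm', 'log2'")
    else if (sc == "counts" &&
             any(SummarizedExperiment::assay(object, "exprs") < 0, na.rm = TRUE))
        msg <- c(msg, "negative entries are not allowed on the counts scale")
    if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames = sample identifiers).
#' @param labels named character vector mapping sample identifier to class
#'   name; every column of \code{values} must be covered.
#' @param scale measurement scale of \code{values}: raw \code{"counts"}
#'   (non-negative), \code{"cpm"}, or \code{"log2"}.
#' @return an \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ds <- ExpressionDataset(m, c(s1 = "case", s2 = "case", s3 = "control"))
#' exprValues(ds)
#' @export
ExpressionDataset <- function(values, labels, scale = c("counts", "cpm", "log2")) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        stop("expression matrix must have sample identifiers as colnames")
    if (is.null(names(labels)))
        stop("labels must be named by sample identifier")
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
        stop("samples without a class label: ", paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(class = as.character(labels),
                                       row.names = colnames(values)),
        metadata = list(scale = scale))
    new("ExpressionDataset", se)
}

#' Collection of named pathway gene sets
#'
#' @slot sets named list of character vectors (gene identifiers), one per
#'   pathway; names unique.
#' @slot provenance free-text origin of the collection.
#' @seealso [GeneSetCollection()], [readGMT()], [intersectCollection()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", provenance = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- NULL
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || any(names(object@sets) == "") ||
            anyDuplicated(names(object@sets)))
            msg <- c(msg, "pathway names must be present and unique")
        if (!all(vapply(object@sets, is.character, logical(1))))
            msg <- c(msg, "every gene set must be a character vector")
        if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0))
            msg <- c(msg, "gene sets must not contain duplicate genes")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param provenance origin string recorded with the collection.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, provenance = "unspecified") {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    new("GeneSetCollection", sets = sets, provenance = provenance)
}

#' Drug-to-target-genes map
#'
#' @slot targets named list: drug name -> character vector of target gene
#'   identifiers; empty target sets are rejected.
#' @seealso [DrugTargetMap()], [readDrugTargets()], [mapDrugs()]
#' @exportClass DrugTargetMap
setClass("DrugTargetMap", representation(targets = "list"))

setValidity("DrugTargetMap", function(object) {
    msg <- NULL
    if (length(object@targets)) {
        if (is.null(names(object@targets)) || anyDuplicated(names(object@targets)))
            msg <- c(msg, "drug names must be present and unique")
        if (any(lengths(object@targets) == 0))
            msg <- c(msg, "empty target sets are not allowed")
    } else {
        msg <- c(msg, "at least one drug is required")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a DrugTargetMap
#'
#' @param targets named list of character vectors of target genes.
#' @return a \linkS4class{DrugTargetMap}.
#' @export
DrugTargetMap <- function(targets) {
    new("DrugTargetMap", targets = lapply(targets, function(g) unique(as.character(g))))
}

#' Undirected pathway cross-talk network
#'
#' Nodes are pathways; edges are selected cross-talks, stored once in
#' canonical orientation (\code{pathway_a < pathway_b}) with an optional
#' weight (bootstrap selection frequency). Edge weights are metadata only:
#' all shortest-path computations treat edges as unit length.
#'
#' @slot nodes character vector of pathway names.
#' @slot edges data.frame with columns \code{pathway_a}, \code{pathway_b},
#'   \code{weight}.
#' @seealso [PathwayNetwork()], [buildNetwork()], [networkEfficiency()]
#' @exportClass PathwayNetwork
setClass("PathwayNetwork",
         representation(nodes = "character", edges = "data.frame"))

setValidity("PathwayNetwork", function(object) {
    msg <- NULL
    e <- object@edges
    if (!all(c("pathway_a", "pathway_b", "weight") %in% colnames(e)))
        msg <- c(msg, "edges need columns pathway_a, pathway_b, weight")
    else {
        if (anyDuplicated(object@nodes))
            msg <- c(msg, "node names must be unique")
        if (nrow(e)) {
            if (!all(c(e$pathway_a, e$pathway_b) %in% object@nodes))
                msg <- c(msg, "edges reference unknown nodes")
            if (any(e$pathway_a == e$pathway_b))
                msg <- c(msg, "self-loops are not allowed")
            if (any(e$pathway_a >= e$pathway_b))
                msg <- c(msg, "edges must be stored in canonical order (pathway_a < pathway_b)")
            if (anyDuplicated(paste(e$pathway_a, e$pathway_b, sep = "\r")))
                msg <- c(msg, "duplicate edges are not allowed")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a PathwayNetwork
#'
#' Edge endpoints are put into canonical (sorted) orientation and duplicate
#' edges are collapsed by summing their weights.
#'
#' @param nodes character vector of pathway names; endpoints of \code{edges}
#'   are added automatically.
#' @param edges data.frame with columns \code{pathway_a}, \code{pathway_b}
#'   and optionally \code{weight} (default 1 each).
#' @return a \linkS4class{PathwayNetwork}.
#' @examples
#' net <- PathwayNetwork(edges = data.frame(pathway_a = c("A", "B"),
#'                                          pathway_b = c("B", "C")))
#' networkNodes(net)
#' @export
PathwayNetwork <- function(nodes = character(), edges = NULL) {
    if (is.null(edges) || nrow(edges) == 0) {
        edges <- data.frame(pathway_a = character(), pathway_b = character(),
                            weight = numeric())
    } else {
        a <- as.character(edges$pathway_a)
        b <- as.character(edges$pathway_b)
        if (any(a == b)) stop("self-loops are not allowed")
        w <- if ("weight" %in% colnames(edges)) as.numeric(edges$weight) else rep(1, length(a))
        lo <- pmin(a, b); hi <- pmax(a, b)
        key <- paste(lo, hi, sep = "\r")
        agg <- rowsum(w, key)
        parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
        edges <- data.frame(pathway_a = vapply(parts, `[`, "", 1),
                            pathway_b = vapply(parts, `[`, "", 2),
                            weight = agg[, 1], row.names = NULL)
        edges <- edges[order(edges$pathway_a, edges$pathway_b), , drop = FALSE]
        rownames(edges) <- NULL
    }
    nodes <- sort(unique(c(as.character(nodes), edges$pathway_a, edges$pathway_b)))
    new("PathwayNetwork", nodes = nodes, edges = edges)
}

#' Per-sample discriminating-score matrix
#'
#' Rows are samples, columns are unordered pathway pairs in canonical
#' lexicographic order, named \code{"pathwayA|pathwayB"}; each entry is the
#' discriminating score DS = (M_x - M_y) / (S_x + S_y) of that pair in that
#' sample. Sample class labels are carried along for classification.
#'
#' @slot scores numeric matrix, samples x pairs.
#' @slot labels character vector of class labels, aligned with rows.
#' @seealso [dsMatrix()], [topPairs()]
#' @exportClass DSMatrix
setClass("DSMatrix", representation(scores = "matrix", labels = "character"))

setValidity("DSMatrix", function(object) {
    msg <- NULL
    if (length(object@labels) != nrow(object@scores))
        msg <- c(msg, "one label per sample row is required")
    if (nrow(object@scores) && is.null(rownames(object@scores)))
        msg <- c(msg, "score rows must be named by sample")
    if (ncol(object@scores) && is.null(colnames(object@scores)))
        msg <- c(msg, "score columns must be named by pathway pair")
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "all DS entries must be finite")
    if (is.null(msg)) TRUE else msg
})
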