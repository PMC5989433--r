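#' Read an expression matrix with sample labels
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and gene identifiers in the first column; the labels file is tab-separated
#' with columns \code{sample} and \code{class}. Samples present in the matrix
#' but absent from the label file are dropped with a warning; a sample
#' overlap of zero is an error.
#'
#' @param matrixPath path to the expression TSV.
#' @param labelsPath path to the sample/class TSV.
#' @param scale measurement scale of the stored values (see
#'   [ExpressionDataset()]).
#' @return an \linkS4class{ExpressionDataset}.
#' @export
readExpression <- function(matrixPath, labelsPath, scale = c("counts", "cpm", "log2")) {
    scale <- match.arg(scale)
    tab <- read.delim(matrixPath, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2)
        stop("malformed expression matrix header in ", matrixPath)
    genes <- as.character(tab[[1]])
    dup <- genes[duplicated(genes)]
    if (length(dup))
        stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes

    lab <- read.delim(labelsPath, stringsAsFactors = FALSE)
    if (!all(c("sample", "class") %in% colnames(lab)))
        stop("labels file must have columns 'sample' and 'class'")
    labels <- setNames(as.character(lab$class), as.character(lab$sample))

    keep <- colnames(m) %in% names(labels)
    if (!any(keep))
        stop("no overlap between matrix samples and label file ", labelsPath)
    if (!all(keep))
        warning("dropping ", sum(!keep), " sample(s) absent from the label file: ",
                paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
    ExpressionDataset(m, labels, scale = scale)
}

#' Write an ExpressionDataset to matrix + labels TSV files
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param matrixPath,labelsPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeExpression <- function(dataset, matrixPath, labelsPath) {
    m <- exprValues(dataset)
    out <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(out, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
    lab <- data.frame(sample = colnames(m), class = unname(sampleClasses(dataset)))
    write.table(lab, labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(matrixPath, labelsPath))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, \code{name TAB description TAB gene
#' TAB gene ...}. Duplicate genes within a line are deduplicated; lines with
#' no genes are skipped with a warning; duplicate pathway names are an error.
#'
#' @param path path to the GMT file.
#' @param provenance origin string; defaults to the file path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, provenance = path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(fields, `[`, "", 1)
    if (anyDuplicated(nm))
        stop("duplicate pathway name(s) in ", path, ": ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    names(sets) <- nm
    empty <- lengths(sets) == 0
    if (any(empty)) {
        warning("skipping ", sum(empty), " GMT line(s) with no genes: ",
                paste(nm[empty], collapse = ", "))
        sets <- sets[!empty]
    }
    GeneSetCollection(sets, provenance = provenance)
}

#' Write a GeneSetCollection as GMT
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(collection, path) {
    sets <- geneSets(collection)
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, collection@provenance, sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a drug-to-target table
#'
#' Tab-separated rows of \code{drug TAB gene}; rows are grouped by drug into
#' target sets (duplicates collapse by set semantics).
#'
#' @param path path to the TSV (header optional: a first line reading
#'   \code{drug<TAB>gene} is treated as a header).
#' @return a \linkS4class{DrugTargetMap}.
#' @export
readDrugTargets <- function(path) {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("drug", "gene"))
    if (nrow(tab) && tab$drug[1] == "drug" && tab$gene[1] == "gene")
        tab <- tab[-1, , drop = FALSE]
    if (!nrow(tab))
        stop("empty drug-target file: ", path)
    DrugTargetMap(split(tab$gene, tab$drug))
}

#' Write a DrugTargetMap as TSV
#' @param drugs a \linkS4class{DrugTargetMap}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDrugTargets <- function(drugs, path) {
    t <- drugTargets(drugs)
    tab <- data.frame(drug = rep(names(t), lengths(t)), gene = unlist(t, use.names = FALSE))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export / import a pathway network as a TSV edge list
#'
#' Columns \code{pathway_a}, \code{pathway_b}, \code{frequency}. Isolated
#' nodes are preserved via rows with an empty \code{pathway_b}.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @param path file path.
#' @return \code{writeEdgeList} returns \code{path} invisibly;
#'   \code{readEdgeList} returns a \linkS4class{PathwayNetwork}.
#' @export
writeEdgeList <- function(network, path) {
    e <- networkEdges(network)
    tab <- data.frame(pathway_a = e$pathway_a, pathway_b = e$pathway_b,
                      frequency = e$weight)
    isolated <- setdiff(networkNodes(network), c(e$pathway_a, e$pathway_b))
    if (length(isolated))
        tab <- rbind(tab, data.frame(pathway_a = isolated, pathway_b = "",
                                     frequency = NA_real_))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    tab$pathway_b[is.na(tab$pathway_b)] <- ""
    iso <- tab$pathway_b == ""
    edges <- data.frame(pathway_a = tab$pathway_a[!iso],
                        pathway_b = tab$pathway_b[!iso],
                        weight = tab$frequency[!iso])
    PathwayNetwork(nodes = tab$pathway_a[iso], edges = edges)
}

#' Intersect a pathway collection with a measured-gene universe
#'
#' Every set is reduced to its genes present in \code{universe}; sets that
#' fall below \code{minSize} members are dropped with a warning. All
#' enrichment counts downstream use these intersected sizes.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of measured gene identifiers.
#' @param minSize minimum post-intersection set size to keep (default 2).
#' @return the intersected \linkS4class{GeneSetCollection}.
#' @export
intersectCollection <- function(collection, universe, minSize = 2) {
    sets <- lapply(geneSets(collection), intersect, y = universe)
    small <- lengths(sets) < minSize
    if (any(small)) {
        warning("dropping ", sum(small), " pathway(s) with < ", minSize,
                " measured genes: ", paste(names(sets)[small], collapse = ", "))
        sets <- sets[!small]
    }
    GeneSetCollection(sets, provenance = collection@provenance)
}
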