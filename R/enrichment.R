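#' Fisher's exact over-representation test for one pathway
#'
#' Builds the 2x2 table (overlap, query-only, pathway-only, neither) within
#' the gene universe and returns the one-sided (greater) Fisher exact
#' p-value, i.e. the hypergeometric upper tail P(X >= overlap). Query and
#' pathway are intersected with the universe first. An empty query yields
#' p = 1 with a warning; an empty universe is an error.
#'
#' @param query character vector of query genes (e.g. DEGs or drug targets).
#' @param pathway character vector of pathway genes.
#' @param universe character vector of all measured genes.
#' @param alternative \code{"greater"} (over-representation, default) or
#'   \code{"two.sided"}.
#' @return one-row data.frame with columns \code{overlap},
#'   \code{k_pathway}, \code{n_query}, \code{N_universe}, \code{pvalue}.
#' @examples
#' u <- sprintf("g%03d", 1:100)
#' fisherEnrich(u[1:20], u[c(1:6, 50:53)], u)
#' @export
fisherEnrich <- function(query, pathway, universe,
                         alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    universe <- unique(universe)
    if (!length(universe)) stop("empty gene universe")
    query <- intersect(unique(query), universe)
    pathway <- intersect(unique(pathway), universe)
    ov <- length(intersect(query, pathway))
    N <- length(universe); k <- length(pathway); n <- length(query)
    if (n == 0) {
        warning("empty query gene set; returning p = 1")
        p <- 1
    } else {
        tab <- matrix(c(ov, n - ov, k - ov, N - n - k + ov), nrow = 2)
        p <- fisher.test(tab, alternative = alternative)$p.value
    }
    data.frame(overlap = ov, k_pathway = k, n_query = n, N_universe = N,
               pvalue = p)
}

#' Pathway enrichment of a gene list against a collection
#'
#' One Fisher over-representation test per pathway, with BH correction
#' across all pathways tested in this run. A pathway is enriched when its
#' adjusted p-value is strictly below \code{pThreshold}.
#'
#' @param query character vector of query genes.
#' @param collection a \linkS4class{GeneSetCollection} (already intersected
#'   with the universe, see [intersectCollection()]).
#' @param universe character vector of measured genes.
#' @param pThreshold strict adjusted-p cut (default 0.01).
#' @param alternative passed to [fisherEnrich()].
#' @return data.frame with one row per pathway: \code{pathway},
#'   \code{overlap}, \code{k_pathway}, \code{n_query}, \code{N_universe},
#'   \code{pvalue}, \code{padj}, \code{is_enriched}.
#' @export
enrichPathways <- function(query, collection, universe, pThreshold = 0.01,
                           alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    sets <- geneSets(collection)
    if (!length(sets)) stop("empty pathway collection")
    rows <- lapply(sets, fisherEnrich, query = query, universe = universe,
                   alternative = alternative)
    out <- do.call(rbind, rows)
    out <- data.frame(pathway = names(sets), out, row.names = NULL)
    out$padj <- bhAdjust(out$pvalue)
    out$is_enriched <- out$padj < pThreshold
    out[order(out$padj, out$pvalue, out$pathway), , drop = FALSE]
}
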