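#' Build the pathway cross-talk network from a selection result
#'
#' Nodes are the pathways appearing in any retained pair; edges are the
#' retained pairs, weighted by their bootstrap selection frequency. Pairs
#' below \code{minFrequency} are dropped first.
#'
#' @param selection a \code{SelectionResult} from [runMonteCarlo()], or a
#'   data.frame with columns \code{pathway_a}, \code{pathway_b} and
#'   optionally \code{frequency}.
#' @param minFrequency minimum selection frequency for an edge (default 1).
#' @return a \linkS4class{PathwayNetwork}.
#' @export
buildNetwork <- function(selection, minFrequency = 1) {
    pairs <- if (inherits(selection, "SelectionResult")) selection$pairs else selection
    if (!"frequency" %in% colnames(pairs)) pairs$frequency <- 1
    pairs <- pairs[pairs$frequency >= minFrequency, , drop = FALSE]
    if (!nrow(pairs))
        stop("no pathway pairs left after the frequency filter")
    PathwayNetwork(edges = data.frame(pathway_a = pairs$pathway_a,
                                      pathway_b = pairs$pathway_b,
                                      weight = pairs$frequency))
}

asIgraph <- function(network) {
    g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(networkNodes(network))
    e <- networkEdges(network)
    if (nrow(e))
        g <- igraph::add_edges(g, rbind(e$pathway_a, e$pathway_b))
    g
}

#' Global network efficiency
#'
#' NE = sum over ordered node pairs i != j of 1/d(i, j), divided by
#' N(N - 1), with unweighted (unit-length) shortest-path distances;
#' disconnected pairs contribute 0 (1/infinity). NE is 1 for a complete
#' graph, 0 for an edgeless one, and defined as 0 when N <= 1.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @return an object of class \code{EfficiencyResult}: list with elements
#'   \code{NE} and \code{N}.
#' @examples
#' k4 <- PathwayNetwork(edges = data.frame(
#'     pathway_a = c("A", "A", "A", "B", "B", "C"),
#'     pathway_b = c("B", "C", "D", "C", "D", "D")))
#' networkEfficiency(k4)$NE  # 1: every node talks directly to every other
#' @export
networkEfficiency <- function(network) {
    N <- length(networkNodes(network))
    if (N <= 1)
        return(structure(list(NE = 0, N = N), class = "EfficiencyResult"))
    d <- igraph::distances(asIgraph(network))
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    structure(list(NE = sum(inv) / (N * (N - 1)), N = N),
              class = "EfficiencyResult")
}

#' @export
print.EfficiencyResult <- function(x, ...) {
    cat(sprintf("network efficiency NE = %.6g over N = %d nodes\n", x$NE, x$N))
    invisible(x)
}

#' Simulate the inhibition of a pathway subset
#'
#' Models drug-induced inhibition of the given pathways. In the default
#' \code{"delete"} mode the inhibited nodes are removed together with all
#' incident edges, so the efficiency of the result is renormalized by the
#' reduced node count (this is what allows the post-inhibition efficiency
#' to exceed the original one). The \code{"isolate"} mode only removes the
#' incident edges and keeps the nodes, for sensitivity analysis.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @param pathways character vector of nodes to inhibit (must exist).
#' @param mode \code{"delete"} (default) or \code{"isolate"}.
#' @return the inhibited \linkS4class{PathwayNetwork}.
#' @export
inhibit <- function(network, pathways, mode = c("delete", "isolate")) {
    mode <- match.arg(mode)
    pathways <- unique(pathways)
    unknown <- setdiff(pathways, networkNodes(network))
    if (length(unknown))
        stop("unknown pathway(s): ", paste(unknown, collapse = ", "))
    e <- networkEdges(network)
    e <- e[!(e$pathway_a %in% pathways | e$pathway_b %in% pathways), , drop = FALSE]
    nodes <- if (mode == "delete") setdiff(networkNodes(network), pathways)
             else networkNodes(network)
    new("PathwayNetwork", nodes = nodes, edges = e)
}

#' Pathway cross-talk inhibition percentage
#'
#' PCI = 100 x (1 - nNE / NE): the percentage of the network's activity
#' abolished by an inhibition. Negative when the inhibition increased
#' efficiency (nNE > NE); requires NE > 0.
#'
#' @param ne whole-network efficiency: an \code{EfficiencyResult} or a
#'   number.
#' @param nne post-inhibition efficiency, same forms.
#' @return the PCI percentage.
#' @examples
#' pci(0.3218, 0.3194)  # 0.7458..., printed as 0.75%
#' @export
pci <- function(ne, nne) {
    ne <- if (inherits(ne, "EfficiencyResult")) ne$NE else ne
    nne <- if (inherits(nne, "EfficiencyResult")) nne$NE else nne
    if (ne <= 0) stop("PCI is undefined for NE = 0")
    100 * (1 - nne / ne)
}

inhibitionRow <- function(network, subset, NE, mode) {
    inh <- inhibit(network, subset, mode)
    eff <- networkEfficiency(inh)
    data.frame(inhibited = paste(sort(subset), collapse = ";"),
               n_inhibited = length(subset),
               n_remaining = eff$N,
               nNE = eff$NE,
               PCI = pci(NE, eff$NE))
}

#' Inhibition scan of every single pathway
#'
#' Inhibits each node in turn and recomputes the network efficiency,
#' returning one row per node sorted by ascending post-inhibition
#' efficiency (strongest inhibitions first).
#'
#' @param network a \linkS4class{PathwayNetwork} with at least 2 nodes.
#' @param mode inhibition mode, see [inhibit()].
#' @return data.frame with columns \code{inhibited}, \code{n_inhibited},
#'   \code{n_remaining}, \code{nNE}, \code{PCI}.
#' @export
scanSingles <- function(network, mode = c("delete", "isolate")) {
    mode <- match.arg(mode)
    nodes <- networkNodes(network)
    if (length(nodes) < 2) stop("at least 2 nodes are required")
    NE <- networkEfficiency(network)$NE
    out <- do.call(rbind, lapply(nodes, function(v)
        inhibitionRow(network, v, NE, mode)))
    out <- out[order(out$nNE, out$inhibited), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Inhibition scan of every pathway pair
#'
#' Inhibits each of the N(N-1)/2 unordered node pairs in turn.
#'
#' @inheritParams scanSingles
#' @return data.frame as in [scanSingles()], one row per pair, sorted by
#'   ascending post-inhibition efficiency.
#' @export
scanPairs <- function(network, mode = c("delete", "isolate")) {
    mode <- match.arg(mode)
    nodes <- networkNodes(network)
    if (length(nodes) < 3) stop("at least 3 nodes are required")
    NE <- networkEfficiency(network)$NE
    pairs <- combn(nodes, 2)
    out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j)
        inhibitionRow(network, pairs[, j], NE, mode)))
    out <- out[order(out$nNE, out$inhibited), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Drug target pathway network (DTPN)
#'
#' The subnetwork induced by the pathways whose individual inhibition
#' strictly reduces network efficiency (nNE < NE): the candidate drug
#' target pathways.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @param singles optional precomputed [scanSingles()] table in
#'   \code{"delete"} mode; computed when NULL.
#' @return the induced \linkS4class{PathwayNetwork} (empty, with a
#'   warning, when no node qualifies).
#' @export
buildDTPN <- function(network, singles = NULL) {
    if (is.null(singles)) singles <- scanSingles(network, mode = "delete")
    NE <- networkEfficiency(network)$NE
    keep <- singles$inhibited[singles$nNE < NE]
    if (!length(keep)) {
        warning("no pathway reduces network efficiency; DTPN is empty")
        return(PathwayNetwork())
    }
    e <- networkEdges(network)
    e <- e[e$pathway_a %in% keep & e$pathway_b %in% keep, , drop = FALSE]
    new("PathwayNetwork", nodes = sort(keep), edges = e)
}

#' Associate drugs with DTPN pathways by target-gene enrichment
#'
#' For each drug, a Fisher over-representation test between its target
#' genes and each DTPN pathway's gene set within the measured-gene
#' universe; pathways with p strictly below the threshold are associated.
#' A drug with no targets in the universe gets an empty association and a
#' warning.
#'
#' @param drugs a \linkS4class{DrugTargetMap}.
#' @param dtpn the \linkS4class{PathwayNetwork} returned by [buildDTPN()].
#' @param collection the \linkS4class{GeneSetCollection} with the
#'   pathways' gene sets.
#' @param universe character vector of measured genes.
#' @param pThreshold strict Fisher-p cut (default 0.01).
#' @return list of \code{DrugPathwayAssociation} objects: lists with
#'   elements \code{drug}, \code{pathways}, \code{pvalues}.
#' @export
mapDrugs <- function(drugs, dtpn, collection, universe, pThreshold = 0.01) {
    nodes <- networkNodes(dtpn)
    if (!length(nodes)) stop("DTPN is empty")
    sets <- geneSets(collection)[nodes]
    lapply(names(drugTargets(drugs)), function(dr) {
        targets <- intersect(drugTargets(drugs)[[dr]], universe)
        if (!length(targets)) {
            warning("drug '", dr, "' has no targets in the universe")
            p <- setNames(numeric(0), character(0))
        } else {
            p <- vapply(sets, function(s)
                fisherEnrich(targets, s, universe)$pvalue, numeric(1))
        }
        hit <- p < pThreshold
        structure(list(drug = dr,
                       pathways = names(p)[hit],
                       pvalues = p[hit]),
                  class = "DrugPathwayAssociation")
    })
}

#' @export
print.DrugPathwayAssociation <- function(x, ...) {
    cat("drug", x$drug, "->", if (length(x$pathways))
        paste(x$pathways, collapse = ", ") else "(no associated pathway)", "\n")
    invisible(x)
}

#' Inhibition effect of a drug's pathway subsets
#'
#' Evaluates, on the full subtype network, the inhibition of every
#' nonempty subset of the pathways associated with a drug (2^m - 1
#' subsets), reporting nNE and PCI for each; this is the drug-combination
#' synergy table. Refuses more than \code{maxSubset} pathways to keep the
#' enumeration bounded.
#'
#' @param network the full subtype \linkS4class{PathwayNetwork}.
#' @param association a \code{DrugPathwayAssociation} from [mapDrugs()].
#' @param maxSubset maximum number of associated pathways to enumerate
#'   (default 6, i.e. at most 63 subsets).
#' @param mode inhibition mode, see [inhibit()].
#' @return data.frame with columns \code{drug}, \code{inhibited},
#'   \code{n_inhibited}, \code{n_remaining}, \code{nNE}, \code{PCI},
#'   ordered by subset size then name.
#' @export
drugCombinationPCI <- function(network, association, maxSubset = 6,
                               mode = c("delete", "isolate")) {
    mode <- match.arg(mode)
    paths <- sort(association$pathways)
    if (!length(paths))
        return(data.frame(drug = character(), inhibited = character(),
                          n_inhibited = integer(), n_remaining = integer(),
                          nNE = numeric(), PCI = numeric()))
    if (length(paths) > maxSubset)
        stop("drug '", association$drug, "' is associated with ", length(paths),
             " pathways; raise maxSubset to enumerate 2^", length(paths), " - 1 subsets")
    unknown <- setdiff(paths, networkNodes(network))
    if (length(unknown))
        stop("associated pathway(s) not in the network: ",
             paste(unknown, collapse = ", "))
    NE <- networkEfficiency(network)$NE
    subsets <- unlist(lapply(seq_along(paths), function(k)
        combn(paths, k, simplify = FALSE)), recursive = FALSE)
    out <- do.call(rbind, lapply(subsets, function(s)
        inhibitionRow(network, s, NE, mode)))
    out <- data.frame(drug = association$drug, out)
    out <- out[order(out$n_inhibited, out$inhibited), , drop = FALSE]
    rownames(out) <- NULL
    out
}
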