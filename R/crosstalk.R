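#' Mean and standard deviation of a pathway's genes in one sample
#'
#' The building blocks of the discriminating score: M is the arithmetic
#' mean and S the sample (n - 1 denominator) standard deviation of the
#' pathway's measured genes in a single sample's expression vector
#' (log2 scale expected).
#'
#' @param sampleValues named numeric vector, gene -> expression value.
#' @param pathway character vector of pathway genes; at least two must be
#'   present in \code{sampleValues}.
#' @return list with elements \code{M} and \code{S}.
#' @examples
#' pathwayStats(c(A = 1, B = 3, C = 7), c("A", "B"))
#' @export
pathwayStats <- function(sampleValues, pathway) {
    v <- sampleValues[intersect(pathway, names(sampleValues))]
    if (length(v) < 2)
        stop("pathway has fewer than 2 measured genes (should have been dropped at load)")
    list(M = mean(v), S = sd(v))
}

#' Discriminating score of a pathway pair
#'
#' DS = (M_x - M_y) / (S_x + S_y). When both standard deviations are zero
#' the ratio is undefined: equal means give 0, unequal means give
#' sign(M_x - M_y) times \code{cap}, keeping the feature matrix finite.
#'
#' @param x,y pathway statistics as returned by [pathwayStats()].
#' @param cap magnitude used for the degenerate zero-variance case
#'   (default 1e6).
#' @return the DS value (antisymmetric in x and y).
#' @examples
#' dsScore(list(M = 2, S = 1), list(M = 1, S = 1))
#' @export
dsScore <- function(x, y, cap = 1e6) {
    denom <- x$S + y$S
    num <- x$M - y$M
    if (denom > 0) return(num / denom)
    if (num == 0) 0 else sign(num) * cap
}

# Per-pathway M and S for every sample at once: returns list(M, S), each a
# pathways x samples matrix. Pathways must have >= 2 measured genes.
pathwayStatsMatrix <- function(m, sets) {
    M <- matrix(NA_real_, length(sets), ncol(m),
                dimnames = list(names(sets), colnames(m)))
    S <- M
    for (nm in names(sets)) {
        sub <- m[sets[[nm]], , drop = FALSE]
        if (nrow(sub) < 2)
            stop("pathway '", nm, "' has fewer than 2 measured genes")
        mu <- colMeans(sub)
        M[nm, ] <- mu
        S[nm, ] <- sqrt(colSums(sweep(sub, 2, mu)^2) / (nrow(sub) - 1))
    }
    list(M = M, S = S)
}

#' Discriminating-score matrix for all pathway pairs
#'
#' For every sample and every unordered pair of the given pathways
#' (canonical lexicographic order, columns named \code{"x|y"} with x < y),
#' computes DS from that sample's per-pathway mean and standard deviation.
#' The dataset must be log2-scaled; use [normalizeCPM()] +
#' [log2Transform()] first.
#'
#' @param dataset an \linkS4class{ExpressionDataset} on the log2 scale.
#' @param pathways character vector of pathway names to pair up.
#' @param collection a \linkS4class{GeneSetCollection} holding their gene
#'   sets (intersected with the measured genes).
#' @param cap degenerate-case cap passed to the DS rule (default 1e6).
#' @return a \linkS4class{DSMatrix} with P(P-1)/2 columns for P pathways.
#' @export
dsMatrix <- function(dataset, pathways, collection, cap = 1e6) {
    if (exprScale(dataset) != "log2")
        stop("dsMatrix expects a log2-scaled dataset; got '", exprScale(dataset), "'")
    pathways <- sort(unique(pathways))
    if (length(pathways) < 2)
        stop("at least two pathways are required to form pairs")
    sets <- geneSets(collection)[pathways]
    if (anyNA(names(sets)))
        stop("pathway(s) missing from the collection: ",
             paste(setdiff(pathways, names(geneSets(collection))), collapse = ", "))
    m <- exprValues(dataset)
    st <- pathwayStatsMatrix(m, sets)
    pairs <- combn(pathways, 2)
    scores <- matrix(NA_real_, ncol(m), ncol(pairs),
                     dimnames = list(colnames(m),
                                     paste(pairs[1, ], pairs[2, ], sep = "|")))
    for (j in seq_len(ncol(pairs))) {
        x <- pairs[1, j]; y <- pairs[2, j]
        num <- st$M[x, ] - st$M[y, ]
        den <- st$S[x, ] + st$S[y, ]
        ds <- ifelse(den > 0, num / den, ifelse(num == 0, 0, sign(num) * cap))
        scores[, j] <- ds
    }
    new("DSMatrix", scores = scores, labels = unname(sampleClasses(dataset)))
}
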