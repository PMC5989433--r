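#' Configuration for differential expression analysis
#'
#' Thresholds follow the pipeline's DEG rule: a gene is differentially
#' expressed when |log2 fold change| > \code{lfcThreshold} (strict) and its
#' Benjamini-Hochberg adjusted p-value is < \code{pThreshold} (strict).
#' \code{useAdjusted = FALSE} switches the p cut to the raw p-value.
#'
#' @param lfcThreshold positive log2 fold-change cut (default 1).
#' @param pThreshold positive p-value cut (default 0.01).
#' @param pseudocount added before log2 transform (default 1).
#' @param normalize apply counts-per-million scaling before the log
#'   transform when the dataset is on the counts scale (default TRUE).
#' @param useAdjusted apply \code{pThreshold} to the BH-adjusted p (default
#'   TRUE) rather than the raw p.
#' @return an object of class \code{DEAConfig}.
#' @export
deaConfig <- function(lfcThreshold = 1, pThreshold = 0.01, pseudocount = 1,
                      normalize = TRUE, useAdjusted = TRUE) {
    stopifnot(lfcThreshold > 0, pThreshold > 0, pseudocount >= 0)
    structure(list(lfcThreshold = lfcThreshold, pThreshold = pThreshold,
                   pseudocount = pseudocount, normalize = normalize,
                   useAdjusted = useAdjusted),
              class = "DEAConfig")
}

#' Counts-per-million normalization
#'
#' Each sample (column) is scaled so its values sum to 1e6. Requires the
#' counts scale; a sample with zero total is an error.
#'
#' @param dataset an \linkS4class{ExpressionDataset} on the counts scale.
#' @return the dataset on the \code{"cpm"} scale.
#' @export
normalizeCPM <- function(dataset) {
    if (exprScale(dataset) != "counts")
        stop("normalizeCPM expects a dataset on the counts scale, got '",
             exprScale(dataset), "'")
    m <- exprValues(dataset)
    libSize <- colSums(m)
    if (any(libSize == 0))
        stop("sample(s) with zero library size: ",
             paste(colnames(m)[libSize == 0], collapse = ", "))
    cpm <- sweep(m, 2, libSize, "/") * 1e6
    ExpressionDataset(cpm, sampleClasses(dataset), scale = "cpm")
}

#' Log2 transform with pseudocount
#'
#' @param dataset an \linkS4class{ExpressionDataset} on the counts or cpm
#'   scale.
#' @param pseudocount value added before taking log2 (default 1).
#' @return the dataset on the \code{"log2"} scale.
#' @export
log2Transform <- function(dataset, pseudocount = 1) {
    if (exprScale(dataset) == "log2")
        stop("dataset is already log2-scaled")
    ExpressionDataset(log2(exprValues(dataset) + pseudocount),
                      sampleClasses(dataset), scale = "log2")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped to 1 and aligned with the input order.
#' Thin validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues numeric vector of probabilities in \[0, 1\].
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(pvalues) {
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

# Vectorised Welch two-sample test per matrix row (x, y: group matrices).
# Zero pooled variance: p = 1 when the means agree, p = 0 otherwise.
welchRows <- function(x, y) {
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (nx - 1)
    vy <- rowSums((y - my)^2) / (ny - 1)
    se2 <- vx / nx + vy / ny
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * pt(-abs(t), df)
    zero <- se2 == 0
    p[zero] <- ifelse(mx[zero] == my[zero], 1, 0)
    list(diff = mx - my, p = p)
}

#' Differential expression between a case and a control class
#'
#' Two-sample unequal-variance (Welch) test per gene on the
#' log2(CPM + pseudocount) scale, with BH multiplicity correction across
#' all tested genes. The log2 fold change is the difference of mean
#' log2-transformed values (case minus control).
#'
#' @param dataset an \linkS4class{ExpressionDataset} (counts, cpm or log2
#'   scale; counts are CPM-normalized first when
#'   \code{config$normalize} is TRUE).
#' @param case,control class names; both must be present with at least two
#'   samples each.
#' @param config a [deaConfig()].
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{pvalue}, \code{padj}, \code{is_deg}, one row per gene.
#' @examples
#' cfg <- simulationConfig(nPathways = 6, perturbed = c(P001 = 2), seed = 1)
#' gs <- makePathways(cfg)
#' ds <- makeExpression(cfg, gs)
#' deg <- differentialExpression(ds, "case", "control", deaConfig())
#' table(deg$is_deg)
#' @export
differentialExpression <- function(dataset, case, control, config = deaConfig()) {
    labels <- sampleClasses(dataset)
    for (cl in c(case, control)) {
        n <- sum(labels == cl)
        if (n == 0) stop("unknown class: ", cl)
        if (n < 2) stop("class '", cl, "' has fewer than 2 samples")
    }
    if (exprScale(dataset) == "counts" && config$normalize)
        dataset <- normalizeCPM(dataset)
    if (exprScale(dataset) != "log2")
        dataset <- log2Transform(dataset, config$pseudocount)
    m <- exprValues(dataset)
    w <- welchRows(m[, labels == case, drop = FALSE],
                   m[, labels == control, drop = FALSE])
    padj <- bhAdjust(w$p)
    pUsed <- if (config$useAdjusted) padj else w$p
    data.frame(gene = rownames(m),
               log2fc = unname(w$diff),
               pvalue = unname(w$p),
               padj = unname(padj),
               is_deg = unname(abs(w$diff) > config$lfcThreshold &
                               pUsed < config$pThreshold),
               row.names = NULL)
}
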