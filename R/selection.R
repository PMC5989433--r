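#' Configuration for pathway-pair selection
#'
#' Parameters of the Monte Carlo feature-selection wrapper: class-balanced
#' 60/40 train/test bootstraps, per-pair random-forest AUC under stratified
#' k-fold cross-validation, top-k retained per bootstrap and validated on
#' the held-out split.
#'
#' @param nBootstraps number of Monte Carlo bootstraps (default 50).
#' @param trainFraction fraction of each (balanced) class placed in the
#'   training split (default 0.6).
#' @param topK pairs retained per bootstrap by training AUC (default 10).
#' @param cvFolds folds of the cross-validation (default 10).
#' @param nTrees trees per random forest (default 500); mtry is sqrt of the
#'   feature count, i.e. 1 for a single-pair feature.
#' @param balanceClasses downsample both classes to the minority size
#'   before splitting (default TRUE).
#' @param testAUCFloor minimum held-out AUC for a pair to count as
#'   validated (default 0.5).
#' @param enrichPThreshold adjusted-p cut for the per-bootstrap pathway
#'   enrichment stage (default 0.01).
#' @param seed master seed; all per-bootstrap randomness is derived from it.
#' @return an object of class \code{SelectionConfig}.
#' @export
selectionConfig <- function(nBootstraps = 50, trainFraction = 0.6, topK = 10,
                            cvFolds = 10, nTrees = 500, balanceClasses = TRUE,
                            testAUCFloor = 0.5, enrichPThreshold = 0.01,
                            seed = 1) {
    stopifnot(trainFraction > 0, trainFraction < 1, topK >= 1, cvFolds >= 2,
              nBootstraps >= 1, nTrees >= 1)
    structure(list(nBootstraps = nBootstraps, trainFraction = trainFraction,
                   topK = topK, cvFolds = cvFolds, nTrees = nTrees,
                   balanceClasses = balanceClasses, testAUCFloor = testAUCFloor,
                   enrichPThreshold = enrichPThreshold, seed = as.integer(seed)),
              class = "SelectionConfig")
}

# One derived 31-bit seed per (master seed, index, salt) so every bootstrap
# and fold assignment is independently reproducible.
deriveSeed <- function(seed, index, salt = 0) {
    as.integer((as.double(seed) * 7919 + as.double(index) * 104729 +
                as.double(salt) * 613) %% 2147483629) + 1L
}

#' Balanced Monte Carlo train/test split
#'
#' Both classes are first downsampled without replacement to the minority
#' class size, then split into train/test stratified by class at the
#' configured fraction. Deterministic given (master seed, bootstrap index).
#'
#' @param dataset an \linkS4class{ExpressionDataset} (or a named character
#'   vector of class labels).
#' @param config a [selectionConfig()].
#' @param bootstrapIndex integer bootstrap number.
#' @return list with character vectors \code{train} and \code{test} of
#'   sample identifiers.
#' @export
mcSplit <- function(dataset, config, bootstrapIndex) {
    labels <- if (is(dataset, "ExpressionDataset")) sampleClasses(dataset) else dataset
    classes <- unique(labels)
    if (length(classes) < 2) stop("both classes must be present")
    sizes <- table(labels)
    minSize <- min(sizes)
    if (minSize < 5)
        stop("minority class has ", minSize, " samples; at least 5 are needed")
    set.seed(deriveSeed(config$seed, bootstrapIndex, salt = 1))
    train <- character(); test <- character()
    for (cl in sort(classes)) {
        pool <- names(labels)[labels == cl]
        keep <- if (config$balanceClasses) sample(pool, minSize) else sample(pool)
        nTrain <- round(config$trainFraction * length(keep))
        train <- c(train, keep[seq_len(nTrain)])
        test <- c(test, keep[-seq_len(nTrain)])
    }
    list(train = train, test = test)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so every fold holds both classes when each class has
# at least k members.
stratifiedFolds <- function(labels, k, seed) {
    set.seed(seed)
    fold <- integer(length(labels))
    for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

# Rank-statistic (Mann-Whitney) AUC with average ranks for ties.
rankAUC <- function(scores, isPositive) {
    nPos <- sum(isPositive); nNeg <- sum(!isPositive)
    if (nPos == 0 || nNeg == 0) return(NA_real_)
    r <- rank(scores)
    (sum(r[isPositive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Fit a probability forest on a single feature and return P(positive) for
# the test feature values. A constant feature admits no split, so the
# forest's prediction collapses to the training class prior; short-circuit
# that case (randomForest's split search degenerates on it).
rfProb <- function(trainFeature, trainLabels, testFeature, positive, nTrees, seed) {
    if (length(unique(trainFeature)) < 2)
        return(rep(mean(trainLabels == positive), length(testFeature)))
    set.seed(seed)
    y <- factor(trainLabels, levels = sort(unique(trainLabels)))
    fit <- randomForest::randomForest(
        x = data.frame(f = trainFeature), y = y,
        ntree = nTrees, mtry = 1)
    pr <- predict(fit, data.frame(f = testFeature), type = "prob")
    pr[, positive]
}

#' Cross-validated random-forest AUC of a single feature
#'
#' The feature (one pathway pair's DS values, or one gene's expression) is
#' scored by a random forest under stratified k-fold cross-validation with
#' a fixed fold seed. Out-of-fold predicted probabilities are pooled across
#' folds and ranked once against the true labels (the cvAUC-style pooled
#' estimator), with the \code{positive} class scored as positive; pooling
#' keeps the estimate stable even when single folds hold only a handful of
#' samples per class.
#'
#' @param feature numeric vector, one value per sample.
#' @param labels character vector of class labels (exactly two classes,
#'   each with at least \code{config$cvFolds} members).
#' @param positive the class scored as positive (the case class).
#' @param config a [selectionConfig()].
#' @param seed fold/forest seed (default: the config's master seed).
#' @return the cross-validated AUC in \[0, 1\].
#' @export
pairAUC <- function(feature, labels, positive, config = selectionConfig(),
                    seed = config$seed) {
    classes <- unique(labels)
    if (length(classes) != 2)
        stop("exactly two classes are required, got ", length(classes))
    if (!positive %in% classes) stop("unknown positive class: ", positive)
    if (min(table(labels)) < config$cvFolds)
        stop("each class needs at least cvFolds = ", config$cvFolds, " samples")
    fold <- stratifiedFolds(labels, config$cvFolds, deriveSeed(seed, 0, salt = 2))
    prob <- numeric(length(feature))
    for (f in seq_len(config$cvFolds)) {
        hold <- fold == f
        prob[hold] <- rfProb(feature[!hold], labels[!hold], feature[hold],
                             positive, config$nTrees,
                             deriveSeed(seed, f, salt = 3))
    }
    rankAUC(prob, labels == positive)
}

#' Rank pathway pairs by cross-validated AUC
#'
#' Every pair column of the training DS matrix is scored with [pairAUC()];
#' pairs are ranked by descending training AUC with ties broken by the
#' canonical pair name, and the top k are returned. When a held-out DS
#' matrix is supplied, each retained pair also gets a testing AUC from a
#' forest trained on the full training split and applied to the held-out
#' samples.
#'
#' @param train a \linkS4class{DSMatrix} for the training split.
#' @param test optional \linkS4class{DSMatrix} for the held-out split
#'   (same pair columns); \code{NULL} leaves the testing AUC as NA.
#' @param positive the class scored as positive.
#' @param config a [selectionConfig()].
#' @param seed scoring seed (default: the config's master seed).
#' @return data.frame with columns \code{pair}, \code{pathway_a},
#'   \code{pathway_b}, \code{train_auc}, \code{test_auc}, at most
#'   \code{config$topK} rows, best first.
#' @export
topPairs <- function(train, test = NULL, positive, config = selectionConfig(),
                     seed = config$seed) {
    sc <- dsScores(train); lab <- dsLabels(train)
    # one shared scoring seed: every pair is judged on the same folds, so
    # identical features get identical AUCs and ties are real ties
    scoreSeed <- deriveSeed(seed, 0, salt = 4)
    trainAUC <- vapply(seq_len(ncol(sc)), function(j)
        pairAUC(sc[, j], lab, positive, config, seed = scoreSeed),
        numeric(1))
    ord <- order(-trainAUC, colnames(sc))
    keep <- ord[seq_len(min(config$topK, length(ord)))]
    out <- data.frame(pair = colnames(sc)[keep],
                      train_auc = trainAUC[keep],
                      test_auc = NA_real_)
    if (!is.null(test)) {
        tsc <- dsScores(test); tlab <- dsLabels(test)
        testSeed <- deriveSeed(seed, 0, salt = 5)
        out$test_auc <- vapply(out$pair, function(p) {
            pr <- rfProb(sc[, p], lab, tsc[, p], positive, config$nTrees,
                         testSeed)
            rankAUC(pr, tlab == positive)
        }, numeric(1))
    }
    parts <- strsplit(out$pair, "|", fixed = TRUE)
    out$pathway_a <- vapply(parts, `[`, "", 1)
    out$pathway_b <- vapply(parts, `[`, "", 2)
    rownames(out) <- NULL
    out[, c("pair", "pathway_a", "pathway_b", "train_auc", "test_auc")]
}

#' Monte Carlo cross-validated selection of cross-talking pathway pairs
#'
#' The full selection wrapper: for each bootstrap, a balanced 60/40 split
#' is drawn; differential expression and pathway enrichment run on the
#' training split; DS matrices over the enriched pathways are built for
#' both splits; the top-k pairs by cross-validated training AUC are
#' retained when their held-out AUC reaches the configured floor.
#' Selections are aggregated into per-pair frequencies across bootstraps.
#'
#' @param dataset an \linkS4class{ExpressionDataset} holding the case and
#'   control samples (counts scale; CPM + log2 handled internally).
#' @param collection a \linkS4class{GeneSetCollection}, intersected with
#'   the measured genes.
#' @param case,control class names (case is scored as positive).
#' @param deaCfg a [deaConfig()].
#' @param selCfg a [selectionConfig()].
#' @param keepTables also store each bootstrap's DEG and enrichment tables
#'   in the result (default FALSE).
#' @return an object of class \code{SelectionResult}: list with
#'   \code{pairs} (data.frame pathway_a, pathway_b, frequency,
#'   mean_train_auc, mean_test_auc), \code{perBootstrap} (list of
#'   per-bootstrap data.frames; empty data.frame when a bootstrap found no
#'   enriched pathway pair), optionally \code{tables}, and the run
#'   metadata.
#' @examples
#' \donttest{
#' cfg <- simulationConfig(seed = 11)
#' gs <- makePathways(cfg)
#' ds <- makeExpression(cfg, gs)
#' sel <- runMonteCarlo(ds, intersectCollection(gs, rownames(ds)),
#'                      selCfg = selectionConfig(nBootstraps = 2, nTrees = 50))
#' head(sel$pairs)
#' }
#' @export
runMonteCarlo <- function(dataset, collection, case = "case",
                          control = "control", deaCfg = deaConfig(),
                          selCfg = selectionConfig(), keepTables = FALSE) {
    labels <- sampleClasses(dataset)
    keep <- labels %in% c(case, control)
    dataset <- dataset[, keep]
    logData <- dataset
    if (exprScale(logData) == "counts" && deaCfg$normalize)
        logData <- normalizeCPM(logData)
    if (exprScale(logData) != "log2")
        logData <- log2Transform(logData, deaCfg$pseudocount)

    perBootstrap <- vector("list", selCfg$nBootstraps)
    tables <- if (keepTables) vector("list", selCfg$nBootstraps) else NULL
    empty <- data.frame(pair = character(), pathway_a = character(),
                        pathway_b = character(), train_auc = numeric(),
                        test_auc = numeric())
    for (b in seq_len(selCfg$nBootstraps)) {
        sp <- mcSplit(dataset, selCfg, b)
        deg <- differentialExpression(dataset[, sp$train], case, control, deaCfg)
        degGenes <- deg$gene[deg$is_deg]
        enr <- enrichPathways(degGenes, collection, rownames(dataset),
                              pThreshold = selCfg$enrichPThreshold)
        if (keepTables) tables[[b]] <- list(deg = deg, enrichment = enr)
        hits <- enr$pathway[enr$is_enriched]
        if (length(hits) < 2) {
            message("bootstrap ", b, ": ", length(hits),
                    " enriched pathway(s); no pairs to score")
            perBootstrap[[b]] <- empty
            next
        }
        dsTrain <- dsMatrix(logData[, sp$train], hits, collection)
        dsTest <- dsMatrix(logData[, sp$test], hits, collection)
        tp <- topPairs(dsTrain, dsTest, positive = case, config = selCfg,
                       seed = deriveSeed(selCfg$seed, b, salt = 6))
        perBootstrap[[b]] <- tp[tp$test_auc >= selCfg$testAUCFloor, , drop = FALSE]
    }
    all <- do.call(rbind, perBootstrap)
    pairs <- if (nrow(all)) {
        agg <- lapply(split(all, all$pair), function(d)
            data.frame(pathway_a = d$pathway_a[1], pathway_b = d$pathway_b[1],
                       frequency = nrow(d),
                       mean_train_auc = mean(d$train_auc),
                       mean_test_auc = mean(d$test_auc)))
        out <- do.call(rbind, agg)
        out <- out[order(-out$frequency, out$pathway_a, out$pathway_b), ]
        rownames(out) <- NULL
        out
    } else {
        data.frame(pathway_a = character(), pathway_b = character(),
                   frequency = integer(), mean_train_auc = numeric(),
                   mean_test_auc = numeric())
    }
    structure(list(pairs = pairs, perBootstrap = perBootstrap,
                   tables = tables, case = case, control = control,
                   config = selCfg),
              class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
    cat("SelectionResult:", nrow(x$pairs), "distinct pathway pairs selected across",
        x$config$nBootstraps, "bootstraps\n")
    if (nrow(x$pairs)) print(utils::head(x$pairs, 10))
    invisible(x)
}

#' Rank individual genes by cross-validated classification AUC
#'
#' Each gene's expression (log2 CPM) is scored with the same
#' cross-validated random-forest AUC used for pathway pairs, and genes are
#' ranked by descending AUC (ties broken by gene name). Used to inspect
#' which single genes of a pathway network carry the class signal.
#'
#' @param dataset an \linkS4class{ExpressionDataset} with exactly two
#'   classes among its samples.
#' @param genes character vector of genes to rank (subset of the measured
#'   genes).
#' @param positive the class scored as positive.
#' @param config a [selectionConfig()].
#' @param topN number of top genes to report (default 10); a request
#'   exceeding the gene count returns them all with a warning.
#' @return data.frame with columns \code{gene}, \code{auc}, best first.
#' @export
geneAUCRanking <- function(dataset, genes, positive,
                           config = selectionConfig(), topN = 10) {
    genes <- unique(genes)
    if (!length(genes)) stop("empty gene set")
    missing <- setdiff(genes, rownames(dataset))
    if (length(missing))
        stop("gene(s) not measured: ", paste(missing, collapse = ", "))
    if (exprScale(dataset) == "counts")
        dataset <- normalizeCPM(dataset)
    if (exprScale(dataset) != "log2")
        dataset <- log2Transform(dataset)
    m <- exprValues(dataset)
    labels <- unname(sampleClasses(dataset))
    auc <- vapply(genes, function(g)
        pairAUC(m[g, ], labels, positive, config,
                seed = deriveSeed(config$seed, match(g, genes), salt = 7)),
        numeric(1))
    out <- data.frame(gene = genes, auc = unname(auc))
    out <- out[order(-out$auc, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    if (topN > nrow(out)) {
        warning("requested top ", topN, " of ", nrow(out), " genes; returning all")
        topN <- nrow(out)
    }
    out[seq_len(topN), , drop = FALSE]
}
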