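# Small forests keep the randomized blocks quick; AUC recovery at these
# sample sizes does not depend on the forest being large.
fastCfg <- function(...) selectionConfig(nTrees = 60, ...)

test_that("the balanced split downsamples to the minority and divides 60/40", {
    labels <- setNames(rep(c("case", "control"), c(100, 40)),
                       sprintf("s%03d", 1:140))
    cfg <- fastCfg(seed = 5)
    sp <- mcSplit(labels, cfg, 1)
    expect_length(c(sp$train, sp$test), 80)
    expect_equal(as.vector(table(labels[sp$train])[c("case", "control")]),
                 c(24L, 24L))
    expect_equal(as.vector(table(labels[sp$test])[c("case", "control")]),
                 c(16L, 16L))
    expect_length(intersect(sp$train, sp$test), 0)

    sp2 <- mcSplit(labels, cfg, 1)
    expect_identical(sp, sp2)
    sp3 <- mcSplit(labels, cfg, 2)
    expect_false(identical(sp, sp3))

    few <- setNames(rep(c("a", "b"), c(4, 30)), sprintf("t%02d", 1:34))
    expect_error(mcSplit(few, cfg, 1), "at least 5")
})

test_that("each sample lands in the training split about 60% of the time", {
    labels <- setNames(rep(c("case", "control"), each = 20),
                       sprintf("s%02d", 1:40))
    cfg <- fastCfg(seed = 9)
    inTrain <- setNames(numeric(40), names(labels))
    for (b in 1:50) {
        sp <- mcSplit(labels, cfg, b)
        inTrain[sp$train] <- inTrain[sp$train] + 1
    }
    freq <- inTrain / 50
    expect_true(all(freq > 0.45 & freq < 0.75))
})

test_that("cross-validated AUC hits the separable, tied and null anchors", {
    cfg <- fastCfg(seed = 2)
    labels <- rep(c("case", "control"), each = 20)
    sep <- c(rnorm(20, 10, 0.1), rnorm(20, 0, 0.1))
    expect_equal(pairAUC(sep, labels, "case", cfg), 1)

    expect_equal(pairAUC(rep(1, 40), labels, "case", cfg), 0.5)

    # null feature: a bigger forest here so the remaining spread is the
    # irreducible sampling noise of a 100 vs 100 null AUC
    aucs <- vapply(1:20, function(s) {
        set.seed(s)
        pairAUC(rnorm(200), rep(c("case", "control"), each = 100), "case",
                selectionConfig(nTrees = 200), seed = s)
    }, numeric(1))
    expect_true(all(abs(aucs - 0.5) < 0.1))
})

test_that("pairAUC rejects degenerate label inputs", {
    cfg <- fastCfg()
    expect_error(pairAUC(rnorm(10), rep("one", 10), "one", cfg), "two classes")
    expect_error(pairAUC(rnorm(12), rep(c("a", "b"), c(6, 6)), "a",
                         fastCfg(cvFolds = 10)), "cvFolds")
    expect_error(pairAUC(rnorm(40), rep(c("a", "b"), 20), "zz", cfg), "zz")
})

test_that("a planted separating pair outranks noise pairs", {
    labels <- rep(c("case", "control"), each = 15)
    wins <- 0
    for (s in 1:5) {
        set.seed(s)
        noise <- matrix(rnorm(30 * 30), 30, dimnames = list(
            sprintf("s%02d", 1:30),
            paste0("N", sprintf("%02da", 1:30), "|N", sprintf("%02db", 1:30))))
        signal <- ifelse(labels == "case", 2, -2) + rnorm(30, 0, 0.3)
        sc <- cbind(noise, `Psig|Pzig` = signal)
        dm <- new("DSMatrix", scores = sc, labels = labels)
        tp <- topPairs(dm, positive = "case", config = fastCfg(cvFolds = 5),
                       seed = s)
        if (tp$pair[1] == "Psig|Pzig") wins <- wins + 1
    }
    expect_gte(wins, 5 * 0.95 - 1)  # >= 95% of seeds, i.e. all 5 here

    # boundary: exactly topK pairs available -> all returned
    dm2 <- new("DSMatrix", scores = sc[, 1:3], labels = labels)
    tp2 <- topPairs(dm2, positive = "case", config = fastCfg(topK = 3, cvFolds = 5))
    expect_equal(nrow(tp2), 3)
})

test_that("AUC ties are broken by the canonical pair name", {
    labels <- rep(c("case", "control"), each = 15)
    set.seed(8)
    f <- rnorm(30)
    sc <- cbind(`B|C` = f, `A|B` = f)  # identical feature, identical AUC
    rownames(sc) <- sprintf("s%02d", 1:30)
    dm <- new("DSMatrix", scores = sc, labels = labels)
    tp <- topPairs(dm, positive = "case", config = fastCfg(cvFolds = 5))
    expect_identical(tp$pair, c("A|B", "B|C"))
})

test_that("Monte Carlo selection is deterministic and bounded", {
    cfg <- simulationConfig(perturbed = c(P001 = 1.5, P002 = 2.5, P003 = 3.5),
                            seed = 21)
    gs <- makePathways(cfg)
    ds <- makeExpression(cfg, gs)
    col <- intersectCollection(gs, rownames(ds))
    selCfg <- fastCfg(nBootstraps = 2, topK = 10, seed = 21)
    s1 <- runMonteCarlo(ds, col, selCfg = selCfg)
    s2 <- runMonteCarlo(ds, col, selCfg = selCfg)
    expect_identical(s1$pairs, s2$pairs)
    expect_lte(sum(vapply(s1$perBootstrap, nrow, integer(1))), 2 * 10)
    expect_true(all(s1$pairs$frequency <= 2))
})

test_that("strongly planted cross-talking pairs are selected in most bootstraps", {
    cfg <- simulationConfig(perturbed = c(P001 = 1.5, P002 = 2.5, P003 = 3.5),
                            seed = 33)
    gs <- makePathways(cfg)
    ds <- makeExpression(cfg, gs)
    col <- intersectCollection(gs, rownames(ds))
    nBoot <- 5
    sel <- runMonteCarlo(ds, col, selCfg = fastCfg(nBootstraps = nBoot, seed = 33))
    planted <- c("P001|P002", "P001|P003", "P002|P003")
    freq <- setNames(sel$pairs$frequency,
                     paste(sel$pairs$pathway_a, sel$pairs$pathway_b, sep = "|"))
    expect_true(all(planted %in% names(freq)))
    expect_true(all(freq[planted] >= 0.8 * nBoot))
})

test_that("gene ranking finds a separable gene and stays near 0.5 on null data", {
    cfg <- simulationConfig(nPathways = 3, genesPerPathway = 5, nBackground = 0,
                            nCase = 200, nControl = 200,
                            perturbed = numeric(), noiseSD = 0.3, seed = 44)
    gs <- makePathways(cfg)
    ds <- makeExpression(cfg, gs)
    m <- exprValues(ds)
    lab <- sampleClasses(ds)
    # plant a cleanly separated gene
    m["G00001", ] <- ifelse(lab == "case", 2^12, 2^2)
    ds2 <- ExpressionDataset(m, lab, scale = "log2")
    rk <- geneAUCRanking(ds2, rownames(m)[1:10], positive = "case",
                         config = selectionConfig(nTrees = 200, seed = 44))
    expect_identical(rk$gene[1], "G00001")
    expect_equal(rk$auc[1], 1)

    # null genes: AUC within 0.5 +/- 0.12
    expect_true(all(abs(rk$auc[-1] - 0.5) < 0.12))

    expect_warning(rk5 <- geneAUCRanking(ds2, rownames(m)[1:5], "case",
                                         fastCfg(seed = 44, cvFolds = 5),
                                         topN = 10),
                   "returning all")
    expect_equal(nrow(rk5), 5)
    expect_error(geneAUCRanking(ds2, character(), "case"), "empty gene set")
})
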