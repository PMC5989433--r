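test_that("the network is built from retained pairs with frequency weights", {
    net <- buildNetwork(data.frame(pathway_a = c("A", "B"),
                                   pathway_b = c("B", "C")))
    expect_length(networkNodes(net), 3)
    expect_equal(nrow(networkEdges(net)), 2)

    dup <- buildNetwork(data.frame(pathway_a = c("A", "A"),
                                   pathway_b = c("B", "B")))
    expect_equal(nrow(networkEdges(dup)), 1)
    expect_equal(networkEdges(dup)$weight, 2)

    expect_error(buildNetwork(data.frame(pathway_a = "A", pathway_b = "B",
                                         frequency = 1), minFrequency = 2),
                 "frequency filter")
})

test_that("network efficiency hits its closed-form anchors", {
    expect_equal(networkEfficiency(completeNetwork(4))$NE, 1)
    path <- PathwayNetwork(edges = data.frame(pathway_a = c("A", "B"),
                                              pathway_b = c("B", "C")))
    expect_equal(networkEfficiency(path)$NE, 5 / 6)
    edgeless <- PathwayNetwork(nodes = c("A", "B", "C"))
    expect_equal(networkEfficiency(edgeless)$NE, 0)
    expect_equal(networkEfficiency(PathwayNetwork(nodes = "A"))$NE, 0)
    expect_equal(networkEfficiency(PathwayNetwork())$NE, 0)
})

test_that("efficiency agrees with the Floyd-Warshall oracle on random graphs", {
    for (s in 1:50) {
        n <- 2 + (s %% 11)   # N in 2..12
        net <- randomNetwork(n, p = 0.15 + 0.6 * (s %% 5) / 5, seed = s)
        expect_equal(networkEfficiency(net)$NE,
                     bruteNE(networkNodes(net), networkEdges(net)),
                     tolerance = 1e-12)
    }
    # ordered-pair symmetry: doubling the unordered sum equals the ordered sum
    net <- randomNetwork(9, 0.4, seed = 99)
    d <- igraph::distances(pciNet:::asIgraph(net))
    inv <- 1 / d; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
    expect_equal(2 * sum(inv[upper.tri(inv)]), sum(inv))
    # cross-check against igraph's own global efficiency
    expect_equal(networkEfficiency(net)$NE,
                 igraph::global_efficiency(pciNet:::asIgraph(net)))
})

test_that("node-deletion inhibition can both lower and raise efficiency", {
    star <- starNetwork()
    NE <- networkEfficiency(star)$NE
    expect_equal(NE, 3 / 4)
    hub <- networkEfficiency(inhibit(star, "h"))
    expect_equal(hub$NE, 0)           # three isolated leaves
    expect_equal(hub$N, 3)
    leaf <- networkEfficiency(inhibit(star, "a"))
    expect_equal(leaf$NE, 5 / 6)      # star on 3 nodes
    expect_gt(leaf$NE, NE)            # nNE > NE is possible
    expect_lt(hub$NE, NE)             # and nNE < NE too

    all4 <- inhibit(star, c("h", "a", "b", "c"))
    expect_length(networkNodes(all4), 0)
    expect_equal(networkEfficiency(all4)$NE, 0)
    expect_error(inhibit(star, "zz"), "zz")
})

test_that("edge-isolation mode keeps the node and never raises efficiency", {
    star <- starNetwork()
    NE <- networkEfficiency(star)$NE
    iso <- inhibit(star, "a", mode = "isolate")
    expect_length(networkNodes(iso), 4)
    expect_lte(networkEfficiency(iso)$NE, NE)
})

test_that("PCI reproduces the printed table arithmetic", {
    expect_equal(round(pci(0.3218, 0.3194), 2), 0.75)
    expect_equal(round(pci(0.3272, 0.327093), 2), 0.03)
    expect_equal(round(pci(0.3445, 0.3241), 1), 5.9)
    expect_equal(round(pci(0.3445, 0.3429), 2), 0.46)
    expect_equal(pci(0.4, 0.4), 0)
    expect_equal(pci(0.4, 0), 100)
    expect_lt(pci(3 / 4, 5 / 6), 0)   # star leaf case: negative PCI
    expect_error(pci(0, 0.1), "undefined")
    # EfficiencyResult inputs are accepted too
    k4 <- completeNetwork(4)
    expect_equal(pci(networkEfficiency(k4), networkEfficiency(inhibit(k4, "N01"))), 0)
})

test_that("single-node scans match brute-force recomputation", {
    star <- starNetwork()
    sc <- scanSingles(star)
    expect_equal(sc$inhibited[1], "h")   # hub has minimal nNE
    expect_equal(sc$nNE[1], 0)

    k5 <- completeNetwork(5)
    sck <- scanSingles(k5)
    expect_equal(sck$nNE, rep(1, 5))
    expect_equal(sck$PCI, rep(0, 5))

    for (s in 1:10) {
        net <- randomNetwork(8, 0.35, seed = 200 + s)
        sc <- scanSingles(net)
        for (i in seq_len(nrow(sc))) {
            v <- sc$inhibited[i]
            rest <- setdiff(networkNodes(net), v)
            e <- networkEdges(net)
            e <- e[e$pathway_a != v & e$pathway_b != v, , drop = FALSE]
            expect_equal(sc$nNE[i], bruteNE(rest, e), tolerance = 1e-12)
        }
    }
})

test_that("pair scans enumerate all unordered pairs", {
    expect_equal(nrow(scanPairs(completeNetwork(4))), 6)
    expect_equal(nrow(scanPairs(ringNetwork(10))), 45)
    # nested-subset consistency: pair result equals recomputation from scratch
    net <- randomNetwork(7, 0.5, seed = 3)
    sp <- scanPairs(net)
    pick <- strsplit(sp$inhibited[1], ";")[[1]]
    expect_equal(sp$nNE[1],
                 networkEfficiency(inhibit(net, pick))$NE)
})

test_that("the DTPN keeps exactly the nodes whose removal lowers efficiency", {
    star <- starNetwork()
    dtpn <- buildDTPN(star)
    expect_identical(networkNodes(dtpn), "h")

    expect_warning(empty <- buildDTPN(completeNetwork(4)), "empty")
    expect_length(networkNodes(empty), 0)

    for (s in 1:5) {
        net <- randomNetwork(9, 0.3, seed = 300 + s)
        singles <- scanSingles(net)
        NE <- networkEfficiency(net)$NE
        expected <- sort(singles$inhibited[singles$nNE < NE])
        if (length(expected)) {
            dtpn <- buildDTPN(net, singles)
            expect_identical(networkNodes(dtpn), expected)
            e <- networkEdges(dtpn)
            expect_true(all(c(e$pathway_a, e$pathway_b) %in% expected))
        }
    }
})

test_that("drugs are associated through target enrichment inside the DTPN only", {
    u <- sprintf("g%03d", 1:100)
    sets <- list(hit = u[1:10], other = u[11:30], outside = u[31:40])
    gs <- GeneSetCollection(sets)
    net <- PathwayNetwork(edges = data.frame(
        pathway_a = c("hit", "hit"), pathway_b = c("other", "outside")))
    dtpn <- PathwayNetwork(nodes = c("hit", "other"),
                           edges = data.frame(pathway_a = "hit",
                                              pathway_b = "other"))
    drugs <- DrugTargetMap(list(
        focused = u[1:5],          # 5/5 targets inside the 10-gene pathway
        diffuse = u[seq(5, 95, by = 10)],  # spread across the universe
        offnet = u[31:35]))        # enriched only in a non-DTPN pathway
    assoc <- mapDrugs(drugs, dtpn, gs, u)
    names(assoc) <- vapply(assoc, `[[`, "", "drug")

    expect_identical(assoc$focused$pathways, "hit")
    expect_equal(unname(assoc$focused$pvalues["hit"]),
                 bruteHyperTail(5, 10, 5, 100), tolerance = 1e-10)
    expect_length(assoc$diffuse$pathways, 0)
    expect_length(assoc$offnet$pathways, 0)  # DTPN scoping rule

    noTargets <- DrugTargetMap(list(ghost = "not_measured"))
    expect_warning(a <- mapDrugs(noTargets, dtpn, gs, u), "ghost")
    expect_length(a[[1]]$pathways, 0)
})

test_that("drug combinations enumerate every nonempty pathway subset", {
    net <- randomNetwork(8, 0.5, seed = 17)
    nodes <- networkNodes(net)
    a2 <- structure(list(drug = "d2", pathways = nodes[1:2],
                         pvalues = c(0.001, 0.002)),
                    class = "DrugPathwayAssociation")
    expect_equal(nrow(drugCombinationPCI(net, a2)), 3)
    a4 <- structure(list(drug = "d4", pathways = nodes[1:4],
                         pvalues = rep(0.001, 4)),
                    class = "DrugPathwayAssociation")
    tab <- drugCombinationPCI(net, a4)
    expect_equal(nrow(tab), 15)
    full <- tab[tab$n_inhibited == 4, ]
    expect_equal(full$nNE, networkEfficiency(inhibit(net, nodes[1:4]))$NE)
    expect_error(drugCombinationPCI(net, a4, maxSubset = 3), "maxSubset")
    a0 <- structure(list(drug = "d0", pathways = character(),
                         pvalues = numeric()), class = "DrugPathwayAssociation")
    expect_equal(nrow(drugCombinationPCI(net, a0)), 0)
})
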