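#' Configuration of a full pipeline run
#'
#' Bundles the input paths, the stage configurations and the output
#' directory for [runPipeline()]. The master \code{seed} overrides the
#' seed inside \code{selCfg} so one number controls every source of
#' randomness in the run.
#'
#' @param expressionPath,labelsPath,gmtPath input files (see
#'   [readExpression()] and [readGMT()]).
#' @param drugPath optional drug-target TSV; NULL skips the drug stages.
#' @param case,control class names in the label file.
#' @param deaCfg a [deaConfig()].
#' @param selCfg a [selectionConfig()].
#' @param minFrequency minimum bootstrap selection frequency for a network
#'   edge (default 1, i.e. the union of validated pairs).
#' @param inhibitionMode \code{"delete"} or \code{"isolate"}, see
#'   [inhibit()].
#' @param maxSubset drug-combination enumeration cap, see
#'   [drugCombinationPCI()].
#' @param outputDir directory for the run artifacts (created if needed).
#' @param seed master seed.
#' @return an object of class \code{RunConfig}.
#' @export
runConfig <- function(expressionPath, labelsPath, gmtPath, drugPath = NULL,
                      case = "case", control = "control",
                      deaCfg = deaConfig(), selCfg = selectionConfig(),
                      minFrequency = 1, inhibitionMode = c("delete", "isolate"),
                      maxSubset = 6, outputDir = "pciNet-run", seed = 1) {
    inhibitionMode <- match.arg(inhibitionMode)
    for (p in c(expressionPath, labelsPath, gmtPath, drugPath))
        if (!file.exists(p)) stop("input file does not exist: ", p)
    selCfg$seed <- as.integer(seed)
    structure(list(expressionPath = expressionPath, labelsPath = labelsPath,
                   gmtPath = gmtPath, drugPath = drugPath, case = case,
                   control = control, deaCfg = deaCfg, selCfg = selCfg,
                   minFrequency = minFrequency,
                   inhibitionMode = inhibitionMode, maxSubset = maxSubset,
                   outputDir = outputDir, seed = as.integer(seed)),
              class = "RunConfig")
}

writeTSV <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the seven-step pipeline end to end
#'
#' Reads the inputs, runs Monte Carlo pathway-pair selection, builds the
#' cross-talk network, scans single and pairwise inhibitions, derives the
#' DTPN and (when a drug table is given) the drug association and
#' combination tables, writing every stage's artifact under the output
#' directory:
#' \code{bootstrap_degs/}, \code{bootstrap_enrichment/},
#' \code{selection.tsv}, \code{network_edges.tsv},
#' \code{inhibition_singles.tsv}, \code{inhibition_pairs.tsv},
#' \code{dtpn_edges.tsv}, \code{drug_report.tsv} and a machine-readable
#' \code{summary.json}. Runs are idempotent: the same seed yields
#' byte-identical artifacts. Any stage failure aborts with the stage name.
#'
#' @param config a [runConfig()].
#' @return invisibly, the summary list that was written to
#'   \code{summary.json}.
#' @export
runPipeline <- function(config) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$outputDir, ...)

    dataset <- withStage("read_expression",
        readExpression(config$expressionPath, config$labelsPath))
    collection <- withStage("read_gmt", readGMT(config$gmtPath))
    collection <- withStage("intersect_collection",
        intersectCollection(collection, rownames(dataset)))
    drugs <- if (!is.null(config$drugPath))
        withStage("read_drug_targets", readDrugTargets(config$drugPath)) else NULL

    sel <- withStage("monte_carlo_selection",
        runMonteCarlo(dataset, collection, config$case, config$control,
                      config$deaCfg, config$selCfg, keepTables = TRUE))
    dir.create(out("bootstrap_degs"), showWarnings = FALSE)
    dir.create(out("bootstrap_enrichment"), showWarnings = FALSE)
    for (b in seq_along(sel$tables)) {
        writeTSV(sel$tables[[b]]$deg,
                 out("bootstrap_degs", sprintf("degs_b%03d.tsv", b)))
        writeTSV(sel$tables[[b]]$enrichment,
                 out("bootstrap_enrichment", sprintf("enrichment_b%03d.tsv", b)))
    }
    writeTSV(sel$pairs, out("selection.tsv"))
    if (!nrow(sel$pairs))
        stop("[stage: monte_carlo_selection] no validated pathway pair in any bootstrap")

    network <- withStage("build_network", buildNetwork(sel, config$minFrequency))
    writeEdgeList(network, out("network_edges.tsv"))
    eff <- networkEfficiency(network)

    singles <- withStage("inhibition_singles",
        scanSingles(network, config$inhibitionMode))
    writeTSV(singles, out("inhibition_singles.tsv"))
    pairsScan <- if (length(networkNodes(network)) >= 3)
        withStage("inhibition_pairs", scanPairs(network, config$inhibitionMode))
    else NULL
    if (!is.null(pairsScan)) writeTSV(pairsScan, out("inhibition_pairs.tsv"))

    dtpn <- withStage("build_dtpn",
        withCallingHandlers(buildDTPN(network, singles),
                            warning = function(w) invokeRestart("muffleWarning")))
    writeEdgeList(dtpn, out("dtpn_edges.tsv"))

    drugReport <- NULL
    if (!is.null(drugs) && length(networkNodes(dtpn))) {
        assoc <- withStage("map_drugs",
            suppressWarnings(mapDrugs(drugs, dtpn, collection, rownames(dataset))))
        drugReport <- do.call(rbind, lapply(assoc, function(a)
            drugCombinationPCI(network, a, config$maxSubset,
                               config$inhibitionMode)))
        if (is.null(drugReport) || !nrow(drugReport))
            drugReport <- data.frame(drug = character(), inhibited = character(),
                                     n_inhibited = integer(),
                                     n_remaining = integer(),
                                     nNE = numeric(), PCI = numeric())
        writeTSV(drugReport, out("drug_report.tsv"))
    }

    bestPerDrug <- if (!is.null(drugReport) && nrow(drugReport)) {
        lapply(split(drugReport, drugReport$drug), function(d) {
            best <- d[which.max(d$PCI), ]
            list(pathway_set = best$inhibited, nNE = best$nNE, PCI = best$PCI)
        })
    } else NULL

    summary <- list(
        package_version = as.character(packageVersion("pciNet")),
        seed = config$seed,
        inhibition_mode = config$inhibitionMode,
        n_samples = ncol(dataset),
        n_genes = nrow(dataset),
        n_pathways_tested = length(collection),
        n_network_nodes = length(networkNodes(network)),
        n_network_edges = nrow(networkEdges(network)),
        NE = eff$NE,
        dtpn_nodes = networkNodes(dtpn),
        dtpn_empty = length(networkNodes(dtpn)) == 0,
        top_single_inhibitions = utils::head(singles, 10),
        top_pair_inhibitions = if (!is.null(pairsScan)) utils::head(pairsScan, 10),
        best_subset_per_drug = bestPerDrug)
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, dataframe = "rows")
    invisible(summary)
}
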