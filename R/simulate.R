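#' Configuration for the synthetic study generator
#'
#' Describes a synthetic two-class expression study with planted
#' differentially expressed pathways. Defaults emulate a modest subtype
#' study: 30 case vs 30 control samples, 55 disjoint 20-gene pathways of
#' which the first five are perturbed in the case class with distinct log2
#' effect sizes (1.5 to 2.7) -- distinct, because the discriminating score
#' of a pathway pair cancels a shift common to both pathways -- plus 100
#' background genes in no pathway, log2-scale noise sd 0.5, and 13 drugs
#' whose targets are drawn from one pathway each.
#'
#' @param nCase,nControl sample counts per class (default 30 each).
#' @param nPathways number of pathways (default 55).
#' @param genesPerPathway genes per pathway (default 20).
#' @param overlapFraction fraction of genes shared by adjacent pathways,
#'   in \[0, 1) (default 0).
#' @param nBackground extra genes belonging to no pathway (default 100).
#' @param nGenes optional explicit total gene count; NULL derives it from
#'   the pathway layout plus \code{nBackground}.
#' @param perturbed named numeric vector: pathway name -> log2 effect
#'   added to that pathway's genes in case samples.
#' @param noiseSD per-observation Gaussian noise sd on the log2 scale
#'   (default 0.5).
#' @param baselineMean,baselineSD distribution of per-gene baseline log2
#'   means (defaults 5 and 2).
#' @param drugs named list: drug -> list(pathway =, fraction =,
#'   nOffTarget =); NULL builds the default 13-drug panel with the first
#'   five drugs targeting the perturbed pathways (fraction 0.8).
#' @param seed master seed for the generator.
#' @return an object of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nCase = 30, nControl = 30, nPathways = 55,
                             genesPerPathway = 20, overlapFraction = 0,
                             nBackground = 100, nGenes = NULL,
                             perturbed = NULL, noiseSD = 0.5,
                             baselineMean = 5, baselineSD = 2,
                             drugs = NULL, seed = 1) {
    stopifnot(nCase > 0, nControl > 0, nPathways > 0, genesPerPathway >= 2,
              overlapFraction >= 0, overlapFraction < 1, noiseSD >= 0,
              nBackground >= 0)
    pnames <- sprintf("P%03d", seq_len(nPathways))
    if (is.null(perturbed)) {
        k <- min(5, nPathways)
        perturbed <- setNames(seq(1.5, by = 0.3, length.out = k), pnames[seq_len(k)])
    }
    if (!all(names(perturbed) %in% pnames))
        stop("perturbed names must reference existing pathways: ",
             paste(setdiff(names(perturbed), pnames), collapse = ", "))
    if (any(!is.finite(perturbed))) stop("effect sizes must be finite")
    if (is.null(drugs)) {
        dnames <- sprintf("Drug%02d", 1:13)
        drugs <- setNames(lapply(seq_along(dnames), function(i)
            list(pathway = pnames[(i - 1) %% nPathways + 1],
                 fraction = 0.8, nOffTarget = 0)), dnames)
    }
    for (dr in names(drugs)) {
        sp <- drugs[[dr]]
        if (!sp$pathway %in% pnames)
            stop("drug '", dr, "' targets unknown pathway ", sp$pathway)
        if (sp$fraction > 1 || sp$fraction <= 0)
            stop("drug '", dr, "': target fraction must be in (0, 1]")
    }
    structure(list(nCase = nCase, nControl = nControl, nPathways = nPathways,
                   genesPerPathway = genesPerPathway,
                   overlapFraction = overlapFraction,
                   nBackground = nBackground, nGenes = nGenes,
                   perturbed = perturbed, noiseSD = noiseSD,
                   baselineMean = baselineMean, baselineSD = baselineSD,
                   drugs = drugs, seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Generate a pathway collection with controlled overlap
#'
#' Pathways P001, P002, ... are laid out over a synthetic gene universe so
#' that adjacent pathways share \code{round(overlapFraction *
#' genesPerPathway)} genes; background genes belong to no pathway.
#'
#' @param config a [simulationConfig()].
#' @return a \linkS4class{GeneSetCollection}.
#' @examples
#' gs <- makePathways(simulationConfig(nPathways = 10, overlapFraction = 0.5))
#' length(intersect(gs[["P001"]], gs[["P002"]]))
#' @export
makePathways <- function(config) {
    gpp <- config$genesPerPathway
    ov <- round(config$overlapFraction * gpp)
    step <- gpp - ov
    needed <- step * config$nPathways + ov
    if (!is.null(config$nGenes) && config$nGenes < needed + config$nBackground)
        stop("nGenes = ", config$nGenes, " cannot host ", config$nPathways,
             " pathways of ", gpp, " genes at overlap ", config$overlapFraction,
             " plus ", config$nBackground, " background genes (need ",
             needed + config$nBackground, ")")
    total <- if (is.null(config$nGenes)) needed + config$nBackground else config$nGenes
    genes <- sprintf("G%05d", seq_len(total))
    sets <- lapply(seq_len(config$nPathways), function(i)
        genes[((i - 1) * step + 1):((i - 1) * step + gpp)])
    names(sets) <- sprintf("P%03d", seq_len(config$nPathways))
    GeneSetCollection(sets, provenance = "synthetic")
}

#' Generate a labelled expression dataset with planted pathway effects
#'
#' Per-gene baseline log2 means are drawn once; every observation gets
#' Gaussian log2 noise; case samples additionally receive each perturbed
#' pathway's log2 effect on that pathway's genes (a gene in several
#' perturbed pathways gets the largest applicable effect). Log2 values
#' are exponentiated to positive pseudo-counts, so the returned dataset
#' is on the counts scale. Deterministic given the config seed.
#'
#' @param config a [simulationConfig()].
#' @param collection the matching [makePathways()] collection.
#' @return an \linkS4class{ExpressionDataset} with classes \code{"case"}
#'   and \code{"control"}.
#' @export
makeExpression <- function(config, collection) {
    sets <- geneSets(collection)
    pathwayGenes <- unique(unlist(sets))
    total <- if (is.null(config$nGenes)) length(pathwayGenes) + config$nBackground
             else config$nGenes
    genes <- union(pathwayGenes, sprintf("G%05d", seq_len(total)))
    nG <- length(genes)
    n <- config$nCase + config$nControl
    samples <- sprintf("S%03d", seq_len(n))
    labels <- setNames(rep(c("case", "control"), c(config$nCase, config$nControl)),
                       samples)

    set.seed(deriveSeed(config$seed, 1, salt = 11))
    baseline <- rnorm(nG, config$baselineMean, config$baselineSD)
    log2m <- baseline + matrix(rnorm(nG * n, 0, config$noiseSD), nG, n)
    dimnames(log2m) <- list(genes, samples)

    if (length(config$perturbed)) {
        shift <- setNames(numeric(nG), genes)
        for (p in names(config$perturbed)) {
            g <- sets[[p]]
            shift[g] <- pmax(shift[g], config$perturbed[[p]])
        }
        log2m[, labels == "case"] <- log2m[, labels == "case"] + shift
    }
    ExpressionDataset(2^log2m, labels, scale = "counts")
}

#' Generate a drug-target table hitting chosen pathways
#'
#' Each drug's targets are a random sample of its pathway's genes at the
#' configured fraction, plus optional off-target genes drawn from outside
#' the pathway. Deterministic given the config seed.
#'
#' @param config a [simulationConfig()].
#' @param collection the matching [makePathways()] collection.
#' @return a \linkS4class{DrugTargetMap}.
#' @export
makeDrugTargets <- function(config, collection) {
    sets <- geneSets(collection)
    allGenes <- unique(unlist(sets))
    set.seed(deriveSeed(config$seed, 2, salt = 12))
    targets <- lapply(names(config$drugs), function(dr) {
        sp <- config$drugs[[dr]]
        pool <- sets[[sp$pathway]]
        hit <- sample(pool, max(1, round(sp$fraction * length(pool))))
        off <- if (sp$nOffTarget > 0)
            sample(setdiff(allGenes, pool), sp$nOffTarget) else character()
        c(hit, off)
    })
    names(targets) <- names(config$drugs)
    DrugTargetMap(targets)
}

#' Write a complete synthetic fixture directory
#'
#' Generates pathways, expression and drug targets and writes them in the
#' exact formats the readers consume (expression + labels TSV, GMT, drug
#' TSV), together with a \code{manifest.json} recording every ground-truth
#' parameter.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written file paths.
#' @export
simulateFixtures <- function(config, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gs <- makePathways(config)
    ds <- makeExpression(config, gs)
    dt <- makeDrugTargets(config, gs)
    paths <- list(expression = file.path(dir, "expression.tsv"),
                  labels = file.path(dir, "labels.tsv"),
                  gmt = file.path(dir, "pathways.gmt"),
                  drugs = file.path(dir, "drugs.tsv"),
                  manifest = file.path(dir, "manifest.json"))
    writeExpression(ds, paths$expression, paths$labels)
    writeGMT(gs, paths$gmt)
    writeDrugTargets(dt, paths$drugs)
    manifest <- config
    class(manifest) <- NULL
    manifest$perturbed <- as.list(manifest$perturbed)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(paths)
}
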