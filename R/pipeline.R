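#' @include AllGenerics.R
NULL

#' Assemble a pipeline configuration
#'
#' Bundles input paths and stage parameters for [runPipeline()]. All
#' thresholds default to the reference protocol: 1% DEG FDR, score cutoff
#' 0.9, 1000 degree-preserving randomizations, crosstalk and pivot alpha
#' 0.05, pivot minimum of strictly more than 2 in-module targets, and
#' enrichment FDR 0.05.
#'
#' @param expressionPaths named list (\code{inflammation}, \code{cancer})
#'   of lists; each dataset entry is
#'   \code{list(exprs = <path>, labels = <path>, id = <dataset id>)}.
#' @param edgeTablePath scored interaction TSV.
#' @param regulatorPath 3-column (regulator, type, target) TSV; \code{NULL}
#'   skips the pivot stage.
#' @param gmtPath GMT annotation file; \code{NULL} skips enrichment.
#' @param outDir output directory (created if needed).
#' @param fdrTarget,scoreCutoff,mcode,nRandom,swapsPerEdge,crosstalkAlpha
#'   stage parameters (see the stage functions).
#' @param pivotMinTargets,pivotAlpha,enrichmentFdr,nPermutations stage
#'   parameters.
#' @param rngSeed global seed; per-stage streams are derived from it.
#' @return a validated configuration list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(expressionPaths, edgeTablePath,
                           regulatorPath = NULL, gmtPath = NULL,
                           outDir = "pipeline-out",
                           fdrTarget = 0.01, scoreCutoff = 0.9,
                           mcode = MCODEParams(), nRandom = 1000L,
                           swapsPerEdge = 10L, crosstalkAlpha = 0.05,
                           pivotMinTargets = 3L, pivotAlpha = 0.05,
                           enrichmentFdr = 0.05, nPermutations = 100L,
                           rngSeed = 1L) {
    alphas <- c(fdrTarget = fdrTarget, crosstalkAlpha = crosstalkAlpha,
                pivotAlpha = pivotAlpha, enrichmentFdr = enrichmentFdr)
    if (any(alphas <= 0 | alphas >= 1))
        stop("all significance levels must lie in (0, 1)")
    if (!all(c("inflammation", "cancer") %in% names(expressionPaths)))
        stop("expressionPaths needs entries 'inflammation' and 'cancer'")
    structure(list(
        expressionPaths = expressionPaths, edgeTablePath = edgeTablePath,
        regulatorPath = regulatorPath, gmtPath = gmtPath, outDir = outDir,
        fdrTarget = fdrTarget, scoreCutoff = scoreCutoff, mcode = mcode,
        nRandom = as.integer(nRandom),
        swapsPerEdge = as.integer(swapsPerEdge),
        crosstalkAlpha = crosstalkAlpha,
        pivotMinTargets = as.integer(pivotMinTargets),
        pivotAlpha = pivotAlpha, enrichmentFdr = enrichmentFdr,
        nPermutations = as.integer(nPermutations),
        rngSeed = as.integer(rngSeed)), class = "PipelineConfig")
}

.configInputFiles <- function(config) {
    files <- config$edgeTablePath
    for (ctx in names(config$expressionPaths))
        for (ds in config$expressionPaths[[ctx]])
            files <- c(files, ds$exprs, ds$labels)
    c(files, config$regulatorPath, config$gmtPath)
}

#' Run the full module-crosstalk pipeline
#'
#' Executes, in order and for both contexts: per-dataset DEG calling,
#' cross-dataset integration, interactome filtering, DEG mapping, maximal
#' connected component extraction, MCODE-style module detection, crosstalk
#' permutation testing, pivot-regulator identification (when a regulator
#' map is configured) and gene-set enrichment of every module (when a GMT
#' is configured). Every intermediate artifact is written under
#' \code{outDir}, and a JSON manifest recording input checksums,
#' parameters, seed and output checksums is written last. Identical
#' configurations with identical seeds produce identical artifacts.
#'
#' @param config a configuration from [pipelineConfig()].
#' @return the manifest, invisibly (a list).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    inputs <- .configInputFiles(config)
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(config$outDir, ...)
    artifacts <- character()
    seed <- config$rngSeed

    # --- differential expression ---------------------------------------
    integrated <- list()
    degSeedOffset <- 0L
    for (ctx in c("inflammation", "cancer")) {
        tables <- list()
        for (ds in config$expressionPaths[[ctx]]) {
            dat <- readExpression(ds$exprs, ds$labels, ds$id)
            degSeedOffset <- degSeedOffset + 1L
            tab <- callDEGs(dat, fdrTarget = config$fdrTarget,
                            nPermutations = config$nPermutations,
                            rngSeed = seed + 100L + degSeedOffset)
            tables[[ds$id]] <- tab
            p <- out(sprintf("degs_%s.tsv", ds$id))
            writeDEGTable(tab, p, ds$id)
            artifacts <- c(artifacts, p)
        }
        integrated[[ctx]] <- integrateDEGs(tables, ctx)
        p <- out(sprintf("integrated_degs_%s.tsv", ctx))
        writeIntegratedDEGs(integrated[[ctx]], p)
        artifacts <- c(artifacts, p)
    }

    # --- interactome and modules ---------------------------------------
    net <- readInteractions(config$edgeTablePath, config$scoreCutoff)
    modules <- list()
    for (ctx in c("inflammation", "cancer")) {
        sub <- mapDEGs(net, integrated[[ctx]])
        mcc <- maximalConnectedComponent(sub)
        mods <- mcodeComplexes(mcc, config$mcode, ctx)
        modules[[ctx]] <- mods
        p <- out(sprintf("modules_%s.tsv", ctx))
        writeModules(mods, p)
        artifacts <- c(artifacts, p)
        p <- out(sprintf("mcc_%s.sif", ctx))
        writeSIF(mcc, p)
        artifacts <- c(artifacts, p)
    }

    # --- crosstalk ------------------------------------------------------
    crosstalk <- crosstalkTest(net, modules$inflammation, modules$cancer,
                               nRandom = config$nRandom,
                               rngSeed = seed + 500L,
                               swapsPerEdge = config$swapsPerEdge,
                               alpha = config$crosstalkAlpha)
    p <- out("crosstalk.tsv")
    writeCrosstalkTable(crosstalk, p)
    artifacts <- c(artifacts, p)
    sigNet <- significantCrosstalkNetwork(net, crosstalk,
                                          c(modules$inflammation,
                                            modules$cancer))
    p <- out("crosstalk_significant.graphml")
    writeGraphML(sigNet, p)
    artifacts <- c(artifacts, p)

    # --- pivots ---------------------------------------------------------
    pivots <- NULL
    if (!is.null(config$regulatorPath)) {
        map <- readRegulatorTable(config$regulatorPath)
        pivots <- findPivots(map, crosstalk,
                             c(modules$inflammation, modules$cancer),
                             background = nodeIds(net),
                             minTargets = config$pivotMinTargets,
                             alpha = config$pivotAlpha)
        p <- out("pivots.tsv")
        writePivotTable(pivots, p)
        artifacts <- c(artifacts, p)
    }

    # --- enrichment -----------------------------------------------------
    if (!is.null(config$gmtPath)) {
        ann <- readGMT(config$gmtPath)
        allMods <- c(modules$inflammation, modules$cancer)
        enr <- do.call(rbind, lapply(allMods, function(m) {
            res <- suppressWarnings(
                enrich(moduleMembers(m), ann, nodeIds(net),
                       config$enrichmentFdr))
            if (nrow(res)) cbind(module = moduleId(m), res) else NULL
        }))
        if (is.null(enr))
            enr <- data.frame(module = character(), term = character())
        p <- out("enrichment.tsv")
        utils::write.table(enr, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        artifacts <- c(artifacts, p)
    }

    # --- manifest -------------------------------------------------------
    sigTab <- resultTable(crosstalk)
    manifest <- list(
        inputs = as.list(setNames(tools::md5sum(inputs),
                                  basename(inputs))),
        parameters = list(
            fdrTarget = config$fdrTarget,
            scoreCutoff = config$scoreCutoff,
            nodeScoreCutoff = config$mcode@nodeScoreCutoff,
            kCoreMin = config$mcode@kCoreMin,
            haircut = config$mcode@haircut,
            fluff = config$mcode@fluff,
            nRandom = config$nRandom,
            swapsPerEdge = config$swapsPerEdge,
            crosstalkAlpha = config$crosstalkAlpha,
            pivotMinTargets = config$pivotMinTargets,
            pivotAlpha = config$pivotAlpha,
            enrichmentFdr = config$enrichmentFdr,
            nPermutations = config$nPermutations),
        rngSeed = config$rngSeed,
        summary = list(
            nIntegratedDEGs = lapply(integrated, function(s)
                length(moduleMembers(s))),
            nModules = lapply(modules, length),
            networkNodes = numNodes(net),
            networkEdges = numEdges(net),
            nSignificantPairs = sum(sigTab$significant),
            nPivots = if (!is.null(pivots))
                length(unique(pivots$regulator[pivots$isPivot])) else NA),
        outputs = as.list(setNames(tools::md5sum(artifacts),
                                   basename(artifacts))))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

#' Merged network of significant crosstalk pairs
#'
#' Induced subgraph on the union of members of all significant pairs,
#' with an edge attribute \code{class}: \code{"common"} for edges whose
#' endpoints are both shared genes of some significant pair,
#' \code{"crosstalk"} for edges crossing between the exclusive members of
#' a significant pair, \code{"intra"} otherwise.
#'
#' @param net the [Interactome-class] the modules live in.
#' @param crosstalk a [CrosstalkResults-class].
#' @param modules list of [GeneModule-class] covering all pair ids.
#' @return an [Interactome-class] with classified edges.
#' @export
significantCrosstalkNetwork <- function(net, crosstalk, modules) {
    tab <- resultTable(crosstalk)
    sig <- tab[tab$significant, , drop = FALSE]
    names(modules) <- vapply(modules, moduleId, "")
    keep <- unique(unlist(lapply(
        unique(c(sig$moduleA, sig$moduleB)),
        function(id) moduleMembers(modules[[id]]))))
    keep <- intersect(keep, nodeIds(net))
    g <- igraph::induced_subgraph(asIgraph(net), keep)
    if (igraph::ecount(g)) {
        el <- igraph::as_edgelist(g)
        cls <- rep("intra", nrow(el))
        for (i in seq_len(nrow(sig))) {
            ma <- moduleMembers(modules[[sig$moduleA[i]]])
            mb <- moduleMembers(modules[[sig$moduleB[i]]])
            sh <- intersect(ma, mb)
            ax <- setdiff(ma, mb); bx <- setdiff(mb, ma)
            cross <- (el[, 1L] %in% ax & el[, 2L] %in% bx) |
                     (el[, 1L] %in% bx & el[, 2L] %in% ax)
            common <- el[, 1L] %in% sh & el[, 2L] %in% sh
            cls[cross & cls == "intra"] <- "crosstalk"
            cls[common] <- "common"
        }
        igraph::E(g)$class <- cls
    }
    Interactome(g, net@scoreCutoff)
}

#' Materialize synthetic data on disk
#'
#' Generates every synthetic artifact for a configuration and writes the
#' files the pipeline stages read: per-dataset expression TSVs and label
#' files, the scored edge table, the regulator table and the truth JSON.
#'
#' @param config a [SyntheticConfig-class].
#' @param outDir output directory (created if needed).
#' @return list with elements \code{pipelineConfig} (ready for
#'   [runPipeline()], minus a GMT) and \code{files} (all written paths).
#' @export
simulateToDir <- function(config, outDir) {
    validObject(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
    syn <- generateSynthetic(config)
    files <- character()
    expressionPaths <- list(inflammation = list(), cancer = list())
    for (id in names(syn$expression)) {
        ctx <- sub("_ds\\d+$", "", id)
        exprPath <- file.path(outDir, paste0(id, "_exprs.tsv"))
        labelPath <- file.path(outDir, paste0(id, "_labels.tsv"))
        writeExpression(syn$expression[[id]], exprPath, labelPath)
        files <- c(files, exprPath, labelPath)
        expressionPaths[[ctx]][[length(expressionPaths[[ctx]]) + 1L]] <-
            list(exprs = exprPath, labels = labelPath, id = id)
    }
    edgePath <- file.path(outDir, "interactome.tsv")
    writeEdgeTable(syn$interactome, edgePath)
    regPath <- file.path(outDir, "regulators.tsv")
    writeRegulatorMap(syn$regulators, regPath)
    truthPath <- file.path(outDir, "truth.json")
    writeTruth(syn$truth, truthPath)
    files <- c(files, edgePath, regPath, truthPath)
    list(pipelineConfig = pipelineConfig(
             expressionPaths = expressionPaths,
             edgeTablePath = edgePath, regulatorPath = regPath,
             outDir = file.path(outDir, "results"),
             rngSeed = config@rngSeed),
         files = files)
}
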