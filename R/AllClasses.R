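#' @import methods
#' @importFrom igraph is_simple is_directed vcount ecount V E gorder gsize
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats setNames
NULL

setOldClass("igraph")

#' Scored undirected interactome
#'
#' Thin S4 wrapper around a simple undirected \pkg{igraph} graph whose edges
#' carry a confidence score in \[0, 1\]. All pipeline stages that operate on
#' networks accept and return this class, so that graph invariants (simple,
#' undirected, named vertices) are checked once at construction.
#'
#' @slot graph an \pkg{igraph} object: simple, undirected, vertices named by
#'   gene symbol, edge attribute \code{score}.
#' @slot scoreCutoff the score cutoff active when the network was filtered;
#'   \code{NA} when no filtering has been applied.
#'
#' @export
setClass("Interactome",
    representation(graph = "igraph", scoreCutoff = "numeric"),
    prototype(scoreCutoff = NA_real_))

setValidity("Interactome", function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (!igraph::is_simple(g))
        msg <- c(msg, "graph must be simple (no loops, no parallel edges)")
    if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
        msg <- c(msg, "vertices must be named")
    if (igraph::ecount(g) > 0) {
        sc <- igraph::E(g)$score
        if (is.null(sc))
            msg <- c(msg, "edges must carry a 'score' attribute")
        else if (anyNA(sc) || any(sc < 0) || any(sc > 1))
            msg <- c(msg, "edge scores must lie in [0, 1]")
        else if (!is.na(object@scoreCutoff) && any(sc < object@scoreCutoff))
            msg <- c(msg, "all edge scores must be >= the active score cutoff")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an Interactome from an igraph graph
#'
#' @param graph a simple undirected \pkg{igraph} graph with named vertices.
#'   A missing \code{score} edge attribute is filled with 1.0.
#' @param scoreCutoff optional score cutoff recorded on the object.
#' @return an [Interactome-class] object.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' net <- Interactome(g)
#' numNodes(net)
#' @export
Interactome <- function(graph, scoreCutoff = NA_real_) {
    if (igraph::ecount(graph) > 0 && is.null(igraph::E(graph)$score))
        igraph::E(graph)$score <- 1.0
    new("Interactome", graph = graph, scoreCutoff = as.numeric(scoreCutoff))
}

#' Expression dataset with two-group design
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one study's
#' log-scale gene-by-sample expression matrix in assay \code{"exprs"},
#' per-sample group labels (\code{"disease"} vs \code{"normal"}) in
#' \code{colData()$group}, and the dataset identifier in the metadata.
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    grp <- SummarizedExperiment::colData(object)$group
    if (is.null(grp)) {
        msg <- c(msg, "colData column 'group' is required")
    } else {
        grp <- as.character(grp)
        if (!all(grp %in% c("disease", "normal")))
            msg <- c(msg, "group labels must be 'disease' or 'normal'")
        if (sum(grp == "disease") < 2 || sum(grp == "normal") < 2)
            msg <- c(msg, "each group needs at least 2 samples")
    }
    if (is.null(rownames(object)) || anyNA(rownames(object)))
        msg <- c(msg, "gene ids (rownames) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (is.null(S4Vectors::metadata(object)$datasetId))
        msg <- c(msg, "metadata 'datasetId' is required")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric genes-by-samples matrix of log-scale expression,
#'   with gene ids as rownames and sample ids as colnames.
#' @param groups character vector (one entry per sample) of labels
#'   \code{"disease"} / \code{"normal"}.
#' @param datasetId identifier of the study the matrix came from.
#' @return an [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rnorm(40), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' eds <- ExpressionDataset(m, rep(c("disease", "normal"), each = 5), "demo")
#' datasetId(eds)
#' @export
ExpressionDataset <- function(values, groups, datasetId) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = as.matrix(values)),
        colData = S4Vectors::DataFrame(group = as.character(groups),
                                       row.names = colnames(values)))
    S4Vectors::metadata(se)$datasetId <- as.character(datasetId)
    as(se, "ExpressionDataset")
}

#' Integrated, direction-consistent DEG set
#'
#' Genes called differentially expressed in at least two datasets of one
#' context with the same direction everywhere (for a context backed by a
#' single comparison, that single comparison is the support).
#'
#' @slot context label of the comparison the set belongs to, e.g.
#'   \code{"inflammation"}, \code{"cancer"} or
#'   \code{"inflammation-vs-cancer"}.
#' @slot direction named character vector, gene id to \code{"up"} /
#'   \code{"down"} (disease relative to normal).
#' @slot support named list, gene id to the dataset ids supporting the call.
#' @export
setClass("IntegratedDEGSet",
    representation(context = "character", direction = "character",
                   support = "list"))

setValidity("IntegratedDEGSet", function(object) {
    msg <- character()
    if (length(object@context) != 1L)
        msg <- c(msg, "context must be a single label")
    if (length(object@direction) &&
        !all(object@direction %in% c("up", "down")))
        msg <- c(msg, "directions must be 'up' or 'down'")
    if (!identical(names(object@direction), names(object@support)))
        msg <- c(msg, "direction and support must name the same genes")
    if (length(msg)) msg else TRUE
})

#' A dense functional module detected in one context's network
#'
#' @slot moduleId identifier, conventionally \code{"<context>_<ordinal>"}.
#' @slot context disease context the module was detected in.
#' @slot members gene ids of the module.
#' @slot seedGene the highest-weight vertex the complex was grown from.
#' @slot score complex score: subgraph density times member count.
#' @export
setClass("GeneModule",
    representation(moduleId = "character", context = "character",
                   members = "character", seedGene = "character",
                   score = "numeric"))

setValidity("GeneModule", function(object) {
    msg <- character()
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (length(object@members) &&
        length(object@seedGene) == 1L &&
        !object@seedGene %in% object@members)
        msg <- c(msg, "seed gene must be a member")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneModule-class
#' @param moduleId,context,members,seedGene,score see slot documentation.
#' @export
GeneModule <- function(moduleId, context, members, seedGene = members[1L],
                       score = NA_real_) {
    new("GeneModule", moduleId = as.character(moduleId),
        context = as.character(context), members = as.character(members),
        seedGene = as.character(seedGene), score = as.numeric(score))
}

#' Parameters of the MCODE-style complex detection
#'
#' Defaults mirror the published defaults of the seeded-growth algorithm:
#' node score cutoff 0.2, haircut on, fluff off, fluff density cutoff 0.2,
#' maximum growth depth 100, and complexes must contain a non-empty 2-core.
#'
#' @slot nodeScoreCutoff fraction in \[0, 1): a neighbor joins a complex when
#'   its weight exceeds (1 - cutoff) times the seed weight.
#' @slot kCoreMin complexes whose k-core of this order is empty are dropped.
#' @slot haircut remove members with fewer than 2 in-complex neighbors.
#' @slot fluff add high-density neighborhoods around the complex.
#' @slot fluffDensityCutoff neighborhood-density threshold used by fluff.
#' @slot maxDepth maximum breadth-first growth depth from the seed.
#' @export
setClass("MCODEParams",
    representation(nodeScoreCutoff = "numeric", kCoreMin = "integer",
                   haircut = "logical", fluff = "logical",
                   fluffDensityCutoff = "numeric", maxDepth = "integer"))

setValidity("MCODEParams", function(object) {
    msg <- character()
    if (object@nodeScoreCutoff < 0 || object@nodeScoreCutoff >= 1)
        msg <- c(msg, "nodeScoreCutoff must lie in [0, 1)")
    if (object@kCoreMin < 2L)
        msg <- c(msg, "kCoreMin must be >= 2")
    if (object@maxDepth < 1L)
        msg <- c(msg, "maxDepth must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname MCODEParams-class
#' @param nodeScoreCutoff,kCoreMin,haircut,fluff,fluffDensityCutoff,maxDepth
#'   see slot documentation.
#' @export
MCODEParams <- function(nodeScoreCutoff = 0.2, kCoreMin = 2L, haircut = TRUE,
                        fluff = FALSE, fluffDensityCutoff = 0.2,
                        maxDepth = 100L) {
    new("MCODEParams", nodeScoreCutoff = as.numeric(nodeScoreCutoff),
        kCoreMin = as.integer(kCoreMin), haircut = isTRUE(haircut),
        fluff = isTRUE(fluff),
        fluffDensityCutoff = as.numeric(fluffDensityCutoff),
        maxDepth = as.integer(maxDepth))
}

#' Crosstalk test results for all module pairs
#'
#' One row of \code{resultTable()} per (context-A module, context-B module)
#' pair, together with the full matrix of null inter-edge counts so the
#' permutation p-value can be re-derived exactly from the stored ensemble.
#'
#' @slot table data.frame with columns \code{moduleA}, \code{moduleB},
#'   \code{observed}, \code{nullMean}, \code{p}, \code{significant},
#'   \code{nSharedGenes}, \code{nSharedEdges}.
#' @slot nullCounts integer matrix, pairs by replicates: inter-edge counts
#'   in each randomized network.
#' @slot sharedGenes,sharedEdges per-pair lists of common genes and of edges
#'   internal to the member intersection.
#' @slot nRandom size of the randomized ensemble.
#' @slot alpha significance level applied to the permutation p-values.
#' @export
setClass("CrosstalkResults",
    representation(table = "data.frame", nullCounts = "matrix",
                   sharedGenes = "list", sharedEdges = "list",
                   nRandom = "integer", alpha = "numeric"))

setValidity("CrosstalkResults", function(object) {
    msg <- character()
    if (nrow(object@table) != nrow(object@nullCounts))
        msg <- c(msg, "one nullCounts row per tested pair is required")
    if (nrow(object@nullCounts) && ncol(object@nullCounts) != object@nRandom)
        msg <- c(msg, "nullCounts must have nRandom columns")
    if (nrow(object@table)) {
        p <- object@table$p
        if (any(p < 0 | p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Regulator-to-target map for TFs and miRNAs
#'
#' @slot targets named list: regulator id to character vector of target
#'   gene ids (non-empty, unique within a regulator).
#' @slot type named character: regulator id to \code{"TF"} or
#'   \code{"miRNA"}.
#' @slot provenance named character: regulator id to source label.
#' @export
setClass("RegulatorTargetMap",
    representation(targets = "list", type = "character",
                   provenance = "character"))

setValidity("RegulatorTargetMap", function(object) {
    msg <- character()
    if (!identical(names(object@targets), names(object@type)))
        msg <- c(msg, "targets and type must name the same regulators")
    if (anyDuplicated(names(object@targets)))
        msg <- c(msg, "regulator ids must be unique")
    if (length(object@targets) &&
        any(lengths(object@targets) == 0L))
        msg <- c(msg, "target sets must be non-empty")
    if (length(object@type) && !all(object@type %in% c("TF", "miRNA")))
        msg <- c(msg, "regulator type must be 'TF' or 'miRNA'")
    if (length(msg)) msg else TRUE
})

#' @rdname RegulatorTargetMap-class
#' @param targets,type,provenance see slot documentation. \code{provenance}
#'   defaults to \code{"unspecified"} for every regulator.
#' @export
RegulatorTargetMap <- function(targets, type,
                               provenance = setNames(
                                   rep("unspecified", length(targets)),
                                   names(targets))) {
    new("RegulatorTargetMap", targets = targets,
        type = type[names(targets)], provenance = provenance[names(targets)])
}

#' Named collection of annotation gene sets
#'
#' @slot sets named list: term id to gene set (unique gene ids).
#' @slot descriptions named character: term id to free-text description.
#' @export
setClass("AnnotationCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("AnnotationCollection", function(object) {
    msg <- character()
    if (anyDuplicated(names(object@sets)))
        msg <- c(msg, "term ids must be unique")
    if (!identical(names(object@sets), names(object@descriptions)))
        msg <- c(msg, "sets and descriptions must name the same terms")
    if (length(object@sets) && any(lengths(object@sets) == 0L))
        msg <- c(msg, "gene sets must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic-data generator
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' a 1000-gene scale-free-like interactome (preferential attachment, 3
#' edges per new node), four dense planted modules per disease context
#' (sizes 8-12, internal density 0.8), two module pairs with 12 planted
#' extra inter-edges, three expression datasets per context with 20
#' samples per group, planted differential expression of 5 standardized
#' units, and 100 regulators of which four are planted dual-module pivots
#' with 4 targets in each module.
#'
#' @slot rngSeed integer seed; identical configurations generate
#'   byte-identical outputs.
#' @slot nGenes number of genes in the interactome.
#' @slot backgroundAttachment edges added per new node by the
#'   preferential-attachment background.
#' @slot plantedModules data.frame with columns \code{size},
#'   \code{internalDensity}, \code{context}.
#' @slot plantedCrosstalk data.frame with columns \code{moduleI},
#'   \code{moduleJ} (row indices into \code{plantedModules}) and
#'   \code{extraInterEdges}.
#' @slot nDatasetsPerContext expression datasets generated per context.
#' @slot samplesPerGroup samples per condition within a dataset.
#' @slot degEffectSize standardized mean shift of planted DEGs (in units
#'   of \code{noiseSd}).
#' @slot noiseSd per-gene Gaussian noise standard deviation.
#' @slot backgroundDegFraction fraction of non-module genes additionally
#'   planted as DEGs in each context, emulating the (large) majority of
#'   disease DEGs that do not sit in a dense module.
#' @slot nRegulators number of decoy regulators.
#' @slot decoyTargets targets drawn per decoy regulator.
#' @slot plantedPivots data.frame with columns \code{regulatorId},
#'   \code{type}, \code{moduleI}, \code{moduleJ}, \code{targetsPerModule}.
#' @export
setClass("SyntheticConfig",
    representation(rngSeed = "integer", nGenes = "integer",
                   backgroundAttachment = "integer",
                   plantedModules = "data.frame",
                   plantedCrosstalk = "data.frame",
                   nDatasetsPerContext = "integer",
                   samplesPerGroup = "integer", degEffectSize = "numeric",
                   noiseSd = "numeric", backgroundDegFraction = "numeric",
                   nRegulators = "integer",
                   decoyTargets = "integer", plantedPivots = "data.frame"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    counts <- c(nGenes = object@nGenes,
                backgroundAttachment = object@backgroundAttachment,
                nDatasetsPerContext = object@nDatasetsPerContext,
                samplesPerGroup = object@samplesPerGroup,
                nRegulators = object@nRegulators,
                decoyTargets = object@decoyTargets)
    bad <- names(counts)[is.na(counts) | counts < 1L]
    if (length(bad))
        msg <- c(msg, paste0("counts must be positive: ",
                             paste(bad, collapse = ", ")))
    pm <- object@plantedModules
    if (nrow(pm)) {
        if (any(pm$internalDensity <= 0 | pm$internalDensity > 1))
            msg <- c(msg, "internal densities must lie in (0, 1]")
        if (any(pm$size < 2))
            msg <- c(msg, "planted module sizes must be >= 2")
        if (sum(pm$size) > object@nGenes)
            msg <- c(msg, "planted module sizes must sum to <= nGenes")
        if (!all(pm$context %in% c("inflammation", "cancer")))
            msg <- c(msg, "module context must be inflammation or cancer")
    }
    pc <- object@plantedCrosstalk
    if (nrow(pc)) {
        idx <- c(pc$moduleI, pc$moduleJ)
        if (any(idx < 1 | idx > nrow(pm)))
            msg <- c(msg, "crosstalk module indices out of range")
        if (any(pc$extraInterEdges < 1))
            msg <- c(msg, "extraInterEdges must be positive")
    }
    pp <- object@plantedPivots
    if (nrow(pp)) {
        idx <- c(pp$moduleI, pp$moduleJ)
        if (any(idx < 1 | idx > nrow(pm))) {
            msg <- c(msg, "pivot module indices out of range")
        } else if (any(pp$targetsPerModule > pm$size[pp$moduleI]) ||
                   any(pp$targetsPerModule > pm$size[pp$moduleJ])) {
            msg <- c(msg, "targetsPerModule exceeds a module size")
        }
        if (!all(pp$type %in% c("TF", "miRNA")))
            msg <- c(msg, "pivot type must be 'TF' or 'miRNA'")
    }
    if (object@samplesPerGroup < 2L)
        msg <- c(msg, "samplesPerGroup must be >= 2 (variance undefined)")
    if (is.na(object@backgroundDegFraction) ||
        object@backgroundDegFraction < 0 ||
        object@backgroundDegFraction >= 1)
        msg <- c(msg, "backgroundDegFraction must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic-data run
#'
#' @slot moduleMembers named list: planted module id to member gene ids.
#' @slot moduleContext named character: planted module id to context.
#' @slot trueDEGs named list: context to data.frame(\code{gene},
#'   \code{direction}).
#' @slot truePivots data.frame with columns \code{regulator}, \code{type},
#'   \code{moduleI}, \code{moduleJ} (planted module ids).
#' @slot crosstalkPairs data.frame with columns \code{moduleI},
#'   \code{moduleJ}, \code{extraAdded}, \code{interEdges} (total inter-edge
#'   count between non-shared members after planting).
#' @slot genes all gene ids of the generated interactome.
#' @export
setClass("PlantedTruth",
    representation(moduleMembers = "list", moduleContext = "character",
                   trueDEGs = "list", truePivots = "data.frame",
                   crosstalkPairs = "data.frame", genes = "character"))
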