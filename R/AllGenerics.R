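#' @include AllClasses.R
NULL

# ---- generics ---------------------------------------------------------------

#' Underlying igraph graph of a network object
#' @param x an [Interactome-class].
#' @return an \pkg{igraph} object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Node identifiers of a network
#' @param x an [Interactome-class].
#' @return character vector of gene ids.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Number of nodes
#' @param x an [Interactome-class].
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges
#' @param x an [Interactome-class].
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Dataset identifier
#' @param x an [ExpressionDataset-class].
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' Per-sample group labels
#' @param x an [ExpressionDataset-class].
#' @return character vector ("disease"/"normal"), one entry per sample.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Member gene ids
#' @param x a [GeneModule-class] or [IntegratedDEGSet-class].
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' Disease context label
#' @param x a [GeneModule-class] or [IntegratedDEGSet-class].
#' @export
setGeneric("moduleContext", function(x) standardGeneric("moduleContext"))

#' Module identifier
#' @param x a [GeneModule-class].
#' @export
setGeneric("moduleId", function(x) standardGeneric("moduleId"))

#' Seed gene of a detected complex
#' @param x a [GeneModule-class].
#' @export
setGeneric("seedGene", function(x) standardGeneric("seedGene"))

#' Complex score (density times size)
#' @param x a [GeneModule-class].
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))

#' Gene-to-direction map of an integrated DEG set
#' @param x an [IntegratedDEGSet-class].
#' @return named character vector, gene id to "up"/"down".
#' @export
setGeneric("degDirections", function(x) standardGeneric("degDirections"))

#' Supporting dataset ids of an integrated DEG set
#' @param x an [IntegratedDEGSet-class].
#' @return named list, gene id to character vector of dataset ids.
#' @export
setGeneric("degSupport", function(x) standardGeneric("degSupport"))

#' Per-pair crosstalk result table
#' @param x a [CrosstalkResults-class].
#' @return data.frame, one row per tested module pair.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' Stored null inter-edge counts
#' @param x a [CrosstalkResults-class].
#' @return integer matrix, pairs by randomized replicates.
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' Target sets of a regulator map
#' @param x a [RegulatorTargetMap-class].
#' @return named list, regulator id to target gene ids.
#' @export
setGeneric("regulatorTargets", function(x) standardGeneric("regulatorTargets"))

#' Regulator types (TF / miRNA)
#' @param x a [RegulatorTargetMap-class].
#' @export
setGeneric("regulatorType", function(x) standardGeneric("regulatorType"))

#' Gene sets of an annotation collection
#' @param x an [AnnotationCollection-class].
#' @return named list, term id to gene set.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Term descriptions of an annotation collection
#' @param x an [AnnotationCollection-class].
#' @export
setGeneric("termDescriptions",
           function(x) standardGeneric("termDescriptions"))

# ---- methods ----------------------------------------------------------------

#' @rdname asIgraph
setMethod("asIgraph", "Interactome", function(x) x@graph)

#' @rdname nodeIds
setMethod("nodeIds", "Interactome", function(x) {
    if (igraph::vcount(x@graph) == 0L) character() else igraph::V(x@graph)$name
})

#' @rdname numNodes
setMethod("numNodes", "Interactome", function(x) igraph::vcount(x@graph))

#' @rdname numEdges
setMethod("numEdges", "Interactome", function(x) igraph::ecount(x@graph))

#' @rdname datasetId
setMethod("datasetId", "ExpressionDataset",
          function(x) S4Vectors::metadata(x)$datasetId)

#' @rdname groupLabels
setMethod("groupLabels", "ExpressionDataset", function(x) {
    setNames(as.character(SummarizedExperiment::colData(x)$group),
             colnames(x))
})

#' @rdname moduleMembers
setMethod("moduleMembers", "GeneModule", function(x) x@members)

#' @rdname moduleMembers
setMethod("moduleMembers", "IntegratedDEGSet",
          function(x) names(x@direction))

#' @rdname moduleContext
setMethod("moduleContext", "GeneModule", function(x) x@context)

#' @rdname moduleContext
setMethod("moduleContext", "IntegratedDEGSet", function(x) x@context)

#' @rdname moduleId
setMethod("moduleId", "GeneModule", function(x) x@moduleId)

#' @rdname seedGene
setMethod("seedGene", "GeneModule", function(x) x@seedGene)

#' @rdname moduleScore
setMethod("moduleScore", "GeneModule", function(x) x@score)

#' @rdname degDirections
setMethod("degDirections", "IntegratedDEGSet", function(x) x@direction)

#' @rdname degSupport
setMethod("degSupport", "IntegratedDEGSet", function(x) x@support)

#' @rdname resultTable
setMethod("resultTable", "CrosstalkResults", function(x) x@table)

#' @rdname nullCounts
setMethod("nullCounts", "CrosstalkResults", function(x) x@nullCounts)

#' @rdname regulatorTargets
setMethod("regulatorTargets", "RegulatorTargetMap", function(x) x@targets)

#' @rdname regulatorType
setMethod("regulatorType", "RegulatorTargetMap", function(x) x@type)

#' @rdname geneSets
setMethod("geneSets", "AnnotationCollection", function(x) x@sets)

#' @rdname termDescriptions
setMethod("termDescriptions", "AnnotationCollection",
          function(x) x@descriptions)

# ---- show -------------------------------------------------------------------

setMethod("show", "Interactome", function(object) {
    cat("Interactome with", numNodes(object), "nodes and",
        numEdges(object), "edges")
    if (!is.na(object@scoreCutoff))
        cat(" (score cutoff", object@scoreCutoff, ")")
    cat("\n")
})

setMethod("show", "GeneModule", function(object) {
    cat("GeneModule", object@moduleId, "[", object@context, "]:",
        length(object@members), "genes, seed", object@seedGene,
        ", score", round(object@score, 3), "\n")
})

setMethod("show", "IntegratedDEGSet", function(object) {
    d <- object@direction
    cat("IntegratedDEGSet [", object@context, "]:", length(d), "genes (",
        sum(d == "up"), "up /", sum(d == "down"), "down )\n")
})

setMethod("show", "CrosstalkResults", function(object) {
    tab <- object@table
    cat("CrosstalkResults:", nrow(tab), "module pairs,",
        sum(tab$significant), "significant at alpha =", object@alpha,
        "(", object@nRandom, "randomized networks )\n")
})

setMethod("show", "RegulatorTargetMap", function(object) {
    ty <- object@type
    cat("RegulatorTargetMap:", length(ty), "regulators (",
        sum(ty == "TF"), "TF /", sum(ty == "miRNA"), "miRNA ),",
        sum(lengths(object@targets)), "regulator-target pairs\n")
})

setMethod("show", "AnnotationCollection", function(object) {
    cat("AnnotationCollection:", length(object@sets), "terms, median set",
        "size", if (length(object@sets))
            stats::median(lengths(object@sets)) else 0, "\n")
})

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nGenes, "genes,",
        nrow(object@plantedModules), "planted modules,",
        nrow(object@plantedCrosstalk), "planted crosstalk pairs,",
        nrow(object@plantedPivots), "planted pivots (seed",
        object@rngSeed, ")\n")
})

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:", length(object@moduleMembers), "planted modules,",
        sum(vapply(object@trueDEGs, nrow, 1L)), "planted DEG records,",
        nrow(object@truePivots), "planted pivots\n")
})
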