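#' @include AllGenerics.R
NULL

# ---- expression -------------------------------------------------------------

#' Write an expression dataset as TSV plus a label file
#'
#' The expression file has gene ids in the first column (header
#' \code{gene}) and one column per sample; the label file has two columns
#' (\code{sample}, \code{group}).
#'
#' @param dataset an [ExpressionDataset-class].
#' @param exprPath,labelPath output paths.
#' @export
writeExpression <- function(dataset, exprPath, labelPath) {
    x <- SummarizedExperiment::assay(dataset, "exprs")
    df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lab <- data.frame(sample = colnames(x), group = groupLabels(dataset),
                      stringsAsFactors = FALSE)
    utils::write.table(lab, labelPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(exprPath, labelPath))
}

#' Read an expression dataset from TSV plus a label file
#'
#' @param exprPath,labelPath files in the format written by
#'   [writeExpression()].
#' @param datasetId identifier recorded on the dataset.
#' @return an [ExpressionDataset-class].
#' @export
readExpression <- function(exprPath, labelPath, datasetId) {
    for (p in c(exprPath, labelPath))
        if (!file.exists(p)) stop("file not found: ", p)
    df <- utils::read.delim(exprPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    lab <- utils::read.delim(labelPath, stringsAsFactors = FALSE)
    if (!all(colnames(m) %in% lab$sample))
        stop("label file is missing samples present in ", exprPath)
    groups <- lab$group[match(colnames(m), lab$sample)]
    ExpressionDataset(m, groups, datasetId)
}

# ---- networks ---------------------------------------------------------------

#' Write a scored edge table (geneA, geneB, score)
#' @param net an [Interactome-class].
#' @param path output TSV path.
#' @export
writeEdgeTable <- function(net, path) {
    g <- asIgraph(net)
    el <- igraph::as_edgelist(g)
    sc <- if (igraph::ecount(g)) igraph::E(g)$score else numeric()
    utils::write.table(
        data.frame(geneA = el[, 1L], geneB = el[, 2L], score = sc,
                   stringsAsFactors = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Write a network in SIF format ("geneA pp geneB"; isolated nodes as
#' single-field lines)
#' @param net an [Interactome-class].
#' @param path output path.
#' @export
writeSIF <- function(net, path) {
    g <- asIgraph(net)
    el <- igraph::as_edgelist(g)
    lines <- if (nrow(el)) paste(el[, 1L], "pp", el[, 2L]) else character()
    isolated <- setdiff(nodeIds(net), unique(as.vector(el)))
    writeLines(c(lines, isolated), path)
    invisible(path)
}

#' Read a SIF file written by [writeSIF()]
#'
#' Edge scores are not representable in SIF; read edges carry score 1.0.
#' @param path SIF path.
#' @return an [Interactome-class].
#' @export
readSIF <- function(path) {
    if (!file.exists(path)) stop("SIF file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    nf <- lengths(parts)
    if (any(!nf %in% c(1L, 3L)))
        stop("malformed SIF line ", which(!nf %in% c(1L, 3L))[1L],
             " in ", path)
    edges <- do.call(rbind, lapply(parts[nf == 3L],
                                   function(p) p[c(1L, 3L)]))
    singles <- unlist(parts[nf == 1L])
    g <- if (is.null(edges))
        igraph::make_empty_graph(0, directed = FALSE)
    else igraph::graph_from_edgelist(edges, directed = FALSE)
    extra <- setdiff(singles, if (igraph::vcount(g)) igraph::V(g)$name
                              else character())
    if (length(extra)) g <- igraph::add_vertices(g, length(extra),
                                                 name = extra)
    if (igraph::ecount(g)) igraph::E(g)$score <- 1.0
    Interactome(igraph::simplify(g))
}

#' Write a network in GraphML format (node and edge attributes included)
#' @param net an [Interactome-class].
#' @param path output path.
#' @export
writeGraphML <- function(net, path) {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
    invisible(path)
}

#' Read a GraphML network
#' @param path GraphML path.
#' @return an [Interactome-class].
#' @export
readGraphML <- function(path) {
    if (!file.exists(path)) stop("GraphML file not found: ", path)
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::ecount(g) > 0L && is.null(igraph::E(g)$score))
        igraph::E(g)$score <- 1.0
    if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id))
        igraph::V(g)$name <- igraph::V(g)$id
    Interactome(igraph::as_undirected(igraph::simplify(g), mode = "collapse"))
}

# ---- regulators -------------------------------------------------------------

#' Write a regulator map as a 3-column TSV (regulator, type, target)
#' @param map a [RegulatorTargetMap-class].
#' @param path output path.
#' @export
writeRegulatorMap <- function(map, path) {
    targets <- regulatorTargets(map)
    df <- data.frame(
        regulator = rep(names(targets), lengths(targets)),
        type = rep(unname(regulatorType(map)), lengths(targets)),
        target = unlist(targets, use.names = FALSE),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read the 3-column (regulator, type, target) dialect written by
#' [writeRegulatorMap()]
#' @param path TSV path.
#' @return a [RegulatorTargetMap-class].
#' @export
readRegulatorTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
        warning("empty regulator file: ", path)
        return(RegulatorTargetMap(list(), character()))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 3L))
        stop("malformed line ", which(nf != 3L)[1L], " in ", path,
             ": expected regulator, type, target")
    df <- data.frame(regulator = vapply(parts, `[[`, "", 1L),
                     type = vapply(parts, `[[`, "", 2L),
                     target = vapply(parts, `[[`, "", 3L),
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(df[, c("regulator", "target")]), ]
    byReg <- split(df, df$regulator)
    RegulatorTargetMap(
        lapply(byReg, function(d) sort(unique(d$target))),
        vapply(byReg, function(d) d$type[1L], ""),
        setNames(rep(basename(path), length(byReg)), names(byReg)))
}

# ---- modules ----------------------------------------------------------------

#' Write detected modules as TSV
#'
#' Columns: moduleId, context, seed, score, comma-joined members.
#' @param modules list of [GeneModule-class] objects.
#' @param path output path.
#' @export
writeModules <- function(modules, path) {
    df <- data.frame(
        moduleId = vapply(modules, moduleId, ""),
        context = vapply(modules, moduleContext, ""),
        seed = vapply(modules, seedGene, ""),
        score = vapply(modules, moduleScore, 0),
        members = vapply(modules, function(m)
            paste(moduleMembers(m), collapse = ","), ""),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read modules written by [writeModules()]
#' @param path TSV path.
#' @return list of [GeneModule-class] objects.
#' @export
readModules <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i)
        GeneModule(df$moduleId[i], df$context[i],
                   strsplit(df$members[i], ",", fixed = TRUE)[[1L]],
                   df$seed[i], df$score[i]))
}

# ---- DEG tables -------------------------------------------------------------

#' Write a per-dataset DEG table (gene, d, direction, q, dataset)
#' @param table data.frame from [callDEGs()].
#' @param path output path.
#' @param datasetId dataset identifier written in the last column.
#' @export
writeDEGTable <- function(table, path, datasetId) {
    table$dataset <- datasetId
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write an integrated DEG set (gene, direction, support)
#' @param set an [IntegratedDEGSet-class].
#' @param path output path.
#' @export
writeIntegratedDEGs <- function(set, path) {
    d <- degDirections(set)
    df <- data.frame(gene = names(d), direction = unname(d),
                     support = vapply(degSupport(set), paste,
                                      "", collapse = ","),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an integrated DEG set written by [writeIntegratedDEGs()]
#' @param path TSV path.
#' @param context context label for the reconstructed set.
#' @return an [IntegratedDEGSet-class].
#' @export
readIntegratedDEGs <- function(path, context) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    new("IntegratedDEGSet", context = as.character(context),
        direction = setNames(df$direction, df$gene),
        support = setNames(strsplit(df$support, ",", fixed = TRUE),
                           df$gene))
}

# ---- crosstalk & pivots -----------------------------------------------------

#' Write the per-pair crosstalk result table as TSV
#' @param results a [CrosstalkResults-class].
#' @param path output path.
#' @export
writeCrosstalkTable <- function(results, path) {
    utils::write.table(resultTable(results), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write pivot verdicts as TSV
#' @param pivots data.frame from [findPivots()].
#' @param path output path.
#' @export
writePivotTable <- function(pivots, path) {
    utils::write.table(pivots, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

# ---- truth ------------------------------------------------------------------

#' Write a planted-truth object as JSON
#' @param truth a [PlantedTruth-class].
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
    obj <- list(
        moduleMembers = truth@moduleMembers,
        moduleContext = as.list(truth@moduleContext),
        trueDEGs = truth@trueDEGs,
        truePivots = truth@truePivots,
        crosstalkPairs = truth@crosstalkPairs,
        genes = truth@genes)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a planted-truth JSON written by [writeTruth()]
#' @param path JSON path.
#' @return a [PlantedTruth-class].
#' @export
readTruth <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    asDf <- function(x, template) {
        if (is.null(x) || length(x) == 0L || NROW(x) == 0L) template
        else as.data.frame(x, stringsAsFactors = FALSE)
    }
    new("PlantedTruth",
        moduleMembers = lapply(obj$moduleMembers, as.character),
        moduleContext = unlist(obj$moduleContext),
        trueDEGs = lapply(obj$trueDEGs, function(d)
            asDf(d, data.frame(gene = character(),
                               direction = character(),
                               stringsAsFactors = FALSE))),
        truePivots = asDf(obj$truePivots,
            data.frame(regulator = character(), type = character(),
                       moduleI = character(), moduleJ = character(),
                       stringsAsFactors = FALSE)),
        crosstalkPairs = asDf(obj$crosstalkPairs,
            data.frame(moduleI = character(), moduleJ = character(),
                       extraAdded = integer(), interEdges = integer(),
                       stringsAsFactors = FALSE)),
        genes = as.character(obj$genes))
}

# ---- annotations ------------------------------------------------------------

#' Write an annotation collection in GMT format
#' @param annotations an [AnnotationCollection-class].
#' @param path output path.
#' @export
writeGMT <- function(annotations, path) {
    sets <- geneSets(annotations)
    desc <- termDescriptions(annotations)
    lines <- vapply(names(sets), function(t)
        paste(c(t, desc[[t]], sets[[t]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
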