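#' @include AllGenerics.R
NULL

#' Read a scored interaction table and filter by confidence
#'
#' Reads a 3-column TSV (geneA, geneB, combined score). Scores given on a
#' 0-999 integer scale (any value above 1 in the file) are divided by 1000
#' before comparison. Self-loops are dropped with a logged count, duplicate
#' pairs collapse to their maximum score, and only edges with normalized
#' score at or above (inclusive) the cutoff are kept.
#'
#' @param path path to the TSV file; a header line is detected by a
#'   non-numeric third field and skipped.
#' @param scoreCutoff minimum normalized score (default 0.9, inclusive).
#' @return an [Interactome-class]; empty (with a warning) when no edge
#'   passes the filter.
#' @export
readInteractions <- function(path, scoreCutoff = 0.9) {
    if (!file.exists(path)) stop("interaction file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    start <- 1L
    if (length(lines)) {
        f1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
        if (length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[3L]))))
            start <- 2L  # header
    }
    if (start > length(lines)) {
        warning("no interactions in ", path)
        return(Interactome(igraph::make_empty_graph(0, directed = FALSE),
                           scoreCutoff))
    }
    body <- lines[start:length(lines)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
        stop("malformed line ", start - 1L + which(nf < 3L)[1L], " in ",
             path, ": expected 3 tab-separated fields")
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(sc))
        stop("malformed line ", start - 1L + which(is.na(sc))[1L], " in ",
             path, ": non-numeric score")
    if (any(sc > 1)) sc <- sc / 1000  # STRING-style integer dialect
    loops <- a == b
    if (any(loops)) {
        message("readInteractions: dropped ", sum(loops), " self-loop(s)")
        a <- a[!loops]; b <- b[!loops]; sc <- sc[!loops]
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    sc <- vapply(split(sc, key), max, 0)        # duplicates -> max score
    pair <- do.call(rbind, strsplit(names(sc), "\r", fixed = TRUE))
    keep <- sc >= scoreCutoff
    if (!any(keep)) {
        warning("no interactions pass score cutoff ", scoreCutoff)
        return(Interactome(igraph::make_empty_graph(0, directed = FALSE),
                           scoreCutoff))
    }
    g <- igraph::graph_from_edgelist(pair[keep, , drop = FALSE],
                                     directed = FALSE)
    igraph::E(g)$score <- unname(sc[keep])
    Interactome(g, scoreCutoff)
}

#' Map an integrated DEG set onto the interactome
#'
#' Returns the subgraph induced by the DEG members present in the network:
#' an edge survives exactly when both endpoints are DEG members and the
#' edge existed. Node attributes \code{direction} and \code{context} are
#' attached from the DEG set.
#'
#' @param net an [Interactome-class].
#' @param degs an [IntegratedDEGSet-class].
#' @return an [Interactome-class] (possibly empty, logged).
#' @export
mapDEGs <- function(net, degs) {
    g <- asIgraph(net)
    keep <- intersect(moduleMembers(degs), nodeIds(net))
    if (length(keep) == 0L)
        message("mapDEGs: no DEG maps onto the network (",
                moduleContext(degs), ")")
    sub <- igraph::induced_subgraph(g, keep)
    if (igraph::vcount(sub) > 0L) {
        igraph::V(sub)$direction <-
            unname(degDirections(degs)[igraph::V(sub)$name])
        igraph::V(sub)$context <- moduleContext(degs)
    }
    Interactome(sub, net@scoreCutoff)
}

#' Maximal connected component
#'
#' The largest component by node count; ties are broken in favor of the
#' component containing the lexicographically smallest node id.
#'
#' @param net an [Interactome-class].
#' @return an [Interactome-class] (the empty graph maps to itself).
#' @export
maximalConnectedComponent <- function(net) {
    g <- asIgraph(net)
    if (igraph::vcount(g) == 0L) return(net)
    comp <- igraph::components(g)
    best <- which(comp$csize == max(comp$csize))
    if (length(best) > 1L) {
        firstNode <- vapply(best, function(k)
            min(igraph::V(g)$name[comp$membership == k]), "")
        best <- best[order(firstNode)][1L]
    }
    sub <- igraph::induced_subgraph(
        g, which(comp$membership == best))
    Interactome(sub, net@scoreCutoff)
}
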