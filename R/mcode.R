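#' @include AllGenerics.R
NULL

.subgraphDensity <- function(g) {
    n <- igraph::vcount(g)
    if (n < 2L) return(0)
    2 * igraph::ecount(g) / (n * (n - 1))
}

#' Highest k-core of a network
#'
#' The non-empty k-core with maximal k: the maximal subgraph in which
#' every vertex has degree at least k within the subgraph. An edgeless
#' graph has k = 0 (every vertex trivially belongs to the 0-core).
#'
#' @param net an [Interactome-class].
#' @return list with elements \code{core} ([Interactome-class]) and
#'   \code{k} (integer).
#' @examples
#' k4 <- Interactome(igraph::make_full_graph(4))
#' highestKCore(k4)$k  # 3
#' @export
highestKCore <- function(net) {
    g <- asIgraph(net)
    if (igraph::vcount(g) == 0L)
        return(list(core = net, k = 0L))
    core <- igraph::coreness(g)
    k <- max(core)
    sub <- igraph::induced_subgraph(g, which(core >= k))
    list(core = Interactome(sub, net@scoreCutoff), k = as.integer(k))
}

# highest-k-core order and density of an arbitrary igraph (internal)
.coreKDensity <- function(g) {
    if (igraph::vcount(g) == 0L) return(c(k = 0, density = 0))
    core <- igraph::coreness(g)
    k <- max(core)
    sub <- igraph::induced_subgraph(g, which(core >= k))
    c(k = k, density = .subgraphDensity(sub))
}

#' MCODE vertex weight (core-clustering coefficient times core order)
#'
#' The weight of a vertex is k times the density of the highest k-core of
#' the subgraph induced by the vertex and its neighbors (the closed
#' neighborhood). Isolated vertices have weight 0.
#'
#' @param net an [Interactome-class].
#' @param v a vertex name; or \code{NULL} to return the weights of all
#'   vertices at once.
#' @return named numeric vector of weights.
#' @examples
#' k4 <- Interactome(igraph::make_full_graph(4))
#' igraph::V(asIgraph(k4))$name <- letters[1:4]
#' vertexWeight(Interactome(asIgraph(k4)), "a")  # 3: k = 3, density 1
#' @export
vertexWeight <- function(net, v = NULL) {
    g <- asIgraph(net)
    names <- if (igraph::vcount(g)) igraph::V(g)$name else character()
    if (is.null(v)) v <- names
    missing <- setdiff(v, names)
    if (length(missing))
        stop("vertex not in network: ", paste(missing, collapse = ", "))
    adj <- igraph::adjacent_vertices(g, v)
    w <- vapply(seq_along(v), function(i) {
        nb <- as.integer(adj[[i]])
        if (length(nb) == 0L) return(0)
        closed <- c(match(v[i], names), nb)
        kd <- .coreKDensity(igraph::induced_subgraph(g, closed))
        kd[["k"]] * kd[["density"]]
    }, 0)
    setNames(w, v)
}

.complexKCore <- function(g, members, k) {
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::vcount(sub) == 0L) return(FALSE)
    max(igraph::coreness(sub)) >= k
}

#' Detect dense complexes with the MCODE seeded-growth algorithm
#'
#' Vertices are weighted once on the full network with [vertexWeight()].
#' Complexes are seeded from the highest-weight unvisited vertex (ties
#' broken by lexicographic vertex name) and grown breadth-first: a
#' neighbor joins when it is not yet part of any complex and its weight
#' exceeds (1 - nodeScoreCutoff) times the seed weight, up to
#' \code{maxDepth} steps from the seed. Optionally, fluff adds unvisited
#' neighbors whose closed-neighborhood density exceeds
#' \code{fluffDensityCutoff}; haircut then prunes members iteratively to
#' the 2-core of the complex. Complexes whose induced subgraph lacks a
#' non-empty \code{kCoreMin}-core are discarded. Results are sorted by
#' complex score (density times size) descending.
#'
#' @param net an [Interactome-class] (typically a context's maximal
#'   connected component).
#' @param params an [MCODEParams-class].
#' @param context context label stamped on the resulting modules.
#' @return list of [GeneModule-class] objects.
#' @export
mcodeComplexes <- function(net, params = MCODEParams(),
                           context = "unspecified") {
    validObject(params)
    g <- asIgraph(net)
    n <- igraph::vcount(g)
    if (n == 0L) return(list())
    names <- igraph::V(g)$name
    w <- vertexWeight(net)
    adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)

    seedOrder <- order(-w, names)
    visited <- logical(n)
    complexes <- list()
    for (seed in seedOrder) {
        if (visited[seed]) next
        threshold <- (1 - params@nodeScoreCutoff) * w[seed]
        members <- seed
        visited[seed] <- TRUE
        frontier <- seed
        depth <- 0L
        while (length(frontier) && depth < params@maxDepth) {
            nxt <- integer()
            for (u in frontier) {
                for (nb in adj[[u]]) {
                    if (!visited[nb] && w[nb] > threshold) {
                        visited[nb] <- TRUE
                        members <- c(members, nb)
                        nxt <- c(nxt, nb)
                    }
                }
            }
            frontier <- nxt
            depth <- depth + 1L
        }

        if (params@fluff) {
            extra <- integer()
            for (u in members) {
                for (nb in adj[[u]]) {
                    if (!visited[nb] && !nb %in% extra) {
                        closed <- c(nb, adj[[nb]])
                        dens <- .subgraphDensity(
                            igraph::induced_subgraph(g, closed))
                        if (dens > params@fluffDensityCutoff)
                            extra <- c(extra, nb)
                    }
                }
            }
            members <- c(members, extra)
        }

        if (params@haircut && length(members) > 1L) {
            sub <- igraph::induced_subgraph(g, members)
            core <- igraph::coreness(sub)
            # induced_subgraph orders vertices by original index, not by
            # the order in `members`: match on names
            keepNames <- igraph::V(sub)$name[core >= 2L]
            members <- members[names[members] %in% keepNames]
        }

        if (length(members) < 2L) next
        if (!.complexKCore(g, members, params@kCoreMin)) next
        sub <- igraph::induced_subgraph(g, members)
        score <- .subgraphDensity(sub) * igraph::vcount(sub)
        # haircut may prune the seed itself; report the highest-weight
        # surviving member as the complex seed in that case
        seedOut <- if (seed %in% members) seed
                   else members[order(-w[members], names[members])][1L]
        complexes[[length(complexes) + 1L]] <- list(
            seed = names[seedOut], members = sort(names[members]),
            score = score)
    }
    if (length(complexes) == 0L) return(list())
    ord <- order(-vapply(complexes, `[[`, 0, "score"),
                 vapply(complexes, `[[`, "", "seed"))
    complexes <- complexes[ord]
    lapply(seq_along(complexes), function(i) {
        cx <- complexes[[i]]
        GeneModule(sprintf("%s_%03d", context, i), context, cx$members,
                   cx$seed, cx$score)
    })
}
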