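#' @include AllGenerics.R
NULL

#' Count inter-module edges between two modules
#'
#' By default, counts network edges with one endpoint among the members
#' exclusive to the first module and the other among the members exclusive
#' to the second; edges touching shared genes are excluded here and
#' reported by [sharedElements()] instead. With
#' \code{includeSharedEndpoints = TRUE}, edges with one endpoint in each
#' module count unless both endpoints are shared genes.
#'
#' @param net an [Interactome-class].
#' @param a,b [GeneModule-class] objects (or character vectors of members).
#' @param includeSharedEndpoints see description; default \code{FALSE}.
#' @return list with elements \code{count} and \code{edges} (two-column
#'   character matrix).
#' @examples
#' g <- igraph::make_graph(~ x - u, y - v, x - y, u - v)
#' interModuleEdges(Interactome(g), c("x", "y"), c("u", "v"))$count  # 2
#' @export
interModuleEdges <- function(net, a, b, includeSharedEndpoints = FALSE) {
    ma <- if (is(a, "GeneModule")) moduleMembers(a) else as.character(a)
    mb <- if (is(b, "GeneModule")) moduleMembers(b) else as.character(b)
    g <- asIgraph(net)
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0L)
        return(list(count = 0L, edges = matrix(character(), ncol = 2L)))
    if (includeSharedEndpoints) {
        shared <- intersect(ma, mb)
        inA1 <- el[, 1L] %in% ma; inA2 <- el[, 2L] %in% ma
        inB1 <- el[, 1L] %in% mb; inB2 <- el[, 2L] %in% mb
        bothShared <- el[, 1L] %in% shared & el[, 2L] %in% shared
        hit <- ((inA1 & inB2) | (inA2 & inB1)) & !bothShared
    } else {
        ax <- setdiff(ma, mb); bx <- setdiff(mb, ma)
        hit <- (el[, 1L] %in% ax & el[, 2L] %in% bx) |
               (el[, 1L] %in% bx & el[, 2L] %in% ax)
    }
    list(count = sum(hit), edges = el[hit, , drop = FALSE])
}

#' Shared genes and shared edges of a module pair
#'
#' Common genes are the member intersection; common edges are the network
#' edges with both endpoints in that intersection.
#'
#' @inheritParams interModuleEdges
#' @return list with elements \code{genes} (character) and \code{edges}
#'   (two-column character matrix).
#' @export
sharedElements <- function(a, b, net) {
    ma <- if (is(a, "GeneModule")) moduleMembers(a) else as.character(a)
    mb <- if (is(b, "GeneModule")) moduleMembers(b) else as.character(b)
    shared <- sort(intersect(ma, mb))
    g <- asIgraph(net)
    el <- igraph::as_edgelist(g)
    if (nrow(el)) {
        hit <- el[, 1L] %in% shared & el[, 2L] %in% shared
        el <- el[hit, , drop = FALSE]
    }
    list(genes = shared, edges = el)
}

#' Degree-preserving network randomization
#'
#' Rewires the network by double-edge swaps: two edges (a, b) and (c, d)
#' are replaced by (a, d) and (c, b). Proposals that would create a
#' self-loop or a parallel edge are rejected, so the result is a simple
#' graph with exactly the original degree sequence. The number of swap
#' trials is \code{swapsPerEdge} times the edge count.
#'
#' @param net an [Interactome-class].
#' @param rngSeed integer seed; pass \code{NULL} to continue the current
#'   RNG stream (used internally when drawing an ensemble).
#' @param swapsPerEdge swap trials per edge (default 10).
#' @return an [Interactome-class] with identical degree sequence; graphs
#'   with fewer than 2 edges are returned unchanged (logged).
#' @export
randomizeNetwork <- function(net, rngSeed = 1L, swapsPerEdge = 10L) {
    if (swapsPerEdge < 1L) stop("swapsPerEdge must be >= 1")
    g <- asIgraph(net)
    if (igraph::ecount(g) < 2L) {
        message("randomizeNetwork: fewer than 2 edges, returned unchanged")
        return(net)
    }
    if (!is.null(rngSeed)) set.seed(rngSeed)
    r <- igraph::rewire(g, igraph::keeping_degseq(
        loops = FALSE, niter = swapsPerEdge * igraph::ecount(g)))
    igraph::E(r)$score <- 1.0  # scores are not meaningful after rewiring
    Interactome(r)
}

#' Permutation p-value from stored null counts
#'
#' p = (number of null counts strictly greater than the observed count)
#' divided by the ensemble size. The conservative variant adds one
#' pseudo-count to numerator and denominator and uses >=.
#'
#' @param observed observed inter-edge count.
#' @param nulls integer vector of null inter-edge counts.
#' @param conservative use ((#\{null >= obs\} + 1) / (N + 1)) instead.
#' @return the p-value as a fraction.
#' @export
crosstalkPValue <- function(observed, nulls, conservative = FALSE) {
    if (conservative) (sum(nulls >= observed) + 1) / (length(nulls) + 1)
    else sum(nulls > observed) / length(nulls)
}

#' Test crosstalk significance for every module pair
#'
#' Draws \code{nRandom} degree-preserving randomizations of the network
#' (one shared ensemble for all pairs), recounts each pair's inter-module
#' edges on every replicate, and computes the permutation p-value: the
#' fraction of replicates whose count strictly exceeds the observed count.
#' A pair is significant when p < \code{alpha} and at least one inter-edge
#' was observed (with the strict-exceedance formula a pair whose observed
#' and null counts are all zero would otherwise get p = 0).
#'
#' @param net the [Interactome-class] the modules live in.
#' @param modulesA,modulesB lists of [GeneModule-class] objects for the
#'   two contexts (e.g. inflammation and cancer).
#' @param nRandom ensemble size (at least 100; the reference protocol in
#'   the field uses 1000).
#' @param rngSeed integer seed for the ensemble.
#' @param swapsPerEdge swap trials per edge per replicate.
#' @param alpha significance level on the permutation p (default 0.05).
#' @param conservative use the pseudo-count p-value variant.
#' @param adjust apply Benjamini-Hochberg across pairs before flagging.
#' @param includeSharedEndpoints forwarded to [interModuleEdges()].
#' @return a [CrosstalkResults-class]; empty when either module list is
#'   empty (logged).
#' @export
crosstalkTest <- function(net, modulesA, modulesB, nRandom = 1000L,
                          rngSeed = 1L, swapsPerEdge = 10L, alpha = 0.05,
                          conservative = FALSE, adjust = FALSE,
                          includeSharedEndpoints = FALSE) {
    if (nRandom < 100L) stop("nRandom must be >= 100")
    emptyRes <- function() new("CrosstalkResults",
        table = data.frame(moduleA = character(), moduleB = character(),
                           observed = integer(), nullMean = numeric(),
                           p = numeric(), significant = logical(),
                           nSharedGenes = integer(),
                           nSharedEdges = integer(),
                           stringsAsFactors = FALSE),
        nullCounts = matrix(integer(), nrow = 0L, ncol = nRandom),
        sharedGenes = list(), sharedEdges = list(),
        nRandom = as.integer(nRandom), alpha = as.numeric(alpha))
    if (length(modulesA) == 0L || length(modulesB) == 0L) {
        message("crosstalkTest: no modules on one side, nothing to test")
        return(emptyRes())
    }
    g <- asIgraph(net)
    names <- igraph::V(g)$name
    n <- length(names)

    pairs <- expand.grid(ai = seq_along(modulesA),
                         bi = seq_along(modulesB))
    nPairs <- nrow(pairs)
    # per-pair membership masks over the vertex index (exclusive or full,
    # depending on the counting convention)
    maskA <- maskB <- matrix(FALSE, nrow = nPairs, ncol = n)
    observed <- integer(nPairs)
    sharedGenes <- vector("list", nPairs)
    sharedEdges <- vector("list", nPairs)
    for (i in seq_len(nPairs)) {
        A <- modulesA[[pairs$ai[i]]]; B <- modulesB[[pairs$bi[i]]]
        ime <- interModuleEdges(net, A, B, includeSharedEndpoints)
        observed[i] <- ime$count
        sh <- sharedElements(A, B, net)
        sharedGenes[[i]] <- sh$genes
        sharedEdges[[i]] <- sh$edges
        if (includeSharedEndpoints) {
            maskA[i, match(moduleMembers(A), names)] <- TRUE
            maskB[i, match(moduleMembers(B), names)] <- TRUE
        } else {
            ax <- setdiff(moduleMembers(A), moduleMembers(B))
            bx <- setdiff(moduleMembers(B), moduleMembers(A))
            maskA[i, match(ax, names)] <- TRUE
            maskB[i, match(bx, names)] <- TRUE
        }
    }
    bothSharedDrop <- includeSharedEndpoints  # need shared-shared exclusion
    sharedMask <- if (bothSharedDrop)
        lapply(seq_len(nPairs), function(i)
            match(sharedGenes[[i]], names)) else NULL

    set.seed(rngSeed)
    nullCounts <- matrix(0L, nrow = nPairs, ncol = nRandom)
    for (r in seq_len(nRandom)) {
        rg <- igraph::rewire(g, igraph::keeping_degseq(
            loops = FALSE, niter = swapsPerEdge * igraph::ecount(g)))
        el <- igraph::as_edgelist(rg, names = FALSE)
        u <- el[, 1L]; v <- el[, 2L]
        for (i in seq_len(nPairs)) {
            hit <- (maskA[i, u] & maskB[i, v]) |
                   (maskA[i, v] & maskB[i, u])
            if (bothSharedDrop && length(sharedMask[[i]])) {
                both <- (u %in% sharedMask[[i]]) & (v %in% sharedMask[[i]])
                hit <- hit & !both
            }
            nullCounts[i, r] <- sum(hit)
        }
    }

    p <- vapply(seq_len(nPairs), function(i)
        crosstalkPValue(observed[i], nullCounts[i, ], conservative), 0)
    flagP <- if (adjust) stats::p.adjust(p, "BH") else p
    tab <- data.frame(
        moduleA = vapply(modulesA, moduleId, "")[pairs$ai],
        moduleB = vapply(modulesB, moduleId, "")[pairs$bi],
        observed = observed,
        nullMean = rowMeans(nullCounts),
        p = p,
        # a pair with no observed inter-edge is never called significant,
        # whatever the (degenerate, all-tied) null says
        significant = flagP < alpha & observed > 0L,
        nSharedGenes = lengths(sharedGenes),
        nSharedEdges = vapply(sharedEdges, nrow, 0L),
        stringsAsFactors = FALSE)
    new("CrosstalkResults", table = tab, nullCounts = nullCounts,
        sharedGenes = sharedGenes, sharedEdges = sharedEdges,
        nRandom = as.integer(nRandom), alpha = as.numeric(alpha))
}
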