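# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# igraph with named vertices wrapped as an Interactome
namedGraph <- function(g, names = NULL) {
    if (is.null(names))
        names <- if (is.null(igraph::V(g)$name))
            paste0("v", seq_len(igraph::vcount(g)))
        else igraph::V(g)$name
    igraph::V(g)$name <- names
    Interactome(g)
}

# empty planting frames for configs without the corresponding structure
noModules <- function() data.frame(size = integer(),
                                   internalDensity = numeric(),
                                   context = character())
noCrosstalk <- function() data.frame(moduleI = integer(),
                                     moduleJ = integer(),
                                     extraInterEdges = integer())
noPivots <- function() data.frame(regulatorId = character(),
                                  type = character(), moduleI = integer(),
                                  moduleJ = integer(),
                                  targetsPerModule = integer())

# small two-group expression dataset from explicit per-gene rows
toyExpression <- function(rows, nDisease = 3, nNormal = 3, id = "toy") {
    m <- do.call(rbind, rows)
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    ExpressionDataset(m, rep(c("disease", "normal"), c(nDisease, nNormal)),
                      id)
}

# integrated DEG set constructed directly from gene -> direction
degSet <- function(direction, context = "inflammation") {
    new("IntegratedDEGSet", context = context, direction = direction,
        support = setNames(as.list(rep("fixture", length(direction))),
                           names(direction)))
}

# exhaustive hypergeometric upper tail: enumerate every overlap outcome
bruteUpperHyper <- function(k, K, N, n) {
    xs <- max(0L, n + K - N):min(K, n)
    probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
    sum(probs[xs >= k])
}

# Jaccard of the best-matching complex for a planted member set
bestJaccard <- function(modules, members) {
    if (length(modules) == 0L) return(0)
    max(vapply(modules, function(m) {
        a <- moduleMembers(m)
        length(intersect(a, members)) / length(union(a, members))
    }, 0))
}

# truth-derived IntegratedDEGSet for one context
truthDegSet <- function(truth, ctx) {
    td <- truth@trueDEGs[[ctx]]
    degSet(setNames(td$direction, td$gene), ctx)
}
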