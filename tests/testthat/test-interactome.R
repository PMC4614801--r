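writeLinesTmp <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
}

test_that("score filtering honors cutoff, dialect and canonicalization", {
    # fractional dialect, inclusive cutoff
    net <- readInteractions(writeLinesTmp(c("P1\tP2\t0.95",
                                            "P5\tP6\t0.90",
                                            "P3\tP4\t0.85")), 0.9)
    expect_equal(numEdges(net), 2L)
    expect_setequal(nodeIds(net), c("P1", "P2", "P5", "P6"))
    # 0-999 integer dialect: 850 -> 0.850, dropped at 0.9
    net2 <- readInteractions(writeLinesTmp(c("P1\tP2\t950",
                                             "P3\tP4\t850")), 0.9)
    expect_equal(numEdges(net2), 1L)
    expect_equal(igraph::E(asIgraph(net2))$score, 0.95)
    # duplicate pairs collapse to the maximum score
    net3 <- readInteractions(writeLinesTmp(c("A\tB\t0.91",
                                             "B\tA\t0.93")), 0.9)
    expect_equal(numEdges(net3), 1L)
    expect_equal(igraph::E(asIgraph(net3))$score, 0.93)
})

test_that("self-loops are dropped and malformed lines are located", {
    expect_message(
        net <- readInteractions(writeLinesTmp(c("A\tA\t0.95",
                                                "A\tB\t0.95")), 0.9),
        "self-loop")
    expect_equal(numEdges(net), 1L)
    expect_error(readInteractions(writeLinesTmp(c("A\tB\t0.95",
                                                  "Conly")), 0.9),
                 "line 2")
    expect_error(readInteractions(writeLinesTmp(c("A\tB\t0.95",
                                                  "C\tD\tzzz")), 0.9),
                 "line 2")
    expect_warning(empty <- readInteractions(
        writeLinesTmp("A\tB\t0.5"), 0.9), "cutoff")
    expect_equal(numEdges(empty), 0L)
})

test_that("raising the cutoff never adds edges", {
    syn <- generateInteractome(syntheticConfig(rngSeed = 4L, nGenes = 80L,
        plantedModules = noModules(), plantedCrosstalk = noCrosstalk(),
        plantedPivots = noPivots()))
    f <- tempfile()
    g <- asIgraph(syn$interactome)
    set.seed(2)
    igraph::E(g)$score <- stats::runif(igraph::ecount(g))
    writeEdgeTable(Interactome(g), f)
    prev <- Inf
    for (cut in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
        n <- numEdges(suppressWarnings(readInteractions(f, cut)))
        expect_lte(n, prev)
        prev <- n
    }
})

test_that("mapDEGs yields exactly the induced subgraph", {
    path <- namedGraph(igraph::make_graph(~ a - b, b - c))
    sub <- mapDEGs(path, degSet(c(a = "up", c = "down")))
    expect_equal(numNodes(sub), 2L)
    expect_equal(numEdges(sub), 0L)
    # all nodes -> identity
    all <- mapDEGs(path, degSet(c(a = "up", b = "up", c = "down")))
    expect_equal(numEdges(all), 2L)
    expect_identical(
        sort(igraph::V(asIgraph(all))$direction[
            match(c("a", "b", "c"), nodeIds(all))]),
        sort(c("up", "up", "down")))
    # empty intersection -> empty graph, logged
    expect_message(none <- mapDEGs(path, degSet(c(z = "up"))), "no DEG")
    expect_equal(numNodes(none), 0L)
})

test_that("maximal connected component picks size then lexicographic tie", {
    g <- namedGraph(igraph::make_graph(~ a - b, b - c, d - e))
    mcc <- maximalConnectedComponent(g)
    expect_setequal(nodeIds(mcc), c("a", "b", "c"))
    # connected graph maps to itself
    conn <- namedGraph(igraph::make_ring(4))
    expect_setequal(nodeIds(maximalConnectedComponent(conn)),
                    nodeIds(conn))
    # tie between {c,d} and {a,b}: the one holding "a" wins
    tie <- namedGraph(igraph::make_graph(~ c - d, a - b))
    expect_setequal(nodeIds(maximalConnectedComponent(tie)), c("a", "b"))
    empty <- Interactome(igraph::make_empty_graph(0, directed = FALSE))
    expect_equal(numNodes(maximalConnectedComponent(empty)), 0L)
})

test_that("Interactome validity rejects malformed graphs", {
    g <- igraph::make_graph(~ a - b)
    igraph::E(g)$score <- 1.5
    expect_error(Interactome(g), "scores")
    d <- igraph::make_graph(c("a", "b"), directed = TRUE)
    expect_error(Interactome(d), "undirected")
})
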