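test_that("inter-module edge counting follows the exclusive convention", {
    g <- namedGraph(igraph::make_graph(~ x - u, y - v, x - y, u - v),
                    names = c("x", "u", "y", "v"))
    res <- interModuleEdges(g, c("x", "y"), c("u", "v"))
    expect_equal(res$count, 2L)
    # edges touching a shared gene are excluded
    g2 <- namedGraph(igraph::make_graph(~ x - d, y - c, c - d),
                     names = c("x", "d", "y", "c"))
    res2 <- interModuleEdges(g2, c("x", "y", "c"), c("c", "d"))
    expect_equal(res2$count, 1L)
    expect_identical(sort(res2$edges[1, ]), c("d", "x"))
    # but can be included under the alternative convention
    res3 <- interModuleEdges(g2, c("x", "y", "c"), c("c", "d"),
                             includeSharedEndpoints = TRUE)
    expect_gte(res3$count, res2$count)
    # edgeless graph
    e <- Interactome(igraph::make_empty_graph(4, directed = FALSE) |>
        igraph::set_vertex_attr("name", value = letters[1:4]))
    expect_equal(interModuleEdges(e, c("a", "b"), c("c", "d"))$count, 0L)
})

test_that("shared elements are the intersection and its internal edges", {
    g <- namedGraph(igraph::make_graph(~ c - d, a - c),
                    names = c("c", "d", "a"))
    sh <- sharedElements(c("a", "c", "d"), c("c", "d", "z"), g)
    expect_identical(sh$genes, c("c", "d"))
    expect_equal(nrow(sh$edges), 1L)
    none <- sharedElements(c("a"), c("z"), g)
    expect_length(none$genes, 0L)
    expect_equal(nrow(none$edges), 0L)
})

test_that("randomization preserves the degree sequence exactly", {
    syn <- generateInteractome(syntheticConfig(rngSeed = 5L, nGenes = 200L))
    net <- syn$interactome
    d0 <- sort(igraph::degree(asIgraph(net)))
    for (s in 1:5) {
        r <- randomizeNetwork(net, rngSeed = s)
        g <- asIgraph(r)
        expect_identical(sort(igraph::degree(g)), d0)
        expect_true(igraph::is_simple(g))
    }
    # identical seed, identical rewiring
    r1 <- randomizeNetwork(net, rngSeed = 77L)
    r2 <- randomizeNetwork(net, rngSeed = 77L)
    expect_identical(igraph::as_edgelist(asIgraph(r1)),
                     igraph::as_edgelist(asIgraph(r2)))
})

test_that("degree sequences with a unique realization are fixed points", {
    k3 <- namedGraph(igraph::make_full_graph(3))
    r <- randomizeNetwork(k3, rngSeed = 1L)
    expect_equal(numEdges(r), 3L)
    expect_true(igraph::is_connected(asIgraph(r)))
    # a 3-path stays a 3-path (degrees 1,2,1) over many seeds
    p3 <- namedGraph(igraph::make_graph(~ a - b, b - c))
    for (s in 1:10) {
        r <- randomizeNetwork(p3, rngSeed = s)
        expect_identical(unname(sort(igraph::degree(asIgraph(r)))),
                         c(1, 1, 2))
    }
    tiny <- namedGraph(igraph::make_graph(~ a - b))
    expect_message(same <- randomizeNetwork(tiny), "fewer than 2 edges")
    expect_equal(numEdges(same), 1L)
})

test_that("the permutation p-value is the strict exceedance fraction", {
    nulls <- c(rep(11L, 50), rep(10L, 100), rep(3L, 850))
    expect_identical(crosstalkPValue(10L, nulls), 0.05)
    expect_identical(crosstalkPValue(20L, nulls), 0)
    expect_identical(crosstalkPValue(-1L, nulls), 1)
    # conservative variant uses >= with a pseudo-count
    expect_equal(crosstalkPValue(10L, nulls, conservative = TRUE),
                 151 / 1001)
    # monotone: more observed edges can only lower p
    set.seed(4)
    ns <- as.integer(rpois(500, 6))
    for (obs in 0:12)
        expect_gte(crosstalkPValue(obs, ns),
                   crosstalkPValue(obs + 1L, ns))
})

test_that("crosstalkTest stores an auditable ensemble of null counts", {
    syn <- generateInteractome(syntheticConfig(rngSeed = 6L, nGenes = 300L))
    mods <- plantedModules(syn$truth)
    names(mods) <- names(syn$truth@moduleMembers)
    ct <- crosstalkTest(syn$interactome, mods[c("M01", "M02")],
                        mods[c("M05", "M06")], nRandom = 100L,
                        rngSeed = 9L)
    tab <- resultTable(ct)
    nc <- nullCounts(ct)
    expect_identical(dim(nc), c(4L, 100L))
    # recompute p from the stored ensemble in exact integer arithmetic
    for (i in seq_len(nrow(tab))) {
        expect_identical(tab$p[i],
                         sum(nc[i, ] > tab$observed[i]) / 100)
    }
    expect_identical(tab$significant, tab$p < 0.05 & tab$observed > 0L)
    # determinism of the shared ensemble
    ct2 <- crosstalkTest(syn$interactome, mods[c("M01", "M02")],
                         mods[c("M05", "M06")], nRandom = 100L,
                         rngSeed = 9L)
    expect_identical(nullCounts(ct2), nc)
    # empty module lists short-circuit
    expect_message(e <- crosstalkTest(syn$interactome, list(), mods,
                                      nRandom = 100L), "no modules")
    expect_equal(nrow(resultTable(e)), 0L)
})
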