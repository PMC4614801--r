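test_that("generation is deterministic given the seed", {
    cfg <- syntheticConfig(rngSeed = 5L, nGenes = 200L)
    a <- generateSynthetic(cfg)
    b <- generateSynthetic(cfg)
    expect_identical(igraph::as_edgelist(asIgraph(a$interactome)),
                     igraph::as_edgelist(asIgraph(b$interactome)))
    expect_identical(a$truth@trueDEGs, b$truth@trueDEGs)
    expect_identical(
        SummarizedExperiment::assay(a$expression[[1]], "exprs"),
        SummarizedExperiment::assay(b$expression[[1]], "exprs"))
    expect_identical(regulatorTargets(a$regulators),
                     regulatorTargets(b$regulators))
    cfg2 <- syntheticConfig(rngSeed = 6L, nGenes = 200L)
    c <- generateInteractome(cfg2)
    expect_false(identical(
        igraph::as_edgelist(asIgraph(a$interactome)),
        igraph::as_edgelist(asIgraph(c$interactome))))
})

test_that("a planted module at density 1 induces a clique", {
    cfg <- syntheticConfig(rngSeed = 3L, nGenes = 100L,
        plantedModules = data.frame(size = 6L, internalDensity = 1.0,
                                    context = "inflammation"),
        plantedCrosstalk = noCrosstalk(), plantedPivots = noPivots())
    out <- generateInteractome(cfg)
    mem <- out$truth@moduleMembers$M01
    sub <- igraph::induced_subgraph(asIgraph(out$interactome), mem)
    expect_equal(igraph::ecount(sub), 15L)   # C(6, 2)
})

test_that("planted modules meet their density floor and are connected", {
    cfg <- syntheticConfig(rngSeed = 8L, nGenes = 300L)
    out <- generateInteractome(cfg)
    pm <- cfg@plantedModules
    for (i in seq_len(nrow(pm))) {
        mem <- out$truth@moduleMembers[[sprintf("M%02d", i)]]
        sub <- igraph::induced_subgraph(asIgraph(out$interactome), mem)
        dens <- 2 * igraph::ecount(sub) /
            (length(mem) * (length(mem) - 1))
        expect_gte(dens, pm$internalDensity[i])
        expect_true(igraph::is_connected(sub))
    }
})

test_that("planted crosstalk edge counts are auditable by enumeration", {
    cfg <- syntheticConfig(rngSeed = 12L, nGenes = 400L)
    out <- generateInteractome(cfg)
    ctp <- out$truth@crosstalkPairs
    expect_equal(ctp$extraAdded, c(12L, 12L))
    el <- igraph::as_edgelist(asIgraph(out$interactome))
    for (r in seq_len(nrow(ctp))) {
        a <- out$truth@moduleMembers[[ctp$moduleI[r]]]
        b <- out$truth@moduleMembers[[ctp$moduleJ[r]]]
        ax <- setdiff(a, b); bx <- setdiff(b, a)
        crossing <- sum((el[, 1] %in% ax & el[, 2] %in% bx) |
                        (el[, 1] %in% bx & el[, 2] %in% ax))
        expect_identical(crossing, ctp$interEdges[r])
        expect_gte(crossing, ctp$extraAdded[r])
    }
})

test_that("infeasible module configurations error", {
    expect_error(syntheticConfig(nGenes = 10L,
        plantedModules = data.frame(size = c(6L, 6L),
                                    internalDensity = 0.9,
                                    context = c("inflammation", "cancer"))),
        "sum")
    expect_error(syntheticConfig(
        plantedModules = data.frame(size = 6L, internalDensity = 1.2,
                                    context = "cancer")),
        "densities")
    expect_error(syntheticConfig(samplesPerGroup = 1L), "samplesPerGroup")
})

test_that("planted DEGs shift group means by the configured effect", {
    cfg <- syntheticConfig(rngSeed = 4L, nGenes = 150L,
                           samplesPerGroup = 10L, degEffectSize = 5,
                           noiseSd = 1, backgroundDegFraction = 0)
    out <- generateInteractome(cfg)
    expr <- generateExpression(cfg, out$truth)
    ds <- expr$inflammation_ds1
    grp <- groupLabels(ds)
    x <- SummarizedExperiment::assay(ds, "exprs")
    td <- out$truth@trueDEGs$inflammation
    diff <- rowMeans(x[td$gene, grp == "disease"]) -
        rowMeans(x[td$gene, grp == "normal"])
    signed <- ifelse(td$direction == "up", diff, -diff)
    # group-mean difference ~ N(5, 1/10 + 1/10) per gene
    expect_lt(max(abs(signed - 5)), 5 * sqrt(0.2))
    expect_lt(abs(mean(signed) - 5), 0.5)
    # non-DEG genes: no systematic shift
    bg <- setdiff(rownames(x), td$gene)
    expect_lt(abs(mean(rowMeans(x[bg, grp == "disease"]) -
                       rowMeans(x[bg, grp == "normal"]))), 0.2)
})

test_that("planted DEG directions agree across datasets of a context", {
    cfg <- syntheticConfig(rngSeed = 9L, nGenes = 150L,
                           nDatasetsPerContext = 3L)
    out <- generateInteractome(cfg)
    expr <- generateExpression(cfg, out$truth)
    td <- out$truth@trueDEGs$cancer
    for (d in 1:3) {
        ds <- expr[[sprintf("cancer_ds%d", d)]]
        grp <- groupLabels(ds)
        x <- SummarizedExperiment::assay(ds, "exprs")
        diff <- rowMeans(x[td$gene, grp == "disease", drop = FALSE]) -
            rowMeans(x[td$gene, grp == "normal", drop = FALSE])
        expect_true(all(sign(diff) == ifelse(td$direction == "up", 1, -1)))
    }
})

test_that("null expression (effect 0) yields almost no DEG calls", {
    frac <- vapply(1:5, function(s) {
        cfg <- syntheticConfig(rngSeed = s, nGenes = 300L,
                               nDatasetsPerContext = 1L,
                               samplesPerGroup = 10L, degEffectSize = 0)
        out <- generateInteractome(cfg)
        expr <- generateExpression(cfg, out$truth)
        tab <- suppressMessages(callDEGs(expr[[1]], fdrTarget = 0.01,
                                         nPermutations = 100L,
                                         rngSeed = s + 40L))
        nrow(tab) / 300
    }, 0)
    expect_lte(mean(frac), 0.02)
})

test_that("planted pivots carry enough in-module targets; decoys are uniform", {
    cfg <- syntheticConfig(rngSeed = 17L)
    out <- generateInteractome(cfg)
    map <- generateRegulatorMap(cfg, out$truth)
    pp <- cfg@plantedPivots
    for (r in seq_len(nrow(pp))) {
        tg <- regulatorTargets(map)[[pp$regulatorId[r]]]
        memI <- out$truth@moduleMembers[[sprintf("M%02d", pp$moduleI[r])]]
        memJ <- out$truth@moduleMembers[[sprintf("M%02d", pp$moduleJ[r])]]
        expect_gte(length(intersect(tg, memI)), pp$targetsPerModule[r])
        expect_gte(length(intersect(tg, memJ)), pp$targetsPerModule[r])
    }
    # with no planted pivots the map holds only decoys with the
    # configured number of uniform targets
    cfg2 <- syntheticConfig(rngSeed = 17L, nRegulators = 20L,
                            plantedPivots = noPivots())
    out2 <- generateInteractome(cfg2)
    map2 <- generateRegulatorMap(cfg2, out2$truth)
    expect_length(regulatorTargets(map2), 20L)
    expect_true(all(lengths(regulatorTargets(map2)) == 10L))
    expect_setequal(unique(unname(regulatorType(map2))), c("TF", "miRNA"))
})

test_that("background degree distribution is right-skewed", {
    for (s in 1:3) {
        cfg <- syntheticConfig(rngSeed = s, nGenes = 500L,
                               plantedModules = noModules(),
                               plantedCrosstalk = noCrosstalk(),
                               plantedPivots = noPivots())
        out <- generateInteractome(cfg)
        deg <- igraph::degree(asIgraph(out$interactome))
        expect_gt(max(deg), 3 * stats::median(deg))
    }
})
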