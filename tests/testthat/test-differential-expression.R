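test_that("the d statistic matches hand-computed pooled-SE arithmetic", {
    eds <- toyExpression(list(gA = c(4, 5, 6, 1, 2, 3),
                              gB = c(2, 2, 3, 2, 2, 3)))
    d <- samStatistic(eds, s0 = 0)
    # s = sqrt((1/3 + 1/3) * (2 + 2) / 4) = sqrt(2/3); d = 3 / s
    expect_equal(unname(d["gA"]), 3 / sqrt(2 / 3), tolerance = 1e-12)
    # identical group profiles -> d exactly 0
    expect_identical(unname(d["gB"]), 0)
    expect_gt(unname(d["gA"]), 0)  # disease mean exceeds normal mean
})

test_that("increasing s0 strictly shrinks nonzero statistics", {
    set.seed(1)
    eds <- toyExpression(list(g1 = rnorm(6) + c(2, 2, 2, 0, 0, 0),
                              g2 = rnorm(6)))
    d1 <- samStatistic(eds, s0 = 0.5)
    d2 <- samStatistic(eds, s0 = 1.0)
    expect_true(all(abs(d2) < abs(d1)))
})

test_that("zero within-group variance with s0 = 0 is flagged per config", {
    eds <- toyExpression(list(flat = c(5, 5, 5, 1, 1, 1)))
    expect_error(samStatistic(eds, s0 = 0), "zero within-group variance")
    d <- samStatistic(eds, s0 = 0, zeroSe = "infinite")
    expect_identical(unname(d["flat"]), Inf)
    # positive s0 stabilizes the same gene
    expect_equal(unname(samStatistic(eds, s0 = 0.5)["flat"]), 8)
})

test_that("d values are invariant to relabeling samples within a group", {
    set.seed(7)
    m <- matrix(rnorm(80), nrow = 8,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
    eds1 <- ExpressionDataset(m, rep(c("disease", "normal"), each = 5), "a")
    perm <- m[, c(3, 1, 2, 5, 4, 8, 10, 6, 7, 9)]  # within-group shuffles
    eds2 <- ExpressionDataset(perm, rep(c("disease", "normal"), each = 5),
                              "a")
    expect_equal(samStatistic(eds1, s0 = 0.1), samStatistic(eds2, s0 = 0.1))
})

test_that("callDEGs recovers strong planted effects with controlled FDR", {
    cfg <- syntheticConfig(rngSeed = 2L, nDatasetsPerContext = 1L,
        samplesPerGroup = 10L, backgroundDegFraction = 0,
        plantedModules = data.frame(size = rep(10L, 5),
                                    internalDensity = 0.8,
                                    context = "inflammation"),
        plantedCrosstalk = noCrosstalk(), plantedPivots = noPivots())
    out <- generateInteractome(cfg)
    expr <- generateExpression(cfg, out$truth)
    tab <- callDEGs(expr[[1]], fdrTarget = 0.01, nPermutations = 100L,
                    rngSeed = 11L)
    truthTab <- out$truth@trueDEGs$inflammation
    expect_gte(sum(tab$gene %in% truthTab$gene), 45)
    called <- tab[tab$gene %in% truthTab$gene, ]
    expect_identical(called$direction,
                     truthTab$direction[match(called$gene, truthTab$gene)])
    expect_true(all(tab$q <= 0.01))
})

test_that("integration requires two supporting datasets with one direction", {
    t1 <- data.frame(gene = c("a", "b", "c"), d = c(3, -2, 2),
                     direction = c("up", "down", "up"), q = 0)
    t2 <- data.frame(gene = c("a", "b"), d = c(2, 2),
                     direction = c("up", "up"), q = 0)
    set <- integrateDEGs(list(ds1 = t1, ds2 = t2), "inflammation")
    # a: up in both -> member; b: conflicting -> out; c: single -> out
    expect_identical(moduleMembers(set), "a")
    expect_identical(unname(degDirections(set)["a"]), "up")
    expect_setequal(degSupport(set)[["a"]], c("ds1", "ds2"))
    # single-comparison contexts may integrate with minSupport = 1
    one <- integrateDEGs(list(ds1 = t1), "inflammation-vs-cancer",
                         minSupport = 1L)
    expect_setequal(moduleMembers(one), c("a", "b", "c"))
})

test_that("integration rejects duplicate or missing dataset ids", {
    t1 <- data.frame(gene = "a", d = 1, direction = "up", q = 0)
    expect_error(integrateDEGs(list(ds1 = t1, ds1 = t1), "cancer"),
                 "duplicate")
    expect_error(integrateDEGs(list(t1), "cancer"), "named")
})

test_that("setOverlap partitions the union exactly", {
    a <- degSet(c(g1 = "up", g2 = "down", g3 = "up"))
    b <- degSet(c(g2 = "up", g3 = "down", g4 = "up"), "cancer")
    ov <- setOverlap(a, b)
    expect_identical(ov$shared, c("g2", "g3"))
    expect_identical(ov$aOnly, "g1")
    expect_identical(ov$bOnly, "g4")
    expect_equal(length(ov$shared) + length(ov$aOnly), 3)
    same <- setOverlap(a, a)
    expect_length(same$aOnly, 0)
    expect_length(same$bOnly, 0)
    expect_setequal(same$shared, moduleMembers(a))
    disjoint <- setOverlap(c("x"), c("y"))
    expect_length(disjoint$shared, 0)
})
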