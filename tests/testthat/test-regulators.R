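test_that("regulator files union with duplicate collapse", {
    f1 <- tempfile(); writeLines(c("R1\tg1", "R1\tg2", "R2\tg1"), f1)
    f2 <- tempfile(); writeLines(c("R1\tg2\tsrcB", "R1\tg3\tsrcB"), f2)
    map <- suppressMessages(readRegulatorMap(c(f1, f2), c("TF", "TF")))
    expect_setequal(regulatorTargets(map)$R1, c("g1", "g2", "g3"))
    expect_setequal(regulatorTargets(map)$R2, "g1")
    expect_identical(unname(regulatorType(map)["R1"]), "TF")
    fe <- tempfile(); writeLines(character(), fe)
    expect_warning(suppressMessages(readRegulatorMap(fe, "miRNA")),
                   "empty")
    fb <- tempfile(); writeLines(c("R1\tg1", "lonely"), fb)
    expect_error(suppressMessages(readRegulatorMap(fb, "TF")), "line 2")
})

test_that("hypergeometric p matches exhaustive enumeration", {
    bg <- paste0("g", 1:10)
    # module 4 of 10, 5 draws, overlap 4: C(4,4)C(6,1)/C(10,5) = 6/252
    p <- hypergeometricEnrichment(bg[1:5], bg[1:4], bg)
    expect_equal(p, 6 / 252, tolerance = 1e-12)
    # randomized small populations against the brute-force oracle
    set.seed(42)
    for (i in 1:25) {
        N <- sample(5:30, 1)
        bg <- paste0("g", seq_len(N))
        K <- sample(1:N, 1)
        n <- sample(1:N, 1)
        mod <- sample(bg, K)
        tg <- sample(bg, n)
        k <- length(intersect(mod, tg))
        expect_equal(hypergeometricEnrichment(tg, mod, bg),
                     bruteUpperHyper(k, K, N, n), tolerance = 1e-10)
    }
    # degenerate cases
    expect_equal(hypergeometricEnrichment(character(), bg[1:3], bg), 1)
    expect_equal(hypergeometricEnrichment(bg[1:4], bg, bg), 1)
    expect_error(hypergeometricEnrichment("g1", "g1", character()),
                 "non-empty")
})

test_that("enlarging a module by target genes never increases p", {
    bg <- paste0("g", 1:40)
    tg <- bg[1:12]
    p <- hypergeometricEnrichment(tg, bg[1:4], bg)
    for (extra in 5:10) {
        p2 <- hypergeometricEnrichment(tg, bg[1:extra], bg)
        expect_lte(p2, p + 1e-12)
        p <- p2
    }
})

test_that("the pivot rule needs >2 targets and p<0.05 in both modules", {
    bg <- paste0("g", 1:1000)
    modA <- GeneModule("inflammation_001", "inflammation", bg[1:8])
    modB <- GeneModule("cancer_001", "cancer", bg[9:16])
    map <- RegulatorTargetMap(
        targets = list(
            good = c(bg[1:3], bg[9:11]),        # 3 + 3 in-module targets
            boundary = c(bg[1:2], bg[9:12]),    # only 2 on one side
            scattered = bg[seq(20, 400, by = 40)]),
        type = c(good = "TF", boundary = "TF", scattered = "miRNA"))
    pairs <- data.frame(moduleA = "inflammation_001",
                        moduleB = "cancer_001")
    res <- findPivots(map, pairs, list(modA, modB), bg)
    verdict <- setNames(res$isPivot, res$regulator)
    expect_true(verdict[["good"]])
    expect_false(verdict[["boundary"]])   # 2 targets: rejected by >2 rule
    expect_false(verdict[["scattered"]])
    expect_lt(res$pA[res$regulator == "good"], 0.05)
    # verdicts invariant to target-list ordering
    map2 <- RegulatorTargetMap(
        targets = lapply(regulatorTargets(map), rev),
        type = regulatorType(map))
    res2 <- findPivots(map2, pairs, list(modA, modB), bg)
    expect_identical(res2$isPivot[order(res2$regulator)],
                     res$isPivot[order(res$regulator)])
})

test_that("planted pivots are recovered and decoys rejected", {
    det <- rej <- numeric()
    for (s in 1:5) {
        syn <- generateSynthetic(syntheticConfig(rngSeed = s))
        truth <- syn$truth
        mods <- plantedModules(truth)
        pairs <- truth@truePivots[, c("moduleI", "moduleJ")]
        pv <- findPivots(syn$regulators, pairs, mods,
                         background = nodeIds(syn$interactome))
        key <- paste(pv$regulator, pv$moduleA, pv$moduleB)
        tkey <- paste(truth@truePivots$regulator,
                      truth@truePivots$moduleI, truth@truePivots$moduleJ)
        det <- c(det, mean(pv$isPivot[key %in% tkey]))
        decoys <- pv[!pv$regulator %in% truth@truePivots$regulator, ]
        rej <- c(rej, mean(!decoys$isPivot))
    }
    expect_equal(mean(det), 1)
    expect_gte(mean(rej), 0.95)
})
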