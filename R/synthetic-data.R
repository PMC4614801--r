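#' @include AllGenerics.R
NULL

#' Default planted-module layout
#'
#' Four modules per context with sizes between 8 and 12 genes and internal
#' density 0.8, matching the scale of complexes the detection stage is
#' expected to recover.
#' @keywords internal
.defaultPlantedModules <- function() {
    data.frame(
        size = c(10L, 12L, 8L, 10L, 10L, 12L, 8L, 10L),
        internalDensity = rep(0.8, 8L),
        context = rep(c("inflammation", "cancer"), each = 4L),
        stringsAsFactors = FALSE)
}

.defaultPlantedCrosstalk <- function() {
    # inflammation module 1 x cancer module 5, inflammation 2 x cancer 6
    data.frame(moduleI = c(1L, 2L), moduleJ = c(5L, 6L),
               extraInterEdges = c(12L, 12L))
}

.defaultPlantedPivots <- function() {
    data.frame(
        regulatorId = c("pivTF001", "pivTF002", "pivmiR001", "pivmiR002"),
        type = c("TF", "TF", "miRNA", "miRNA"),
        moduleI = c(1L, 2L, 1L, 2L),
        moduleJ = c(5L, 6L, 6L, 5L),
        targetsPerModule = rep(4L, 4L),
        stringsAsFactors = FALSE)
}

#' Construct a synthetic-data configuration
#'
#' See [SyntheticConfig-class] for the meaning of every field and the
#' rationale of the defaults.
#'
#' @param rngSeed integer seed.
#' @param nGenes,backgroundAttachment interactome size and
#'   preferential-attachment density.
#' @param plantedModules,plantedCrosstalk,plantedPivots data.frames as
#'   documented on the class; pass zero-row frames to disable planting.
#' @param nDatasetsPerContext,samplesPerGroup expression design.
#' @param degEffectSize,noiseSd planted effect (standardized) and noise SD.
#' @param backgroundDegFraction fraction of non-module genes additionally
#'   planted as DEGs per context.
#' @param nRegulators,decoyTargets decoy regulator layout.
#' @return a validated [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(rngSeed = 1, nGenes = 300)
#' cfg
#' @export
syntheticConfig <- function(rngSeed = 1L,
                            nGenes = 1000L,
                            backgroundAttachment = 3L,
                            plantedModules = .defaultPlantedModules(),
                            plantedCrosstalk = .defaultPlantedCrosstalk(),
                            nDatasetsPerContext = 3L,
                            samplesPerGroup = 20L,
                            degEffectSize = 5,
                            noiseSd = 1,
                            backgroundDegFraction = 0.3,
                            nRegulators = 100L,
                            decoyTargets = 10L,
                            plantedPivots = .defaultPlantedPivots()) {
    new("SyntheticConfig",
        rngSeed = as.integer(rngSeed), nGenes = as.integer(nGenes),
        backgroundAttachment = as.integer(backgroundAttachment),
        plantedModules = plantedModules,
        plantedCrosstalk = plantedCrosstalk,
        nDatasetsPerContext = as.integer(nDatasetsPerContext),
        samplesPerGroup = as.integer(samplesPerGroup),
        degEffectSize = as.numeric(degEffectSize),
        noiseSd = as.numeric(noiseSd),
        backgroundDegFraction = as.numeric(backgroundDegFraction),
        nRegulators = as.integer(nRegulators),
        decoyTargets = as.integer(decoyTargets),
        plantedPivots = plantedPivots)
}

# pair key for an integer edge (i, j), i != j, within an n-vertex graph
.edgeKey <- function(i, j, n) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    (lo - 1) * n + hi
}

#' Generate a synthetic interactome with planted structure
#'
#' Builds a degree-heterogeneous background by preferential attachment,
#' then overlays planted modules by adding internal edges until each
#' module's induced density reaches its configured value (edges are never
#' removed, so configured densities are lower bounds), connects any
#' module that remains disconnected, and finally plants crosstalk by
#' adding the configured number of extra edges between non-shared members
#' of each designated module pair. All edges carry score 1.0.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with elements \code{interactome} ([Interactome-class]) and
#'   \code{truth} ([PlantedTruth-class]).
#' @examples
#' out <- generateInteractome(syntheticConfig(rngSeed = 7, nGenes = 200))
#' out$interactome
#' @export
generateInteractome <- function(config) {
    validObject(config)
    set.seed(config@rngSeed)
    n <- config@nGenes
    genes <- sprintf("g%04d", seq_len(n))

    bg <- igraph::sample_pa(n, m = config@backgroundAttachment,
                            directed = FALSE)
    bg <- igraph::simplify(bg)
    el <- igraph::as_edgelist(bg, names = FALSE)
    # random placement of gene ids over the attachment order so hubs are
    # not systematically the lexicographically smallest ids
    perm <- sample.int(n)
    ei <- perm[el[, 1L]]; ej <- perm[el[, 2L]]
    keys <- .edgeKey(ei, ej, n)
    edges <- cbind(pmin(ei, ej), pmax(ei, ej))

    pm <- config@plantedModules
    memberIdx <- list()
    if (nrow(pm)) {
        if (any(pm$internalDensity * choose(pm$size, 2) < pm$size - 1))
            stop("requested internal density infeasible for module size: ",
                 "a connected module of size s needs >= (s-1) edges")
        pool <- sample(seq_len(n))
        offset <- 0L
        for (m in seq_len(nrow(pm))) {
            memberIdx[[m]] <- sort(pool[(offset + 1L):(offset + pm$size[m])])
            offset <- offset + pm$size[m]
        }
        for (m in seq_len(nrow(pm))) {
            mem <- memberIdx[[m]]
            pairs <- utils::combn(mem, 2L)
            pk <- .edgeKey(pairs[1L, ], pairs[2L, ], n)
            required <- ceiling(pm$internalDensity[m] * ncol(pairs))
            present <- pk %in% keys
            need <- required - sum(present)
            if (need > 0L) {
                pick <- sample(which(!present), need)
                edges <- rbind(edges, t(pairs[, pick, drop = FALSE]))
                keys <- c(keys, pk[pick])
            }
            # enforce connectivity: join components with extra edges
            selPairs <- pairs[, pk %in% keys, drop = FALSE]
            sub <- igraph::graph_from_edgelist(
                cbind(match(selPairs[1L, ], mem),
                      match(selPairs[2L, ], mem)), directed = FALSE)
            sub <- igraph::add_vertices(sub,
                                        max(0L, length(mem) -
                                                igraph::vcount(sub)))
            comp <- igraph::components(sub)
            while (comp$no > 1L) {
                a <- mem[sample(which(comp$membership == 1L), 1L)]
                b <- mem[sample(which(comp$membership == 2L), 1L)]
                edges <- rbind(edges, c(min(a, b), max(a, b)))
                keys <- c(keys, .edgeKey(a, b, n))
                sub <- igraph::add_edges(sub, match(c(a, b), mem))
                comp <- igraph::components(sub)
            }
        }
    }

    pc <- config@plantedCrosstalk
    crossRows <- list()
    if (nrow(pc)) {
        moduleIds <- sprintf("M%02d", seq_len(nrow(pm)))
        for (r in seq_len(nrow(pc))) {
            a <- setdiff(memberIdx[[pc$moduleI[r]]],
                         memberIdx[[pc$moduleJ[r]]])
            b <- setdiff(memberIdx[[pc$moduleJ[r]]],
                         memberIdx[[pc$moduleI[r]]])
            cand <- expand.grid(a = a, b = b)
            ck <- .edgeKey(cand$a, cand$b, n)
            free <- which(!ck %in% keys)
            extra <- pc$extraInterEdges[r]
            if (length(free) < extra)
                stop("cannot plant ", extra, " extra inter-edges: only ",
                     length(free), " non-adjacent cross pairs available")
            pick <- sample(free, extra)
            edges <- rbind(edges,
                           cbind(pmin(cand$a[pick], cand$b[pick]),
                                 pmax(cand$a[pick], cand$b[pick])))
            keys <- c(keys, ck[pick])
            total <- sum(.edgeKey(cand$a, cand$b, n) %in% keys)
            crossRows[[r]] <- data.frame(
                moduleI = moduleIds[pc$moduleI[r]],
                moduleJ = moduleIds[pc$moduleJ[r]],
                extraAdded = extra, interEdges = total,
                stringsAsFactors = FALSE)
        }
    }

    g <- igraph::graph_from_edgelist(
        cbind(genes[edges[, 1L]], genes[edges[, 2L]]), directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g),
                              name = setdiff(genes, igraph::V(g)$name))
    g <- igraph::permute(g, match(igraph::V(g)$name,
                                  sort(igraph::V(g)$name)))
    igraph::E(g)$score <- 1.0
    net <- Interactome(g)

    moduleIds <- if (nrow(pm)) sprintf("M%02d", seq_len(nrow(pm)))
                 else character()
    moduleMembers <- lapply(memberIdx, function(idx) genes[idx])
    names(moduleMembers) <- moduleIds
    moduleContext <- setNames(as.character(pm$context), moduleIds)

    # planted DEGs: members of a context's planted modules plus a fraction
    # of the remaining genes, each with a fixed per-gene direction shared
    # by every dataset of that context
    trueDEGs <- lapply(c(inflammation = "inflammation", cancer = "cancer"),
        function(ctx) {
        gs <- sort(unique(unlist(moduleMembers[moduleContext == ctx],
                                 use.names = FALSE)))
        rest <- setdiff(genes, gs)
        nExtra <- floor(config@backgroundDegFraction * length(rest))
        if (nExtra > 0L) gs <- c(gs, sample(rest, nExtra))
        data.frame(gene = gs,
                   direction = if (length(gs))
                       sample(c("up", "down"), length(gs), replace = TRUE)
                   else character(),
                   stringsAsFactors = FALSE)
    })

    pp <- config@plantedPivots
    truePivots <- if (nrow(pp)) {
        data.frame(regulator = pp$regulatorId, type = pp$type,
                   moduleI = moduleIds[pp$moduleI],
                   moduleJ = moduleIds[pp$moduleJ],
                   stringsAsFactors = FALSE)
    } else {
        data.frame(regulator = character(), type = character(),
                   moduleI = character(), moduleJ = character(),
                   stringsAsFactors = FALSE)
    }

    crosstalkPairs <- if (length(crossRows)) do.call(rbind, crossRows)
        else data.frame(moduleI = character(), moduleJ = character(),
                        extraAdded = integer(), interEdges = integer(),
                        stringsAsFactors = FALSE)

    truth <- new("PlantedTruth", moduleMembers = moduleMembers,
                 moduleContext = moduleContext, trueDEGs = trueDEGs,
                 truePivots = truePivots, crosstalkPairs = crosstalkPairs,
                 genes = genes)
    list(interactome = net, truth = truth)
}

#' Generate synthetic expression datasets
#'
#' For each context, draws \code{nDatasetsPerContext} datasets of
#' \code{2 * samplesPerGroup} samples. Non-DEG genes are Gaussian noise
#' around a common baseline; planted DEGs (the context's planted module
#' members) have their disease-group mean shifted by
#' \code{degEffectSize * noiseSd} in the direction fixed in the truth,
#' identically across all datasets of the context.
#'
#' @param config a [SyntheticConfig-class].
#' @param truth the [PlantedTruth-class] from [generateInteractome()] run
#'   with the same config.
#' @return named list of [ExpressionDataset-class] objects.
#' @export
generateExpression <- function(config, truth) {
    validObject(config)
    if (config@samplesPerGroup < 2L)
        stop("samplesPerGroup must be >= 2: within-group variance undefined")
    set.seed(config@rngSeed + 1L)
    genes <- truth@genes
    s <- config@samplesPerGroup
    shift <- config@degEffectSize * config@noiseSd
    out <- list()
    for (ctx in c("inflammation", "cancer")) {
        degs <- truth@trueDEGs[[ctx]]
        for (d in seq_len(config@nDatasetsPerContext)) {
            id <- sprintf("%s_ds%d", ctx, d)
            vals <- matrix(stats::rnorm(length(genes) * 2L * s,
                                        sd = config@noiseSd),
                           nrow = length(genes),
                           dimnames = list(genes,
                               sprintf("%s_s%02d", id, seq_len(2L * s))))
            groups <- rep(c("disease", "normal"), each = s)
            if (nrow(degs)) {
                delta <- ifelse(degs$direction == "up", shift, -shift)
                vals[degs$gene, groups == "disease"] <-
                    vals[degs$gene, groups == "disease"] + delta
            }
            out[[id]] <- ExpressionDataset(vals, groups, id)
        }
    }
    out
}

#' Generate a synthetic regulator-target map
#'
#' Planted pivot regulators receive \code{targetsPerModule} targets sampled
#' from each of their two planted modules plus \code{decoyTargets} genes
#' drawn from the whole gene universe; decoy regulators draw
#' \code{decoyTargets} targets uniformly from the universe. TF and miRNA
#' decoys are generated in equal numbers.
#'
#' @inheritParams generateExpression
#' @return a [RegulatorTargetMap-class].
#' @export
generateRegulatorMap <- function(config, truth) {
    validObject(config)
    set.seed(config@rngSeed + 2L)
    genes <- truth@genes
    targets <- list(); type <- character()
    pp <- config@plantedPivots
    for (r in seq_len(nrow(pp))) {
        memI <- truth@moduleMembers[[sprintf("M%02d", pp$moduleI[r])]]
        memJ <- truth@moduleMembers[[sprintf("M%02d", pp$moduleJ[r])]]
        k <- pp$targetsPerModule[r]
        if (k > length(memI) || k > length(memJ))
            stop("targetsPerModule exceeds planted module size")
        tg <- unique(c(sample(memI, k), sample(memJ, k),
                       sample(genes, config@decoyTargets)))
        targets[[pp$regulatorId[r]]] <- sort(tg)
        type[pp$regulatorId[r]] <- pp$type[r]
    }
    nTF <- ceiling(config@nRegulators / 2)
    decoyIds <- c(sprintf("TF%03d", seq_len(nTF)),
                  sprintf("miR%03d", seq_len(config@nRegulators - nTF)))
    decoyTypes <- rep(c("TF", "miRNA"),
                      c(nTF, config@nRegulators - nTF))
    for (i in seq_along(decoyIds)) {
        targets[[decoyIds[i]]] <- sort(sample(genes, config@decoyTargets))
        type[decoyIds[i]] <- decoyTypes[i]
    }
    RegulatorTargetMap(targets, type,
                       setNames(rep("synthetic", length(targets)),
                                names(targets)))
}

#' Generate every synthetic artifact in one call
#'
#' @param config a [SyntheticConfig-class].
#' @return list with elements \code{interactome}, \code{truth},
#'   \code{expression} (named list of [ExpressionDataset-class]) and
#'   \code{regulators} ([RegulatorTargetMap-class]).
#' @examples
#' syn <- generateSynthetic(syntheticConfig(rngSeed = 3, nGenes = 200))
#' names(syn)
#' @export
generateSynthetic <- function(config) {
    net <- generateInteractome(config)
    expr <- generateExpression(config, net$truth)
    reg <- generateRegulatorMap(config, net$truth)
    list(interactome = net$interactome, truth = net$truth,
         expression = expr, regulators = reg)
}

#' Planted modules of a truth object as GeneModule objects
#'
#' @param truth a [PlantedTruth-class].
#' @return list of [GeneModule-class], one per planted module.
#' @export
plantedModules <- function(truth) {
    ids <- names(truth@moduleMembers)
    lapply(ids, function(id)
        GeneModule(id, truth@moduleContext[[id]],
                   truth@moduleMembers[[id]]))
}
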