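#' @include AllGenerics.R
NULL

.groupIndices <- function(dataset) {
    grp <- groupLabels(dataset)
    list(disease = which(grp == "disease"), normal = which(grp == "normal"))
}

# gene-wise pooled standard error of the two-group mean difference:
# s_i = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))
.pooledSe <- function(x, idx) {
    n1 <- length(idx$disease); n2 <- length(idx$normal)
    x1 <- x[, idx$disease, drop = FALSE]
    x2 <- x[, idx$normal, drop = FALSE]
    ss1 <- rowSums((x1 - rowMeans(x1))^2)
    ss2 <- rowSums((x2 - rowMeans(x2))^2)
    sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
}

#' SAM-style relative-difference statistic
#'
#' For each gene, d = (mean(disease) - mean(normal)) / (s + s0), where s is
#' the pooled standard error of the mean difference and s0 is a small
#' positive "fudge" constant that stabilizes genes with tiny variance. The
#' default s0 is the median of the gene-wise pooled standard errors.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param s0 non-negative fudge constant; \code{NULL} (default) uses the
#'   median pooled standard error of the dataset.
#' @param zeroSe how to treat genes with zero pooled standard error when
#'   \code{s0 = 0}: \code{"error"} stops, \code{"infinite"} returns signed
#'   infinities (0/0 for equal means becomes 0).
#' @return named numeric vector of d statistics, positive when the disease
#'   mean exceeds the normal mean.
#' @examples
#' m <- rbind(gA = c(4, 5, 6, 1, 2, 3), gB = c(1, 1, 2, 1, 1, 2))
#' colnames(m) <- paste0("s", 1:6)
#' eds <- ExpressionDataset(m, rep(c("disease", "normal"), each = 3), "toy")
#' samStatistic(eds, s0 = 0)["gA"]  # 3 / sqrt(2/3) = 3.674
#' @export
samStatistic <- function(dataset, s0 = NULL,
                         zeroSe = c("error", "infinite")) {
    zeroSe <- match.arg(zeroSe)
    idx <- .groupIndices(dataset)
    if (length(idx$disease) < 2L || length(idx$normal) < 2L)
        stop("each group needs at least 2 samples")
    x <- SummarizedExperiment::assay(dataset, "exprs")
    se <- .pooledSe(x, idx)
    if (is.null(s0)) s0 <- stats::median(se)
    if (s0 < 0) stop("s0 must be non-negative")
    if (s0 == 0 && any(se == 0)) {
        if (zeroSe == "error")
            stop("zero within-group variance with s0 = 0 for gene(s): ",
                 paste(utils::head(rownames(x)[se == 0], 5), collapse = ", "))
    }
    num <- rowMeans(x[, idx$disease, drop = FALSE]) -
        rowMeans(x[, idx$normal, drop = FALSE])
    d <- num / (se + s0)
    d[num == 0 & se + s0 == 0] <- 0
    setNames(d, rownames(x))
}

# d statistics for a batch of label assignments, shared s0.
# assign: n-by-B logical matrix, TRUE = sample plays "disease".
.samStatisticBatch <- function(x, assign, n1, n2, s0) {
    x2 <- x^2
    m1 <- (x %*% assign) / n1
    m2 <- (x %*% (1 - assign)) / n2
    ss1 <- (x2 %*% assign) - n1 * m1^2
    ss2 <- (x2 %*% (1 - assign)) - n2 * m2^2
    ss1[ss1 < 0] <- 0; ss2[ss2 < 0] <- 0  # guard FP cancellation
    se <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
    (m1 - m2) / (se + s0)
}

#' Call differentially expressed genes at a target FDR
#'
#' Computes the SAM-style d statistic for every gene, estimates the null
#' distribution of |d| by permuting group labels (all distinct assignments
#' are enumerated when there are no more of them than \code{nPermutations};
#' otherwise random assignments are drawn), and selects the symmetric
#' threshold on |d| whose permutation-estimated FDR -- the median count of
#' permuted |d| values exceeding the threshold divided by the number of
#' called genes -- is at or below \code{fdrTarget}. Per-gene q-values are
#' the smallest estimated FDR among thresholds that call the gene.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param fdrTarget target false discovery rate in (0, 1); default 0.01.
#' @param nPermutations number of label permutations (at least 50).
#' @param rngSeed integer seed for the permutation draw.
#' @param s0 fudge constant passed to [samStatistic()].
#' @return data.frame with columns \code{gene}, \code{d}, \code{direction}
#'   (\code{"up"} when disease > normal), \code{q}; zero rows when no
#'   threshold achieves the target.
#' @export
callDEGs <- function(dataset, fdrTarget = 0.01, nPermutations = 100L,
                     rngSeed = 1L, s0 = NULL) {
    stopifnot(fdrTarget > 0, fdrTarget < 1)
    if (nPermutations < 50L) stop("nPermutations must be >= 50")
    idx <- .groupIndices(dataset)
    n1 <- length(idx$disease); n2 <- length(idx$normal)
    n <- n1 + n2
    x <- SummarizedExperiment::assay(dataset, "exprs")
    x <- x[, c(idx$disease, idx$normal), drop = FALSE]
    se <- .pooledSe(x, list(disease = seq_len(n1),
                            normal = n1 + seq_len(n2)))
    if (is.null(s0)) s0 <- stats::median(se)
    d <- samStatistic(dataset, s0 = s0)

    set.seed(rngSeed)
    nDistinct <- choose(n, n1)
    if (nDistinct <= nPermutations) {
        sets <- utils::combn(n, n1)
    } else {
        sets <- replicate(nPermutations, sample.int(n, n1))
    }
    assign <- matrix(0, nrow = n, ncol = ncol(sets))
    assign[cbind(as.vector(sets),
                 rep(seq_len(ncol(sets)), each = n1))] <- 1
    dPerm <- .samStatisticBatch(x, assign, n1, n2, s0)

    ord <- order(abs(d), decreasing = TRUE)
    thresholds <- abs(d)[ord]
    absPermSorted <- sort(abs(as.vector(dPerm)))
    B <- ncol(dPerm)
    # median over permutations of the per-permutation exceedance count;
    # counts per permutation computed against each candidate threshold
    exceed <- matrix(0L, nrow = length(thresholds), ncol = B)
    for (b in seq_len(B)) {
        v <- sort(abs(dPerm[, b]))
        exceed[, b] <- length(v) - findInterval(thresholds, v,
                                                left.open = TRUE)
    }
    medExceed <- apply(exceed, 1L, stats::median)
    called <- seq_along(thresholds)
    fdrHat <- medExceed / called
    q <- rev(cummin(rev(pmin(fdrHat, 1))))
    keep <- q <= fdrTarget
    if (!any(keep)) {
        message("callDEGs [", datasetId(dataset),
                "]: no threshold achieves FDR <= ", fdrTarget)
        return(data.frame(gene = character(), d = numeric(),
                          direction = character(), q = numeric(),
                          stringsAsFactors = FALSE))
    }
    sel <- ord[keep]
    data.frame(gene = names(d)[sel], d = unname(d[sel]),
               direction = ifelse(d[sel] > 0, "up", "down"),
               q = q[keep], stringsAsFactors = FALSE)
}

#' Integrate DEG calls across datasets
#'
#' A gene enters the integrated set when (1) it is called in at least
#' \code{minSupport} datasets and (2) its dysregulation direction is the
#' same in every dataset that called it. Genes with any direction conflict
#' are excluded outright.
#'
#' @param tables named list (names = dataset ids) of DEG tables as returned
#'   by [callDEGs()].
#' @param context label stored on the result, e.g. \code{"inflammation"}.
#' @param minSupport minimum number of supporting datasets (default 2; use
#'   1 for a context backed by a single comparison).
#' @return an [IntegratedDEGSet-class].
#' @examples
#' t1 <- data.frame(gene = c("a", "b"), d = c(3, -2),
#'                  direction = c("up", "down"), q = c(0, 0))
#' t2 <- data.frame(gene = c("a", "b"), d = c(2, 2),
#'                  direction = c("up", "up"), q = c(0, 0))
#' integrateDEGs(list(ds1 = t1, ds2 = t2), "inflammation")  # only "a"
#' @export
integrateDEGs <- function(tables, context, minSupport = 2L) {
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
        stop("tables must be a named list (names = dataset ids)")
    if (anyDuplicated(names(tables)))
        stop("duplicate dataset id: ",
             names(tables)[duplicated(names(tables))][1L])
    calls <- do.call(rbind, lapply(names(tables), function(id) {
        tab <- tables[[id]]
        if (nrow(tab) == 0L) return(NULL)
        data.frame(dataset = id, gene = tab$gene,
                   direction = tab$direction, stringsAsFactors = FALSE)
    }))
    direction <- character(); support <- list()
    if (!is.null(calls) && nrow(calls)) {
        byGene <- split(calls, calls$gene)
        for (g in names(byGene)) {
            rows <- byGene[[g]]
            if (nrow(rows) < minSupport) next
            if (length(unique(rows$direction)) != 1L) next
            direction[[g]] <- rows$direction[1L]
            support[[g]] <- rows$dataset
        }
    }
    new("IntegratedDEGSet", context = as.character(context),
        direction = direction, support = support)
}

#' Overlap between two gene sets
#'
#' Partitions the union of two integrated DEG sets (or plain gene id
#' vectors) into shared, first-only and second-only genes.
#'
#' @param a,b [IntegratedDEGSet-class] objects or character vectors.
#' @return list with elements \code{shared}, \code{aOnly}, \code{bOnly}
#'   (sorted character vectors).
#' @export
setOverlap <- function(a, b) {
    ga <- if (is(a, "IntegratedDEGSet")) moduleMembers(a) else as.character(a)
    gb <- if (is(b, "IntegratedDEGSet")) moduleMembers(b) else as.character(b)
    ga <- unique(ga); gb <- unique(gb)
    list(shared = sort(intersect(ga, gb)),
         aOnly = sort(setdiff(ga, gb)),
         bOnly = sort(setdiff(gb, ga)))
}
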