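#' @include AllGenerics.R
NULL

#' Read regulator-target tables
#'
#' Each file is a 2- or 3-column TSV (regulator, target\[, source\]).
#' Entries from all files are unioned; duplicate (regulator, target)
#' pairs collapse to one. Per-source pair counts are logged.
#'
#' @param paths character vector of file paths.
#' @param typeLabels character vector, one label (\code{"TF"} or
#'   \code{"miRNA"}) per file.
#' @return a [RegulatorTargetMap-class]; empty files produce a warning.
#' @export
readRegulatorMap <- function(paths, typeLabels) {
    stopifnot(length(paths) == length(typeLabels))
    if (!all(typeLabels %in% c("TF", "miRNA")))
        stop("typeLabels must be 'TF' or 'miRNA'")
    rows <- list()
    for (i in seq_along(paths)) {
        if (!file.exists(paths[i])) stop("file not found: ", paths[i])
        lines <- readLines(paths[i])
        lines <- lines[nzchar(lines)]
        if (length(lines) == 0L) {
            warning("empty regulator file: ", paths[i])
            next
        }
        parts <- strsplit(lines, "\t", fixed = TRUE)
        nf <- lengths(parts)
        if (any(nf < 2L))
            stop("malformed line ", which(nf < 2L)[1L], " in ", paths[i],
                 ": expected at least 2 tab-separated fields")
        src <- ifelse(nf >= 3L, vapply(parts, function(p)
            if (length(p) >= 3L) p[[3L]] else "", ""), basename(paths[i]))
        src[!nzchar(src)] <- basename(paths[i])
        rows[[i]] <- data.frame(
            regulator = vapply(parts, `[[`, "", 1L),
            target = vapply(parts, `[[`, "", 2L),
            type = typeLabels[i], source = src, stringsAsFactors = FALSE)
        message("readRegulatorMap: ", nrow(rows[[i]]), " pairs from ",
                basename(paths[i]))
    }
    if (length(rows) == 0L || all(vapply(rows, is.null, TRUE)))
        return(RegulatorTargetMap(list(), character()))
    all <- do.call(rbind, rows)
    all <- all[!duplicated(all[, c("regulator", "target")]), ]
    byReg <- split(all, all$regulator)
    targets <- lapply(byReg, function(d) sort(unique(d$target)))
    type <- vapply(byReg, function(d) d$type[1L], "")
    prov <- vapply(byReg, function(d)
        paste(sort(unique(d$source)), collapse = ";"), "")
    RegulatorTargetMap(targets, type, prov)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least the realized overlap between a
#' target set and a module, drawing \code{|targets in background|} genes
#' from a universe of \code{|background|} genes of which
#' \code{|module|} are successes. Targets outside the background are
#' ignored.
#'
#' @param targetSet character vector of target gene ids.
#' @param moduleMembers character vector of module gene ids (must be a
#'   subset of the background).
#' @param background character vector: the gene universe.
#' @return the p-value P(X >= overlap).
#' @examples
#' bg <- paste0("g", 1:10)
#' hypergeometricEnrichment(bg[1:5], bg[1:4], bg)  # 6/252
#' @export
hypergeometricEnrichment <- function(targetSet, moduleMembers, background) {
    background <- unique(background)
    if (length(background) == 0L) stop("background must be non-empty")
    moduleMembers <- unique(moduleMembers)
    if (!all(moduleMembers %in% background))
        stop("moduleMembers must be a subset of the background")
    draws <- unique(intersect(targetSet, background))
    k <- length(intersect(draws, moduleMembers))
    stats::phyper(k - 1, length(moduleMembers),
                  length(background) - length(moduleMembers),
                  length(draws), lower.tail = FALSE)
}

#' Identify pivot regulators of significant crosstalk pairs
#'
#' For every (regulator, significant module pair) combination, counts the
#' regulator's targets inside each module and tests each module's
#' enrichment with the upper-tail hypergeometric test against the
#' background universe. A regulator is a pivot of a pair when both
#' in-module target counts exceed \code{minTargets - 1} (the default
#' \code{minTargets = 3} encodes the "more than 2" rule) and both
#' p-values are below \code{alpha}.
#'
#' @param map a [RegulatorTargetMap-class].
#' @param crosstalk a [CrosstalkResults-class] (only significant pairs are
#'   evaluated) or a two-column data.frame/matrix of module id pairs.
#' @param modules named list of [GeneModule-class] objects covering every
#'   module id referenced by the pairs.
#' @param background character vector: gene universe for the test
#'   (conventionally the node set of the full filtered interactome).
#' @param minTargets minimum in-module targets per module (default 3,
#'   i.e. strictly more than 2).
#' @param alpha per-module hypergeometric significance level.
#' @param adjust apply Benjamini-Hochberg across regulators (per pair and
#'   module side) before applying \code{alpha}.
#' @return data.frame with one row per evaluated combination: columns
#'   \code{regulator}, \code{type}, \code{moduleA}, \code{moduleB},
#'   \code{targetsA}, \code{targetsB}, \code{pA}, \code{pB},
#'   \code{isPivot}.
#' @export
findPivots <- function(map, crosstalk, modules, background,
                       minTargets = 3L, alpha = 0.05, adjust = FALSE) {
    pairTab <- if (is(crosstalk, "CrosstalkResults")) {
        tab <- resultTable(crosstalk)
        tab[tab$significant, c("moduleA", "moduleB"), drop = FALSE]
    } else {
        as.data.frame(crosstalk, stringsAsFactors = FALSE)[, 1:2]
    }
    colnames(pairTab) <- c("moduleA", "moduleB")
    if (nrow(pairTab) == 0L) {
        message("findPivots: no significant pairs to evaluate")
        return(data.frame(regulator = character(), type = character(),
                          moduleA = character(), moduleB = character(),
                          targetsA = integer(), targetsB = integer(),
                          pA = numeric(), pB = numeric(),
                          isPivot = logical(), stringsAsFactors = FALSE))
    }
    moduleIds <- vapply(modules, moduleId, "")
    names(modules) <- moduleIds
    missing <- setdiff(unlist(pairTab), moduleIds)
    if (length(missing))
        stop("modules not supplied for pair ids: ",
             paste(missing, collapse = ", "))
    background <- unique(background)
    regs <- names(regulatorTargets(map))
    out <- vector("list", nrow(pairTab))
    for (i in seq_len(nrow(pairTab))) {
        memA <- intersect(moduleMembers(modules[[pairTab$moduleA[i]]]),
                          background)
        memB <- intersect(moduleMembers(modules[[pairTab$moduleB[i]]]),
                          background)
        rows <- lapply(regs, function(r) {
            tg <- intersect(regulatorTargets(map)[[r]], background)
            data.frame(
                regulator = r, type = regulatorType(map)[[r]],
                moduleA = pairTab$moduleA[i], moduleB = pairTab$moduleB[i],
                targetsA = length(intersect(tg, memA)),
                targetsB = length(intersect(tg, memB)),
                pA = hypergeometricEnrichment(tg, memA, background),
                pB = hypergeometricEnrichment(tg, memB, background),
                stringsAsFactors = FALSE)
        })
        out[[i]] <- do.call(rbind, rows)
    }
    res <- do.call(rbind, out)
    pA <- res$pA; pB <- res$pB
    if (adjust) {
        key <- paste(res$moduleA, res$moduleB)
        for (k in unique(key)) {
            sel <- key == k
            pA[sel] <- bhAdjust(pA[sel])
            pB[sel] <- bhAdjust(pB[sel])
        }
    }
    res$isPivot <- res$targetsA >= minTargets & res$targetsB >= minTargets &
        pA < alpha & pB < alpha
    rownames(res) <- NULL
    res
}
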