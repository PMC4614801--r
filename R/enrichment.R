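#' @include AllGenerics.R
NULL

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] used by every stage that reports
#' q-values, exposed so the adjustment applied across the package can be
#' checked in one place.
#'
#' @param p numeric vector of p-values.
#' @return vector of BH-adjusted q-values (monotone in sorted-p order,
#'   capped at 1).
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Read gene sets in GMT format
#'
#' Each line is tab-separated: term id, description, then one or more gene
#' ids. Duplicate genes within a line are collapsed; duplicate term ids
#' across lines are an error.
#'
#' @param path path to the GMT file.
#' @return an [AnnotationCollection-class].
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
        stop("malformed line ", which(nf < 3L)[1L], " in ", path,
             ": GMT needs term, description and at least one gene")
    terms <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(terms))
        stop("duplicate term id in ", path, ": ",
             terms[duplicated(terms)][1L])
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- terms
    descriptions <- setNames(vapply(parts, `[[`, "", 2L), terms)
    new("AnnotationCollection", sets = sets, descriptions = descriptions)
}

#' Hypergeometric gene-set enrichment with BH control
#'
#' For each annotation term, computes the upper-tail hypergeometric
#' p-value of the overlap between the query and the term's genes within
#' the background universe, then adjusts across all tested terms with
#' Benjamini-Hochberg. The query and every term are restricted to the
#' background first. Terms with zero overlap are reported (p = 1) rather
#' than skipped, so the term universe is stable across queries.
#'
#' @param query character vector of gene ids.
#' @param annotations an [AnnotationCollection-class].
#' @param background character vector: the gene universe.
#' @param fdrCutoff significance threshold on the BH-adjusted q (default
#'   0.05).
#' @return data.frame sorted by q ascending with columns \code{term},
#'   \code{description}, \code{k} (overlap), \code{K} (term size),
#'   \code{n} (query size), \code{N} (background size), \code{p},
#'   \code{q}, \code{significant}. Zero rows (with a warning) for an
#'   empty query.
#' @export
enrich <- function(query, annotations, background, fdrCutoff = 0.05) {
    background <- unique(background)
    if (length(background) == 0L) stop("background must be non-empty")
    query <- unique(intersect(query, background))
    sets <- lapply(geneSets(annotations),
                   function(s) unique(intersect(s, background)))
    empty <- data.frame(term = character(), description = character(),
                        k = integer(), K = integer(), n = integer(),
                        N = integer(), p = numeric(), q = numeric(),
                        significant = logical(), stringsAsFactors = FALSE)
    if (length(query) == 0L) {
        warning("enrich: empty query after background restriction")
        return(empty)
    }
    keep <- lengths(sets) > 0L
    sets <- sets[keep]
    if (length(sets) == 0L) return(empty)
    N <- length(background); n <- length(query)
    k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
    K <- lengths(sets)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    q <- bhAdjust(p)
    res <- data.frame(term = names(sets),
                      description = unname(
                          termDescriptions(annotations)[names(sets)]),
                      k = as.integer(k), K = as.integer(K),
                      n = n, N = N, p = unname(p), q = unname(q),
                      significant = unname(q) < fdrCutoff,
                      stringsAsFactors = FALSE)
    res <- res[order(res$q, res$p, res$term), ]
    rownames(res) <- NULL
    res
}
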