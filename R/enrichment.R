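#' @include AllClasses.R
NULL

.asMapList <- function(map) {
    if (is.data.frame(map)) {
        if (!all(c("category_id", "gene_id") %in% names(map)))
            stop("map must have columns category_id and gene_id")
        split(map$gene_id, map$category_id)
    } else as.list(map)
}

#' Filter functional categories by size within the analysis universe
#'
#' Memberships are first intersected with the universe, then categories
#' smaller than their kind's threshold are removed. "More than 10
#' regulatees" and "more than 30 genes" are read strictly, giving default
#' minimum sizes of 11 and 31; both are configurable.
#'
#' @param map data.frame (\code{category_id}, \code{gene_id}) or named list
#'   of gene-id vectors.
#' @param universe character vector of gene ids defining the analysis
#'   universe.
#' @param kind "regulon", "gene_category" or "module".
#' @param minRegulon,minCategory,minModule minimum member counts per kind.
#' @return named list of member vectors (the filtered map).
#' @export
filterCategories <- function(map, universe, kind = c("regulon",
                             "gene_category", "module"),
                             minRegulon = 11L, minCategory = 31L,
                             minModule = 1L) {
    kind <- match.arg(kind)
    lst <- .asMapList(map)
    lst <- lapply(lst, function(g) intersect(unique(g), universe))
    minSize <- switch(kind, regulon = minRegulon,
                      gene_category = minCategory, module = minModule)
    keep <- lst[lengths(lst) >= minSize]
    if (!length(keep)) stop("no category passes the size filter")
    keep
}

#' Binomial over-representation test with Bonferroni correction
#'
#' For a gene set of size n drawn from a universe of size M, a category with
#' m members in the universe yields an upper-tail binomial p-value
#' P(X >= x) with X ~ Binomial(n, m/M), where x is the observed overlap.
#' Bonferroni multiplies by the number of categories tested together.
#'
#' @param genes character vector (e.g. a DEG set), subset of
#'   \code{universe}; a \code{DEGSet} is also accepted.
#' @param map filtered category map (named list or 2-column data.frame).
#' @param universe character vector of gene ids.
#' @param alpha significance level on the Bonferroni scale.
#' @return data.frame with one row per category: x, n, m, M, p,
#'   p_bonferroni, significant.
#' @export
binomialEnrichment <- function(genes, map, universe, alpha = 0.05) {
    if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes
    genes <- unique(genes)
    if (!all(genes %in% universe))
        stop("gene set must be a subset of the universe")
    lst <- .asMapList(map)
    lst <- lapply(lst, function(g) intersect(unique(g), universe))
    M <- length(universe)
    n <- length(genes)
    if (M == 0) stop("empty universe")
    ncat <- length(lst)
    rows <- lapply(names(lst), function(id) {
        m <- length(lst[[id]])
        if (m == 0) stop("category ", id, " empty within the universe")
        x <- length(intersect(genes, lst[[id]]))
        p <- stats::pbinom(x - 1, n, m / M, lower.tail = FALSE)
        data.frame(category_id = id, x = x, n = n, m = m, M = M, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_bonferroni <- pmin(1, out$p * ncat)
    out$significant <- out$p_bonferroni <= alpha
    rownames(out) <- NULL
    out
}

#' Enrichment of DEG sets in co-expression modules
#'
#' Applies the binomial over-representation machinery with category = module
#' and set = the DEG set of each contrast; Bonferroni correction is over
#' modules x contrasts. Modules empty after intersection with the universe
#' are excluded with a warning.
#'
#' @param modules named list of module gene vectors, or a
#'   \linkS4class{ModuleAssignment} (module 0 ignored).
#' @param degSets named list of gene vectors (or \code{DEGSet}s), one per
#'   contrast.
#' @param universe character vector of gene ids.
#' @param alpha significance level on the Bonferroni scale.
#' @return data.frame with one row per (module, contrast).
#' @export
moduleDegEnrichment <- function(modules, degSets, universe, alpha = 0.05) {
    if (methods::is(modules, "ModuleAssignment")) {
        lab <- moduleLabels(modules)
        modules <- split(names(lab), lab)
        modules <- modules[names(modules) != "0"]
        names(modules) <- paste0("M", names(modules))
    }
    modules <- lapply(modules, function(g) intersect(unique(g), universe))
    empty <- lengths(modules) == 0
    if (any(empty)) {
        warning("excluding empty module(s): ",
                paste(names(modules)[empty], collapse = ", "))
        modules <- modules[!empty]
    }
    degSets <- lapply(degSets, function(s)
        if (is.list(s) && !is.null(s$genes)) s$genes else s)
    M <- length(universe)
    ntests <- length(modules) * length(degSets)
    rows <- list()
    for (ct in names(degSets)) {
        genes <- intersect(unique(degSets[[ct]]), universe)
        n <- length(genes)
        for (mod in names(modules)) {
            m <- length(modules[[mod]])
            x <- length(intersect(genes, modules[[mod]]))
            p <- stats::pbinom(x - 1, n, m / M, lower.tail = FALSE)
            rows[[length(rows) + 1L]] <-
                data.frame(module = mod, contrast = ct, x = x, n = n,
                           m = m, M = M, p = p, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$p_bonferroni <- pmin(1, out$p * ntests)
    out$significant <- out$p_bonferroni <= alpha
    rownames(out) <- NULL
    out
}
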