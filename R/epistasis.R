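#' @include AllClasses.R
NULL

#' Per-gene expression change between two conditions
#'
#' Difference of replicate-mean log expression, \code{condTo - condFrom},
#' over the experiment's gene set.
#'
#' @param x a \linkS4class{ReorgExperiment} (or a plain matrix with a
#'   \code{conditions} vector).
#' @param condFrom,condTo condition labels.
#' @param conditions optional per-sample condition labels when \code{x} is a
#'   matrix.
#' @return named numeric vector of per-gene changes, with attributes
#'   \code{from}, \code{to}.
#' @export
deltaProfile <- function(x, condFrom, condTo, conditions = NULL) {
    if (methods::is(x, "ReorgExperiment")) {
        conditions <- conditionLabels(x)
        m <- SummarizedExperiment::assay(x, "logexpr")
    } else m <- as.matrix(x)
    for (cc in c(condFrom, condTo))
        if (!any(conditions == cc)) stop("condition not present: ", cc)
    d <- rowMeans(m[, conditions == condTo, drop = FALSE]) -
         rowMeans(m[, conditions == condFrom, drop = FALSE])
    attr(d, "from") <- condFrom
    attr(d, "to") <- condTo
    d
}

#' Epistasis slope of simultaneous versus additive transcriptome change
#'
#' Regresses the per-gene simultaneous change y on the sum x of the two
#' single-interruption changes. The default model has no intercept, matching
#' the interceptless form y = alpha x, so alpha = sum(x y) / sum(x^2). An
#' intercept mode is available for sensitivity analysis. alpha = 1 is
#' additivity; alpha below/above 1 is negative/positive epistasis.
#'
#' @param simultaneous named numeric, the dual-interruption change per gene.
#' @param part1,part2 named numeric, the two single-interruption changes.
#' @param intercept fit an intercept (default \code{FALSE}).
#' @param tolerance classification half-width around 1.
#' @param contrast optional label such as "GS ~ G+S".
#' @return an \linkS4class{EpistasisResult}.
#' @export
epistasisSlope <- function(simultaneous, part1, part2, intercept = FALSE,
                           tolerance = 0.05, contrast = "") {
    ids <- names(simultaneous)
    if (!is.null(ids) && !is.null(names(part1))) {
        ids <- intersect(ids, intersect(names(part1), names(part2)))
        if (!length(ids)) stop("no shared genes")
        y <- simultaneous[ids]; x <- part1[ids] + part2[ids]
    } else {
        if (length(simultaneous) != length(part1) ||
            length(part1) != length(part2))
            stop("profiles must share their gene set")
        y <- simultaneous; x <- part1 + part2
    }
    if (length(y) < 3L) stop("at least 3 genes are required")
    if (all(x == 0)) stop("additive change identically zero: slope undefined")
    if (intercept) {
        fit <- stats::lm.fit(cbind(x = x, 1), y)
        alpha <- unname(fit$coefficients["x"])
        b0 <- unname(fit$coefficients[2])
        rss <- sum(fit$residuals^2)
    } else {
        alpha <- sum(x * y) / sum(x * x)
        b0 <- 0
        rss <- sum((y - alpha * x)^2)
    }
    methods::new("EpistasisResult", alpha = alpha, intercept = b0,
                 nGenes = length(y),
                 classification = classifyEpistasis(alpha, tolerance),
                 residualSS = rss, totalSS = sum(y^2),
                 contrast = as.character(contrast))
}

#' Classify an epistasis slope
#'
#' @param alpha finite slope.
#' @param tolerance half-width of the additive band around 1.
#' @return "additive" if |alpha - 1| <= tolerance, else "positive"
#'   (alpha > 1) or "negative" (alpha < 1).
#' @export
classifyEpistasis <- function(alpha, tolerance = 0.05) {
    if (!is.finite(alpha)) stop("alpha must be finite")
    if (abs(alpha - 1) <= tolerance) "additive"
    else if (alpha > 1) "positive" else "negative"
}

#' Epistasis analysis of all dual-interruption pairs
#'
#' Builds the single (G, S, E) and dual (GS, GE, ES) change profiles from the
#' 2x2x2 condition design and fits the epistasis slope for each requested
#' pair.
#'
#' @param x a \linkS4class{ReorgExperiment}.
#' @param pairs subset of c("GS", "GE", "ES").
#' @param stressor stressor label used in the condition names.
#' @param intercept,tolerance passed to \code{\link{epistasisSlope}}.
#' @return named list of \linkS4class{EpistasisResult} objects.
#' @export
epistasisAnalysis <- function(x, pairs = c("GS", "GE", "ES"),
                              stressor = "Thr", intercept = FALSE,
                              tolerance = 0.05) {
    ctr <- interruptionContrasts(stressor)
    deltas <- lapply(ctr, function(p) deltaProfile(x, p[1], p[2]))
    out <- lapply(pairs, function(pr) {
        parts <- strsplit(pr, "")[[1]]
        epistasisSlope(deltas[[pr]], deltas[[parts[1]]], deltas[[parts[2]]],
                       intercept = intercept, tolerance = tolerance,
                       contrast = sprintf("%s ~ %s+%s", pr, parts[1],
                                          parts[2]))
    })
    stats::setNames(out, pairs)
}
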