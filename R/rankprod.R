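#' @include AllClasses.R
NULL

#' Rank product statistics for a two-class comparison
#'
#' For each of the K = nA * nB one-vs-one cross-replicate comparisons, genes
#' are ranked by fold change (log-expression difference B - A): rank 1 for
#' the strongest up-regulation in B for the up statistic, and the reverse
#' ranking for down. The rank product is the geometric mean of a gene's
#' ranks, RP = (prod ranks)^(1/K), computed in log space. Ties receive
#' average ranks. Being rank-based, RP is invariant to any monotone
#' transform of expression.
#'
#' @param exprA,exprB genes-by-replicates log-expression matrices sharing
#'   rownames.
#' @return a \linkS4class{RankProdResult} with statistics only (p-values NA
#'   until \code{\link{rankProdSignificance}} is applied).
#' @export
rankProductStat <- function(exprA, exprB) {
    exprA <- as.matrix(exprA); exprB <- as.matrix(exprB)
    if (nrow(exprA) != nrow(exprB))
        stop("matrices must share their gene set")
    if (!is.null(rownames(exprA)) && !is.null(rownames(exprB)) &&
        !identical(rownames(exprA), rownames(exprB)))
        stop("matrices must share their gene set (rownames differ)")
    if (ncol(exprA) < 1L || ncol(exprB) < 1L)
        stop("at least one replicate per side is required")
    n <- nrow(exprA)
    K <- ncol(exprA) * ncol(exprB)
    logUp <- numeric(n); logDown <- numeric(n)
    for (a in seq_len(ncol(exprA))) {
        for (b in seq_len(ncol(exprB))) {
            fc <- exprB[, b] - exprA[, a]
            logUp <- logUp + log(rank(-fc, ties.method = "average"))
            logDown <- logDown + log(rank(fc, ties.method = "average"))
        }
    }
    ids <- rownames(exprA)
    if (is.null(ids)) ids <- sprintf("gene%d", seq_len(n))
    methods::new("RankProdResult", geneIds = ids,
                 rpUp = exp(logUp / K), rpDown = exp(logDown / K),
                 pUp = rep(NA_real_, n), pDown = rep(NA_real_, n),
                 pfpUp = rep(NA_real_, n), pfpDown = rep(NA_real_, n),
                 nComparisons = as.integer(K), nPermutations = 0L,
                 seed = NA_integer_, nullMethod = "none")
}

# Exact null: under within-comparison rank permutation the marginal rank of a
# gene in each comparison is uniform on 1..n and independent across
# comparisons, so the null RP distribution is that of the geometric mean of K
# iid uniform ranks; enumerate all n^K tuples.
.rpExactNull <- function(n, K) {
    grid <- do.call(expand.grid, rep(list(seq_len(n)), K))
    rowSums(log(as.matrix(grid)))        # log rank products
}

.rpPvals <- function(logRpK, nullLogRp) {
    # P(null <= observed), inclusive, with a tiny relative tolerance
    s <- sort(nullLogRp)
    counts <- findInterval(logRpK + 1e-9, s)
    counts / length(s)
}

#' Permutation or exact significance for rank products
#'
#' The null distribution of RP is generated by permuting ranks within each
#' comparison. When the number of per-gene rank tuples n^K is small (<=
#' \code{exactLimit}) the null is enumerated exactly; otherwise a seeded
#' Monte-Carlo permutation scheme pools null RPs across genes and
#' permutations, and p = (count + 1) / (total + 1) so p is never exactly 0.
#' pfp (proportion of false predictions) is p * n / rank(RP), made monotone
#' non-decreasing in RP order by a step-up pass.
#'
#' @param result a \linkS4class{RankProdResult}.
#' @param nPermutations Monte-Carlo permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @param exact "auto" (exact when n^K <= \code{exactLimit}), "always" or
#'   "never".
#' @param exactLimit tuple-count cap for the exact branch.
#' @return the result with \code{pUp}, \code{pDown}, \code{pfpUp},
#'   \code{pfpDown} filled in.
#' @export
rankProdSignificance <- function(result, nPermutations = 1000L, seed = 1L,
                                 exact = c("auto", "always", "never"),
                                 exactLimit = 1e5) {
    exact <- match.arg(exact)
    n <- length(result@geneIds)
    K <- result@nComparisons
    useExact <- switch(exact,
                       always = TRUE,
                       never = FALSE,
                       auto = n^K <= exactLimit)
    if (useExact) {
        nullLog <- .rpExactNull(n, K)
        pUp <- .rpPvals(K * log(result@rpUp), nullLog)
        pDown <- .rpPvals(K * log(result@rpDown), nullLog)
        result@nPermutations <- 0L
        result@seed <- NA_integer_
        result@nullMethod <- "exact"
    } else {
        if (nPermutations < 100L)
            stop("at least 100 permutations are required")
        set.seed(seed)
        nullLog <- numeric(nPermutations * n)
        for (b in seq_len(nPermutations)) {
            lr <- numeric(n)
            for (k in seq_len(K)) lr <- lr + log(sample.int(n))
            nullLog[((b - 1L) * n + 1L):(b * n)] <- lr
        }
        s <- sort(nullLog)
        pUp <- (findInterval(K * log(result@rpUp) + 1e-9, s) + 1) /
               (length(s) + 1)
        pDown <- (findInterval(K * log(result@rpDown) + 1e-9, s) + 1) /
                 (length(s) + 1)
        result@nPermutations <- as.integer(nPermutations)
        result@seed <- as.integer(seed)
        result@nullMethod <- "permutation"
    }
    stepUp <- function(p, rp) {
        r <- rank(rp, ties.method = "first")
        raw <- p * n / r
        ord <- order(rp)
        raw[ord] <- cummax(raw[ord])
        pmin(1, raw)                    # clipped to the report scale
    }
    result@pUp <- pUp
    result@pDown <- pDown
    result@pfpUp <- stepUp(pUp, result@rpUp)
    result@pfpDown <- stepUp(pDown, result@rpDown)
    result
}

#' Call differentially expressed genes from rank product statistics
#'
#' A gene's direction is the smaller of its up/down rank products; it is
#' called differentially expressed when the pfp of that direction is at or
#' below the FDR threshold.
#'
#' @param result a \linkS4class{RankProdResult} with significance filled in.
#' @param fdrThreshold pfp cut-off (default 0.05).
#' @param contrast optional contrast label.
#' @return a \code{DEGSet}: list with \code{genes}, \code{direction} (named
#'   "up"/"down"), \code{universe}, \code{contrast}, \code{method},
#'   \code{threshold}.
#' @export
callDegs <- function(result, fdrThreshold = 0.05, contrast = "") {
    if (anyNA(result@pfpUp))
        stop("run rankProdSignificance first")
    up <- result@rpUp <= result@rpDown
    pfp <- ifelse(up, result@pfpUp, result@pfpDown)
    sel <- pfp <= fdrThreshold
    out <- list(genes = result@geneIds[sel],
                direction = stats::setNames(ifelse(up[sel], "up", "down"),
                                            result@geneIds[sel]),
                universe = result@geneIds,
                contrast = contrast, method = result@nullMethod,
                threshold = fdrThreshold)
    class(out) <- "DEGSet"
    out
}

#' @export
print.DEGSet <- function(x, ...) {
    cat("DEGSet", if (nzchar(x$contrast)) paste0("(", x$contrast, ")") else "",
        ":", length(x$genes), "of", length(x$universe),
        "genes at pfp <=", x$threshold, "\n")
    if (length(x$genes))
        cat("  up:", sum(x$direction == "up"),
            " down:", sum(x$direction == "down"), "\n")
    invisible(x)
}

#' Overlap structure of several DEG sets
#'
#' Counts every Venn intersection region over a shared gene universe and the
#' pairwise overlap fractions |A and B| / min(|A|, |B|).
#'
#' @param sets list of 2 or more \code{DEGSet} objects (or character vectors
#'   plus a \code{universe}).
#' @param universe required when \code{sets} are plain vectors.
#' @return list with \code{regions} (named counts, names like "A&B") and
#'   \code{pairwise} (fraction matrix).
#' @export
degOverlap <- function(sets, universe = NULL) {
    if (length(sets) < 2L) stop("at least 2 sets are required")
    nm <- names(sets)
    if (is.null(nm)) nm <- LETTERS[seq_along(sets)]
    genes <- lapply(sets, function(s) if (is.list(s)) s$genes else s)
    if (is.null(universe)) {
        unis <- lapply(sets, function(s)
            if (is.list(s)) s$universe else stop("universe required"))
        for (u in unis[-1])
            if (!setequal(u, unis[[1]])) stop("universe mismatch between sets")
        universe <- unis[[1]]
    }
    for (g in genes)
        if (!all(g %in% universe)) stop("set contains genes outside universe")
    member <- vapply(genes, function(g) universe %in% g,
                     logical(length(universe)))
    colnames(member) <- nm
    inUnion <- rowSums(member) > 0
    pat <- apply(member[inUnion, , drop = FALSE], 1, function(r)
        paste(nm[r], collapse = "&"))
    regions <- table(pat)
    k <- length(sets)
    pw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        denom <- min(length(genes[[i]]), length(genes[[j]]))
        pw[i, j] <- if (denom == 0) NA_real_
                    else length(intersect(genes[[i]], genes[[j]])) / denom
    }
    list(regions = c(regions), pairwise = pw)
}

#' Per-gene Welch test differential expression (substitute branch)
#'
#' A labeled substitute for count-model differential expression: per-gene
#' two-sided Welch t-test between the two replicate groups on log
#' expression, Benjamini-Hochberg adjusted. The rank product branch is the
#' primary method; this utility exists for cross-checking on designs with
#' enough replicates.
#'
#' @param exprA,exprB genes-by-replicates log-expression matrices (>= 2
#'   replicates each).
#' @param fdrThreshold BH-adjusted p cut-off.
#' @return data.frame with per-gene difference, p, adjusted p, direction and
#'   call.
#' @export
welchDeTest <- function(exprA, exprB, fdrThreshold = 0.05) {
    if (ncol(exprA) < 2L || ncol(exprB) < 2L)
        stop("at least 2 replicates per side are required")
    p <- vapply(seq_len(nrow(exprA)), function(i)
        welchCompare(exprA[i, ], exprB[i, ]), numeric(1))
    diffmean <- rowMeans(exprB) - rowMeans(exprA)
    padj <- stats::p.adjust(p, method = "BH")
    data.frame(gene_id = rownames(exprA), diff = diffmean, p = p,
               p_adj = padj,
               direction = ifelse(diffmean >= 0, "up", "down"),
               significant = padj <= fdrThreshold,
               stringsAsFactors = FALSE)
}
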