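#' @include AllClasses.R
NULL

#' Unsigned co-expression adjacency
#'
#' a_ij = |cor(gene_i, gene_j)|^beta with Pearson correlation and a_ii = 1.
#'
#' @param expr genes-by-samples matrix or \linkS4class{ReorgExperiment}.
#' @param beta soft-thresholding power (>= 1).
#' @return symmetric adjacency matrix.
#' @export
adjacencyMatrix <- function(expr, beta = 12) {
    m <- .exprMatrix(expr)
    if (ncol(m) < 3L) stop("at least 3 samples are required")
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0))
        stop("constant gene: ", rownames(m)[which(sds == 0)[1]])
    a <- .elemPower(abs(stats::cor(t(m))), beta)
    diag(a) <- 1
    a
}

# elementwise power by repeated squaring for integer exponents (the ^
# operator is slow on large dense matrices)
.elemPower <- function(x, beta) {
    if (beta != round(beta)) return(x^beta)
    e <- as.integer(beta)
    out <- NULL
    sq <- x
    while (e > 0L) {
        if (e %% 2L == 1L) out <- if (is.null(out)) sq else out * sq
        e <- e %/% 2L
        if (e > 0L) sq <- sq * sq
    }
    out
}

.scaleFreeFit <- function(k, nBins = 10L) {
    k <- k[k > 0]
    if (!length(k)) return(list(r2 = NA_real_, table = NULL))
    br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = nBins + 1)))
    if (length(br) < 3L) return(list(r2 = NA_real_, table = NULL))
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    cnt <- tabulate(bin, nbins = nlevels(bin))
    width <- diff(br)
    dens <- cnt / (length(k) * width)
    mk <- tapply(k, bin, mean)
    ok <- cnt > 0 & dens > 0 & is.finite(mk)
    if (sum(ok) < 2L) stop("fewer than 2 nonempty connectivity bins")
    fit <- stats::lm(log10(dens[ok]) ~ log10(mk[ok]))
    list(r2 = summary(fit)$r.squared,
         table = data.frame(k = as.numeric(mk[ok]),
                            density = as.numeric(dens[ok])))
}

#' Pick the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the connectivity k_i = sum_j a_ij (j != i) is
#' computed and the scale-free fit is the R^2 of a log10 p(k) on log10 k
#' regression over equal-occupancy connectivity bins. The smallest candidate
#' reaching \code{r2Target} is returned; if none reaches it, the candidate
#' with the best fit is returned with \code{reachedTarget = FALSE}.
#'
#' @param expr genes-by-samples matrix or \linkS4class{ReorgExperiment}.
#' @param r2Target target fit (default 0.9).
#' @param candidatePowers integer candidates, scanned in order.
#' @param nBins connectivity bins for the fit.
#' @return list with \code{power}, \code{r2}, \code{fits} (R^2 per
#'   candidate) and \code{reachedTarget}.
#' @export
pickSoftPower <- function(expr, r2Target = 0.9, candidatePowers = 1:20,
                          nBins = 10L) {
    m <- .exprMatrix(expr)
    if (ncol(m) < 4L) stop("at least 4 samples are required")
    cc <- abs(stats::cor(t(m)))
    diag(cc) <- 0
    fits <- vapply(candidatePowers, function(b)
        .scaleFreeFit(rowSums(.elemPower(cc, b)), nBins)$r2, numeric(1))
    names(fits) <- candidatePowers
    reached <- which(!is.na(fits) & fits >= r2Target)
    if (length(reached)) {
        i <- reached[1]
        list(power = candidatePowers[i], r2 = fits[[i]], fits = fits,
             reachedTarget = TRUE)
    } else {
        i <- which.max(fits)
        warning("no candidate power reaches R^2 target ", r2Target)
        list(power = candidatePowers[i], r2 = fits[[i]], fits = fits,
             reachedTarget = FALSE)
    }
}

#' Topological overlap matrix
#'
#' Standard unsigned TOM:
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; TOM_ii = 1.
#'
#' @param expr genes-by-samples matrix or \linkS4class{ReorgExperiment}, or
#'   an adjacency matrix when \code{isAdjacency = TRUE}.
#' @param beta soft power used to build the adjacency.
#' @param isAdjacency treat \code{expr} as a ready adjacency matrix.
#' @return symmetric TOM similarity matrix in [0, 1].
#' @export
tomFromExpression <- function(expr, beta = 12, isAdjacency = FALSE) {
    a <- if (isAdjacency) as.matrix(expr) else adjacencyMatrix(expr, beta)
    L <- crossprod(a)               # sum_u a_iu a_uj, u over all genes
    l <- L - 2 * a                  # remove u = i and u = j terms (a_ii = 1)
    k <- rowSums(a) - 1
    km <- matrix(k, nrow(a), ncol(a))
    denom <- pmin(km, t(km)) + 1 - a
    tom <- (l + a) / denom
    diag(tom) <- 1
    tom[tom < 0] <- 0
    tom[tom > 1] <- 1
    dimnames(tom) <- dimnames(a)
    tom
}

#' Detect co-expression modules by adaptive tree cut
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' followed by a simplified adaptive cut: a static cut height is scanned over
#' a grid of merge-height quantiles and the height maximizing the number of
#' clusters of at least \code{minModuleSize} genes (ties: most genes
#' assigned, then lowest height) is kept. Clusters below the minimum size
#' are collected in module 0; module labels are ordered by decreasing size.
#' A final membership refinement then reassigns every gene by topological
#' overlap: a gene belongs to the module maximizing its mean TOM with the
#' module members, provided that mean reaches \code{memberFraction} of the
#' module's median intra-module overlap; genes reaching no module's bar are
#' left unassigned. This re-attaches peripheral members split off by the
#' static cut and expels weakly connected genes the cut happened to sweep
#' into a cluster.
#'
#' @param tom TOM similarity matrix.
#' @param minModuleSize minimum genes per module (default 50).
#' @param gridSize number of cut heights scanned.
#' @param memberFraction fraction of the median intra-module overlap a gene
#'   must reach to hold membership (0 disables the refinement).
#' @param maxCutHeight largest admissible cut height; clusters only forming
#'   at a dissimilarity of essentially 1 have no topological overlap and are
#'   noise, so heights above this bound are not scanned.
#' @return a \linkS4class{ModuleAssignment} (eigengenes empty until
#'   computed).
#' @export
detectModules <- function(tom, minModuleSize = 50L, gridSize = 40L,
                          memberFraction = 0.5, maxCutHeight = 0.99) {
    if (!isSymmetric(unname(tom), tol = 1e-8))
        stop("TOM must be symmetric")
    if (any(tom < -1e-8) || any(tom > 1 + 1e-8))
        stop("TOM values must lie in [0, 1]")
    h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
    hts <- stats::quantile(h$height, probs = seq(0.05, 0.999,
                                                 length.out = gridSize))
    hts <- hts[hts <= maxCutHeight]
    if (!length(hts))
        return(.relabelBySize(rep(0L, nrow(tom)), minModuleSize,
                              rownames(tom)))
    labMat <- stats::cutree(h, h = unique(hts))
    if (is.null(dim(labMat)))
        labMat <- matrix(labMat, ncol = 1,
                         dimnames = list(names(labMat), unique(hts)))
    best <- NULL
    for (ct in colnames(labMat)) {
        lab <- labMat[, ct]
        ct <- as.numeric(ct)
        sz <- table(lab)
        big <- sz[sz >= minModuleSize]
        score <- c(length(big), sum(big), -ct)
        if (is.null(best) ||
            score[1] > best$score[1] ||
            (score[1] == best$score[1] && score[2] > best$score[2]) ||
            (score[1] == best$score[1] && score[2] == best$score[2] &&
             score[3] > best$score[3]))
            best <- list(score = score, lab = lab)
    }
    ma <- .relabelBySize(best$lab, minModuleSize, rownames(tom))
    if (memberFraction > 0)
        ma <- .refineMembership(ma, tom, memberFraction, minModuleSize)
    ma
}

.refineMembership <- function(ma, tom, memberFraction, minModuleSize) {
    lab <- ma@labels
    k <- length(ma@sizes)
    if (!k) return(ma)
    meanTom <- vapply(seq_len(k), function(j) {
        memb <- which(lab == j)
        rowSums(tom[, memb, drop = FALSE]) / length(memb)
    }, numeric(nrow(tom)))
    intraMed <- vapply(seq_len(k), function(j)
        stats::median(meanTom[lab == j, j]), numeric(1))
    bestMod <- max.col(meanTom, ties.method = "first")
    bestVal <- meanTom[cbind(seq_len(nrow(tom)), bestMod)]
    newlab <- ifelse(bestVal >= memberFraction * intraMed[bestMod],
                     bestMod, 0L)
    .relabelBySize(newlab, minModuleSize, ids = names(lab))
}

.relabelBySize <- function(lab, minModuleSize, ids) {
    sz <- table(lab[lab != 0])          # label 0 is never a module
    big <- names(sz)[sz >= minModuleSize]
    ord <- big[order(-sz[big], as.numeric(big))]
    newlab <- integer(length(lab))
    for (i in seq_along(ord)) newlab[lab == ord[i]] <- i
    names(newlab) <- ids
    sizes <- as.integer(table(factor(newlab[newlab > 0],
                                     levels = seq_along(ord))))
    names(sizes) <- sprintf("M%d", seq_along(ord))
    methods::new("ModuleAssignment", labels = newlab,
                 eigengenes = matrix(numeric(0), 0, 0), sizes = sizes,
                 traitCor = data.frame(), classes = character(0))
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression across
#' samples, scaled to unit variance and sign-aligned so that its correlation
#' with the module's mean standardized profile is positive.
#'
#' @param expr genes-by-samples matrix or \linkS4class{ReorgExperiment}.
#' @param genes gene ids (or indices) of the module (>= 2 genes).
#' @return numeric eigengene, one value per sample.
#' @export
moduleEigengene <- function(expr, genes) {
    m <- .exprMatrix(expr)[genes, , drop = FALSE]
    if (nrow(m) < 2L) stop("module must contain at least 2 genes")
    sds <- apply(m, 1, stats::sd)
    if (all(sds == 0)) stop("singular module: all genes constant")
    m <- m[sds > 0, , drop = FALSE]
    z <- t(scale(t(m)))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    ref <- colMeans(z)
    if (stats::sd(ref) > 0 && stats::cor(e, ref) < 0) e <- -e
    e <- e / stats::sd(e)
    stats::setNames(e, colnames(m))
}

#' All module eigengenes of an assignment
#'
#' @param expr genes-by-samples matrix or \linkS4class{ReorgExperiment}.
#' @param assignment a \linkS4class{ModuleAssignment}.
#' @return the assignment with its eigengene matrix (samples x modules)
#'   filled in.
#' @export
moduleEigengenes <- function(expr, assignment) {
    lab <- moduleLabels(assignment)
    k <- length(moduleSizes(assignment))
    m <- .exprMatrix(expr)
    eg <- vapply(seq_len(k), function(j)
        moduleEigengene(m, names(lab)[lab == j]), numeric(ncol(m)))
    colnames(eg) <- paste0("M", seq_len(k))
    rownames(eg) <- colnames(m)
    assignment@eigengenes <- eg
    assignment
}

#' Merge modules with similar eigengenes
#'
#' Repeatedly merges the closest pair of modules whose eigengene
#' dissimilarity (1 - Pearson correlation) is below \code{mergeHeight},
#' recomputing eigengenes after each merge, until no pair qualifies. The
#' final labels are reordered by decreasing size. A second pass is a no-op.
#'
#' @param expr genes-by-samples matrix or \linkS4class{ReorgExperiment}.
#' @param assignment a \linkS4class{ModuleAssignment}.
#' @param mergeHeight dissimilarity threshold (default 0.25).
#' @return merged \linkS4class{ModuleAssignment} with eigengenes.
#' @export
mergeModules <- function(expr, assignment, mergeHeight = 0.25) {
    m <- .exprMatrix(expr)
    lab <- moduleLabels(assignment)
    repeat {
        k <- max(lab)
        if (k < 2L) break
        eg <- vapply(seq_len(k), function(j)
            moduleEigengene(m, names(lab)[lab == j]), numeric(ncol(m)))
        dis <- 1 - stats::cor(eg)
        diag(dis) <- Inf
        mn <- min(dis)
        if (mn >= mergeHeight) break
        ij <- which(dis == mn, arr.ind = TRUE)[1, ]
        keep <- min(ij); drop <- max(ij)
        lab[lab == drop] <- keep
        lab[lab > drop] <- lab[lab > drop] - 1L
    }
    out <- .relabelBySize(lab, minModuleSize = 1L, ids = names(lab))
    moduleEigengenes(m, out)
}

#' Correlate module eigengenes with a sample trait
#'
#' Pearson correlation of each eigengene with a per-sample trait (typically
#' the condition growth rate), with two-sided p-values from the
#' t-distribution and a significance flag at \code{alpha}.
#'
#' @param assignment a \linkS4class{ModuleAssignment} with eigengenes.
#' @param trait numeric trait, one value per sample.
#' @param alpha significance level (default 0.01).
#' @return the assignment with its \code{traitCor} data.frame filled in
#'   (columns module, r, p, significant).
#' @export
moduleTraitCorrelation <- function(assignment, trait, alpha = 0.01) {
    eg <- eigengenes(assignment)
    if (!nrow(eg)) stop("compute eigengenes first")
    if (length(trait) != nrow(eg))
        stop("trait must have one value per sample")
    if (stats::sd(trait) == 0) stop("constant trait")
    res <- do.call(rbind, lapply(colnames(eg), function(mod) {
        ct <- stats::cor.test(eg[, mod], trait)
        data.frame(module = mod, r = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
    }))
    res$significant <- res$p < alpha
    assignment@traitCor <- res
    assignment
}

#' Classify modules from their DEG enrichment pattern
#'
#' Using the (module x contrast) enrichment table over the single (G, S, E)
#' and dual (GS, GE, ES) interruption contrasts: a module enriched in no
#' contrast is \emph{conserved}; a module enriched in S but in neither GS
#' nor ES is \emph{epistatic} (its stress response vanishes under dual
#' interruption); any other module with at least one enrichment is
#' \emph{responsive}.
#'
#' @param enrichTable data.frame from \code{\link{moduleDegEnrichment}}.
#' @param assignment optional \linkS4class{ModuleAssignment} to annotate.
#' @param contrasts required contrast labels.
#' @return named character vector of class labels, or the annotated
#'   assignment when one is supplied.
#' @export
classifyModules <- function(enrichTable, assignment = NULL,
                            contrasts = c("G", "S", "E", "GS", "GE", "ES")) {
    miss <- setdiff(contrasts, unique(enrichTable$contrast))
    if (length(miss))
        stop("missing contrast(s): ", paste(miss, collapse = ", "))
    mods <- unique(enrichTable$module)
    cls <- vapply(mods, function(mod) {
        tt <- enrichTable[enrichTable$module == mod &
                          enrichTable$contrast %in% contrasts, ]
        sig <- tt$contrast[tt$significant]
        if (!length(sig)) "conserved"
        else if ("S" %in% sig && !("GS" %in% sig) && !("ES" %in% sig))
            "epistatic"
        else "responsive"
    }, character(1))
    names(cls) <- mods
    if (is.null(assignment)) return(cls)
    assignment@classes <- cls
    assignment
}

#' Full co-expression module pipeline
#'
#' Adjacency at the given soft power, TOM, adaptive tree cut, eigengene
#' computation and merging of close modules.
#'
#' @param expr genes-by-samples matrix or \linkS4class{ReorgExperiment}.
#' @param beta soft power (default 12).
#' @param minModuleSize minimum module size (default 50).
#' @param mergeHeight eigengene merge threshold (default 0.25).
#' @return a \linkS4class{ModuleAssignment} with eigengenes.
#' @export
coexpressionModules <- function(expr, beta = 12, minModuleSize = 50L,
                                mergeHeight = 0.25) {
    tom <- tomFromExpression(expr, beta = beta)
    ma <- detectModules(tom, minModuleSize = minModuleSize)
    ma <- moduleEigengenes(expr, ma)
    mergeModules(expr, ma, mergeHeight = mergeHeight)
}
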