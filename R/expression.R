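#' @include AllClasses.R
NULL

#' Convert read counts to FPKM
#'
#' FPKM = count * 1e9 / (gene_length_bp * total_sample_counts), a pure ratio
#' normalization by gene length (in kb) and sequencing depth (in millions).
#'
#' @param counts genes-by-samples non-negative count matrix.
#' @param lengths gene lengths in bp (> 0), one per row.
#' @return numeric FPKM matrix with the same dimnames.
#' @export
computeFpkm <- function(counts, lengths) {
    counts <- as.matrix(counts)
    if (length(lengths) != nrow(counts))
        stop("lengths must have one value per gene")
    if (any(lengths <= 0)) stop("zero or negative gene length")
    if (any(counts < 0)) stop("counts must be non-negative")
    tot <- colSums(counts)
    if (any(tot <= 0)) stop("per-sample total counts must be > 0")
    sweep(counts * 1e9 / lengths, 2, tot, "/")
}

#' Log-transform and globally normalize FPKM
#'
#' Takes log10(FPKM + pseudocount) and then shifts each sample additively so
#' that every sample's mean equals the grand mean ("identical mean value on
#' the logarithmic scale"). An additive shift on the log scale is a
#' multiplicative rescaling of the linear values, so relative expression
#' within a sample is untouched. The default pseudocount is the smallest
#' nonzero FPKM in the matrix.
#'
#' @param fpkm non-negative FPKM matrix.
#' @param pseudocount positive constant added before the log; \code{NULL}
#'   for the data-driven default.
#' @return log10 expression matrix with attribute \code{normalized = TRUE}
#'   and the applied \code{pseudocount} and per-sample \code{shifts} as
#'   attributes.
#' @export
globalNormalizeLog <- function(fpkm, pseudocount = NULL) {
    fpkm <- as.matrix(fpkm)
    if (any(fpkm < 0)) stop("FPKM values must be non-negative")
    if (any(colSums(fpkm) == 0)) stop("all-zero sample")
    if (is.null(pseudocount)) {
        nz <- fpkm[fpkm > 0]
        pseudocount <- min(nz)
    }
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    if (pseudocount == 0 && any(fpkm == 0))
        stop("pseudocount 0 with zero FPKM values")
    x <- log10(fpkm + pseudocount)
    shifts <- mean(colMeans(x)) - colMeans(x)
    x <- sweep(x, 2, shifts, "+")
    attr(x, "normalized") <- TRUE
    attr(x, "pseudocount") <- pseudocount
    attr(x, "shifts") <- shifts
    x
}

#' Restrict a matrix to the genes common to several genomes
#'
#' Keeps the genes present in every supplied gene set, preserving the row
#' order of the reference matrix.
#'
#' @param x genes-by-samples matrix (rownames = gene ids) or
#'   \linkS4class{ReorgExperiment}.
#' @param geneSets list of character vectors of gene ids, one per genome.
#' @return \code{x} restricted to the intersection.
#' @export
commonGeneSubset <- function(x, geneSets) {
    common <- rownames(x)
    for (s in geneSets) common <- common[common %in% s]
    if (!length(common)) stop("empty gene intersection")
    x[common, , drop = FALSE]
}

.exprMatrix <- function(x) {
    if (methods::is(x, "ReorgExperiment"))
        SummarizedExperiment::assay(x, "logexpr")
    else as.matrix(x)
}

#' Hierarchical clustering of samples
#'
#' Distance is 1 - Spearman correlation between sample expression profiles;
#' agglomeration uses Ward's method on raw distances (ward.D2). Being
#' rank-based, the result is invariant to any monotone per-sample transform
#' of expression.
#'
#' @param x expression matrix (genes x samples) or
#'   \linkS4class{ReorgExperiment}.
#' @param k number of clusters for the label cut.
#' @return list with \code{hclust} and integer \code{labels}.
#' @export
sampleClustering <- function(x, k = 2L) {
    m <- .exprMatrix(x)
    if (ncol(m) < 2L) stop("at least 2 samples are required")
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0))
        stop("constant sample profile: ", colnames(m)[which(sds == 0)[1]])
    d <- stats::as.dist(1 - stats::cor(m, method = "spearman"))
    h <- stats::hclust(d, method = "ward.D2")
    list(hclust = h, labels = stats::cutree(h, k = k))
}

#' Principal component analysis of samples
#'
#' Centered, unscaled PCA of the sample profiles. For reproducible signs,
#' each component is flipped so that its largest-magnitude gene loading is
#' positive.
#'
#' @param x expression matrix (genes x samples) or
#'   \linkS4class{ReorgExperiment}.
#' @return list with \code{scores} (samples x PCs), \code{loadings}
#'   (genes x PCs) and \code{explained} (fraction of variance per PC).
#' @export
samplePca <- function(x) {
    m <- .exprMatrix(x)
    if (ncol(m) < 2L) stop("at least 2 samples are required")
    p <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    for (j in seq_len(ncol(p$rotation))) {
        i <- which.max(abs(p$rotation[, j]))
        if (p$rotation[i, j] < 0) {
            p$rotation[, j] <- -p$rotation[, j]
            p$x[, j] <- -p$x[, j]
        }
    }
    list(scores = p$x, loadings = p$rotation,
         explained = p$sdev^2 / sum(p$sdev^2))
}
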