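#' @include AllGenerics.R
NULL

#' ReorgExperiment: log-expression with condition design and gene coordinates
#'
#' A thin extension of
#' \linkS4class{RangedSummarizedExperiment} holding a genes-by-samples
#' log10-expression matrix in assay \code{"logexpr"}, per-sample design labels
#' (\code{genome}, \code{stress}, \code{evolved}, \code{replicate} and the
#' derived \code{condition}) in \code{colData}, and gene coordinates on the
#' circular chromosome as \code{rowRanges}. The genome length is stored in
#' \code{metadata(x)$genome_length} and a \code{metadata(x)$normalized} flag
#' records whether global normalization has been applied.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}.
#'
#' @export
setClass("ReorgExperiment", contains = "RangedSummarizedExperiment")

.validReorgExperiment <- function(object) {
    msg <- NULL
    if (!("logexpr" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'logexpr' is required")
    need <- c("genome", "stress", "evolved", "replicate", "condition")
    have <- colnames(SummarizedExperiment::colData(object))
    miss <- setdiff(need, have)
    if (length(miss))
        msg <- c(msg, paste0("missing colData column(s): ",
                             paste(miss, collapse = ", ")))
    norm <- S4Vectors::metadata(object)$normalized
    if (!is.null(norm) && isTRUE(norm)) {
        m <- colMeans(SummarizedExperiment::assay(object, "logexpr"))
        if (length(m) > 1L && diff(range(m)) > 1e-9)
            msg <- c(msg, "normalized flag set but per-sample means differ")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("ReorgExperiment", .validReorgExperiment)

#' Construct a ReorgExperiment
#'
#' @param logexpr numeric matrix, genes (rows) by samples (columns), on the
#'   log10 scale.
#' @param design data.frame with one row per sample and columns
#'   \code{genome}, \code{stress}, \code{evolved}, \code{replicate}.
#' @param annotation optional \code{GRanges} of gene coordinates, one range
#'   per row of \code{logexpr}, with a \code{gene_id} metadata column.
#' @param genomeLength length of the circular chromosome in bp; defaults to
#'   the annotation's seqlength when available.
#' @param normalized logical flag; \code{TRUE} after global normalization.
#'
#' @return a \linkS4class{ReorgExperiment}.
#' @export
ReorgExperiment <- function(logexpr, design, annotation = NULL,
                            genomeLength = NA_real_, normalized = FALSE) {
    logexpr <- as.matrix(logexpr)
    design <- as.data.frame(design)
    if (nrow(design) != ncol(logexpr))
        stop("design must have one row per sample")
    if (is.null(rownames(design)))
        rownames(design) <- colnames(logexpr)
    design$condition <- conditionLabel(design)
    if (is.null(annotation)) {
        annotation <- GenomicRanges::GRanges(
            seqnames = "chr",
            ranges = IRanges::IRanges(start = seq_len(nrow(logexpr)),
                                      width = 1L),
            gene_id = rownames(logexpr))
    }
    if (length(annotation) != nrow(logexpr))
        stop("annotation must have one range per gene")
    if (is.na(genomeLength)) {
        sl <- GenomeInfoDb::seqlengths(annotation)
        genomeLength <- if (length(sl) && !is.na(sl[1])) as.numeric(sl[1])
                        else NA_real_
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(logexpr = logexpr),
        rowRanges = annotation,
        colData = S4Vectors::DataFrame(design))
    obj <- methods::new("ReorgExperiment", se)
    S4Vectors::metadata(obj)$genome_length <- genomeLength
    S4Vectors::metadata(obj)$normalized <- normalized
    methods::validObject(obj)
    obj
}

#' Compose condition labels from design columns
#'
#' @param design data.frame with columns genome, stress, evolved.
#' @return character vector "genome.stress.evolved".
#' @export
conditionLabel <- function(design) {
    paste(design$genome, design$stress, design$evolved, sep = ".")
}

#' @rdname accessors
#' @export
setMethod("conditionLabels", "ReorgExperiment", function(object)
    as.character(SummarizedExperiment::colData(object)$condition))

#' @rdname accessors
#' @export
setMethod("isNormalized", "ReorgExperiment", function(object)
    isTRUE(S4Vectors::metadata(object)$normalized))

#' Genome length of a ReorgExperiment
#' @param object a ReorgExperiment.
#' @return numeric genome length in bp (may be NA).
#' @export
genomeLength <- function(object) {
    gl <- S4Vectors::metadata(object)$genome_length
    if (is.null(gl)) NA_real_ else gl
}

#' GrowthRateResult: windowed exponential growth rate
#'
#' Result of applying the three-point window rule to pointwise log-ratio
#' growth rates: the selected window's mean rate, its start index (1-based),
#' the three member rates and their variance.
#'
#' @slot mu numeric, growth rate (per hour).
#' @slot windowStart integer, 1-based index of the first rate in the window.
#' @slot windowRates numeric(3), the member rates.
#' @slot windowVariance numeric, variance of the member rates.
#'
#' @export
setClass("GrowthRateResult",
    representation(mu = "numeric", windowStart = "integer",
                   windowRates = "numeric", windowVariance = "numeric"))

setValidity("GrowthRateResult", function(object) {
    msg <- NULL
    if (length(object@windowRates) != 3L)
        msg <- c(msg, "window must contain exactly 3 consecutive rates")
    if (length(object@mu) == 1L && length(object@windowRates) == 3L &&
        abs(object@mu - mean(object@windowRates)) > 1e-12)
        msg <- c(msg, "mu must equal the mean of the window rates")
    if (is.null(msg)) TRUE else msg
})

#' @rdname accessors
#' @export
setMethod("growthRate", "GrowthRateResult", function(object) object@mu)

setMethod("show", "GrowthRateResult", function(object) {
    cat("GrowthRateResult: mu =", format(object@mu, digits = 4),
        "per hour\n  window start index:", object@windowStart,
        "\n  window rates:", paste(format(object@windowRates, digits = 4),
                                   collapse = ", "),
        "\n  window variance:", format(object@windowVariance, digits = 4),
        "\n")
})

#' PeriodicityResult: chromosomal periodicity of a transcriptome
#'
#' Holds the spatial expression profile along the circular chromosome, its
#' periodogram, the max-peak frequency and wavelength, the fitted cosine
#' parameters and Fisher's g-test of periodicity.
#'
#' @slot profile data.frame with columns \code{position} (bp) and
#'   \code{value} (smoothed mean log-expression).
#' @slot frequencies numeric, cycles per chromosome (1..floor(n/2)).
#' @slot power numeric, periodogram ordinates matching \code{frequencies}.
#' @slot maxPeakFrequency numeric, frequency of the largest ordinate.
#' @slot wavelength numeric, genome_length / maxPeakFrequency (bp).
#' @slot amplitude,phase,offset numeric, least-squares cosine fit
#'   A cos(2 pi x / wavelength + phase) + offset.
#' @slot fitted numeric, fitted curve at the profile positions.
#' @slot gStatistic numeric, max(power)/sum(power) over the tested ordinates.
#' @slot pValue numeric, exact Fisher g-test p-value.
#' @slot genomeLength numeric, bp.
#' @slot label character, condition or sample label.
#'
#' @export
setClass("PeriodicityResult",
    representation(profile = "data.frame", frequencies = "numeric",
                   power = "numeric", maxPeakFrequency = "numeric",
                   wavelength = "numeric", amplitude = "numeric",
                   phase = "numeric", offset = "numeric", fitted = "numeric",
                   gStatistic = "numeric", pValue = "numeric",
                   genomeLength = "numeric", label = "character"))

setValidity("PeriodicityResult", function(object) {
    msg <- NULL
    if (length(object@gStatistic) == 1L &&
        (object@gStatistic <= 0 || object@gStatistic > 1))
        msg <- c(msg, "g statistic must lie in (0, 1]")
    if (length(object@pValue) == 1L &&
        (object@pValue < 0 || object@pValue > 1))
        msg <- c(msg, "p-value must lie in [0, 1]")
    if (length(object@wavelength) == 1L && length(object@genomeLength) == 1L &&
        length(object@maxPeakFrequency) == 1L &&
        is.finite(object@wavelength) &&
        abs(object@wavelength -
            object@genomeLength / object@maxPeakFrequency) > 1e-6)
        msg <- c(msg, "wavelength must equal genome_length / peak frequency")
    if (is.null(msg)) TRUE else msg
})

#' @rdname accessors
#' @export
setMethod("wavelength", "PeriodicityResult", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("peakFrequency", "PeriodicityResult",
          function(object) object@maxPeakFrequency)

#' @rdname accessors
#' @export
setMethod("gStatistic", "PeriodicityResult", function(object) object@gStatistic)

#' @rdname accessors
#' @export
setMethod("pValue", "PeriodicityResult", function(object) object@pValue)

setMethod("show", "PeriodicityResult", function(object) {
    cat("PeriodicityResult", if (length(object@label))
        paste0("(", object@label, ")") else "", "\n")
    cat("  profile:", nrow(object@profile), "windows over",
        format(object@genomeLength, big.mark = ","), "bp\n")
    cat("  max peak:", object@maxPeakFrequency, "cycles; wavelength",
        format(round(object@wavelength), big.mark = ","), "bp\n")
    cat("  fit: A =", format(object@amplitude, digits = 3),
        "phase =", format(object@phase, digits = 3),
        "offset =", format(object@offset, digits = 3), "\n")
    cat("  Fisher g =", format(object@gStatistic, digits = 4),
        ", p =", format(object@pValue, digits = 3), "\n")
})

#' EpistasisResult: through-origin regression of transcriptome changes
#'
#' Slope of the simultaneous per-gene expression change regressed on the sum
#' of the two single-interruption changes, with the resulting epistasis
#' classification.
#'
#' @slot alpha numeric, regression slope.
#' @slot intercept numeric, fitted intercept (0 in the default
#'   through-origin mode).
#' @slot nGenes integer, number of genes used.
#' @slot classification character, one of "additive", "positive", "negative".
#' @slot residualSS,totalSS numeric, residual and total sum of squares of the
#'   simultaneous profile.
#' @slot contrast character, label such as "GS ~ G+S".
#'
#' @export
setClass("EpistasisResult",
    representation(alpha = "numeric", intercept = "numeric",
                   nGenes = "integer", classification = "character",
                   residualSS = "numeric", totalSS = "numeric",
                   contrast = "character"))

setValidity("EpistasisResult", function(object) {
    if (length(object@classification) == 1L &&
        !object@classification %in% c("additive", "positive", "negative"))
        "classification must be additive/positive/negative" else TRUE
})

#' @rdname accessors
#' @export
setMethod("alphaSlope", "EpistasisResult", function(object) object@alpha)

#' @rdname accessors
#' @export
setMethod("epistasisClass", "EpistasisResult",
          function(object) object@classification)

setMethod("show", "EpistasisResult", function(object) {
    cat("EpistasisResult", if (length(object@contrast))
        paste0("(", object@contrast, ")") else "", "\n")
    cat("  alpha =", format(object@alpha, digits = 4), "->",
        object@classification, "epistasis\n")
    cat("  n genes:", object@nGenes, "; R2 =",
        format(1 - object@residualSS / object@totalSS, digits = 3), "\n")
})

#' RankProdResult: rank product statistics and significance
#'
#' Per-gene rank products for up- and down-regulation across all
#' cross-replicate comparisons, with permutation (or exact) p-values and
#' proportion-of-false-prediction (pfp) estimates.
#'
#' @slot geneIds character.
#' @slot rpUp,rpDown numeric, geometric-mean ranks.
#' @slot pUp,pDown numeric, null probabilities P(RP_null <= RP_obs).
#' @slot pfpUp,pfpDown numeric, step-up adjusted pfp estimates.
#' @slot nComparisons integer, number of cross-replicate comparisons.
#' @slot nPermutations integer, 0 for the exact null.
#' @slot seed integer seed used for the permutation null (NA for exact).
#' @slot nullMethod character, "exact" or "permutation".
#'
#' @export
setClass("RankProdResult",
    representation(geneIds = "character", rpUp = "numeric", rpDown = "numeric",
                   pUp = "numeric", pDown = "numeric",
                   pfpUp = "numeric", pfpDown = "numeric",
                   nComparisons = "integer", nPermutations = "integer",
                   seed = "integer", nullMethod = "character"))

setValidity("RankProdResult", function(object) {
    n <- length(object@geneIds)
    msg <- NULL
    if (any(lengths(list(object@rpUp, object@rpDown)) != n))
        msg <- c(msg, "rank product vectors must match the gene ids")
    if (n && (any(object@rpUp < 1 - 1e-9) || any(object@rpUp > n + 1e-9)))
        msg <- c(msg, "RP must lie in [1, n_genes]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "RankProdResult", function(object) {
    cat("RankProdResult:", length(object@geneIds), "genes,",
        object@nComparisons, "cross-replicate comparisons\n")
    cat("  null:", object@nullMethod,
        if (object@nullMethod == "permutation")
            paste0("(", object@nPermutations, " permutations, seed ",
                   object@seed, ")") else "(full enumeration)", "\n")
    if (length(object@pUp))
        cat("  min p (up/down):", format(min(object@pUp), digits = 3), "/",
            format(min(object@pDown), digits = 3), "\n")
})

#' Coerce a RankProdResult to a data.frame
#'
#' @param x a RankProdResult.
#' @param ... unused.
#' @return data.frame with one row per gene.
#' @export
as.data.frame.RankProdResult <- function(x, ...) {
    data.frame(gene_id = x@geneIds, rp_up = x@rpUp, rp_down = x@rpDown,
               p_up = x@pUp, p_down = x@pDown,
               pfp_up = x@pfpUp, pfp_down = x@pfpDown,
               stringsAsFactors = FALSE)
}

#' ModuleAssignment: co-expression modules with eigengenes
#'
#' Gene-to-module map from topological-overlap clustering. Module 0 collects
#' unassigned genes. Eigengenes are per-sample first principal components of
#' the member genes, unit variance, sign-aligned to the module mean profile.
#'
#' @slot labels named integer vector, gene -> module (0 = unassigned).
#' @slot eigengenes numeric matrix, samples x modules (columns "M1", ...).
#' @slot sizes named integer vector of module sizes (excluding module 0).
#' @slot traitCor data.frame of per-module trait correlations (may be empty).
#' @slot classes named character vector of class labels (may be empty).
#'
#' @export
setClass("ModuleAssignment",
    representation(labels = "integer", eigengenes = "matrix",
                   sizes = "integer", traitCor = "data.frame",
                   classes = "character"))

setValidity("ModuleAssignment", function(object) {
    msg <- NULL
    k <- length(object@sizes)
    lab <- object@labels
    if (any(lab < 0L)) msg <- c(msg, "module labels must be >= 0")
    if (k && max(lab) > k)
        msg <- c(msg, "labels exceed the number of modules")
    tab <- tabulate(lab[lab > 0L], nbins = k)
    if (k && !all(tab == as.integer(object@sizes)))
        msg <- c(msg, "sizes must match the label counts")
    if (is.null(msg)) TRUE else msg
})

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleAssignment", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("moduleSizes", "ModuleAssignment", function(object) object@sizes)

#' @rdname accessors
#' @export
setMethod("eigengenes", "ModuleAssignment", function(object) object@eigengenes)

#' @rdname accessors
#' @export
setMethod("moduleClasses", "ModuleAssignment", function(object) object@classes)

#' @rdname accessors
#' @export
setMethod("traitCorrelation", "ModuleAssignment",
          function(object) object@traitCor)

setMethod("show", "ModuleAssignment", function(object) {
    k <- length(object@sizes)
    cat("ModuleAssignment:", k, "modules over", length(object@labels),
        "genes (", sum(object@labels == 0L), "unassigned )\n")
    if (k) cat("  sizes:", paste(object@sizes, collapse = ", "), "\n")
    if (nrow(object@traitCor))
        cat("  trait-significant modules:",
            paste(object@traitCor$module[object@traitCor$significant],
                  collapse = ", "), "\n")
    if (length(object@classes))
        cat("  classes:", paste(names(object@classes), object@classes,
                                sep = "=", collapse = ", "), "\n")
})
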