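#' @include AllClasses.R
NULL

#' Design of a synthetic transcriptome experiment
#'
#' Bundles the ground-truth parameters for the synthetic-data generator. The
#' defaults emulate a genome-reduced \emph{E. coli} transcriptome study: about
#' 4,000 genes on a circular 4.6-Mb chromosome, a six-period spatial cosine on
#' the log10 expression scale, an 8-condition 2x2x2 design (wild-type N0 vs
#' reduced N28 genome, no stressor vs one stressor, ancestral vs evolved) in
#' duplicate, single-interruption effects on a minority of genes, a negative
#' transcriptome epistasis coefficient for dual interruptions, and 11
#' co-expressed gene modules (sizes 30 to 1,118; one module tied to the
#' condition growth rate).
#'
#' @param nGenes number of genes.
#' @param genomeLength circular chromosome length in bp.
#' @param nPeriods cycles of the spatial expression sinusoid per chromosome.
#' @param amp amplitude of the spatial sinusoid (log10 units).
#' @param phase phase of the spatial sinusoid (radians).
#' @param alphaTrue epistasis coefficient applied to the summed effects of
#'   dual (and triple) interruptions; 1 = additivity, < 1 = negative epistasis.
#' @param effectSdG,effectSdS,effectSdE sd of the per-gene effect (log10
#'   units) among affected genes for genome reduction, stressor and evolution.
#' @param fracAffectedG,fracAffectedS,fracAffectedE fraction of genes
#'   affected by each single interruption.
#' @param nModules number of co-expression modules.
#' @param moduleSizes integer vector of module sizes (length \code{nModules},
#'   sum <= \code{nGenes}).
#' @param growthModuleIndex index of the module whose latent factor follows
#'   the (negated, standardized) condition growth rate; \code{NA} for none.
#' @param noiseSd replicate noise sd (log10 units).
#' @param replicates biological replicates per condition.
#' @param baselineMean,baselineSd per-gene baseline log10 expression.
#' @param stressor label of the environmental stressor condition.
#' @param seed integer seed; every generator output is a deterministic
#'   function of the design including its seed.
#'
#' @return a validated list of class \code{"SyntheticDesign"}.
#' @export
syntheticDesign <- function(nGenes = 4000L, genomeLength = 4.6e6,
                            nPeriods = 6L, amp = 0.3, phase = 0,
                            alphaTrue = 0.6,
                            effectSdG = 1.2, effectSdS = 1.2, effectSdE = 1.2,
                            fracAffectedG = 0.40, fracAffectedS = 0.35,
                            fracAffectedE = 0.15,
                            nModules = 11L,
                            moduleSizes = c(1118L, 520L, 400L, 271L, 300L,
                                            230L, 160L, 110L, 81L, 70L, 30L),
                            growthModuleIndex = 4L,
                            noiseSd = 0.2, replicates = 2L,
                            baselineMean = 2, baselineSd = 0.7,
                            stressor = "Thr", seed = 1L) {
    d <- list(nGenes = as.integer(nGenes), genomeLength = genomeLength,
              nPeriods = as.integer(nPeriods), amp = amp, phase = phase,
              alphaTrue = alphaTrue,
              effectSd = c(G = effectSdG, S = effectSdS, E = effectSdE),
              fracAffected = c(G = fracAffectedG, S = fracAffectedS,
                               E = fracAffectedE),
              nModules = as.integer(nModules),
              moduleSizes = as.integer(moduleSizes),
              growthModuleIndex = growthModuleIndex,
              noiseSd = noiseSd, replicates = as.integer(replicates),
              baselineMean = baselineMean, baselineSd = baselineSd,
              stressor = stressor, seed = as.integer(seed))
    class(d) <- "SyntheticDesign"
    validateSyntheticDesign(d)
    d
}

validateSyntheticDesign <- function(d) {
    stopifnot(d$nGenes >= 1L, d$genomeLength > 0, d$nPeriods >= 1L)
    if (any(d$fracAffected < 0) || any(d$fracAffected > 1))
        stop("affected fractions must lie in [0, 1]")
    if (length(d$moduleSizes) != d$nModules)
        stop("moduleSizes must have length nModules")
    if (sum(d$moduleSizes) > d$nGenes)
        stop("sum(moduleSizes) must not exceed nGenes")
    if (!is.na(d$growthModuleIndex) &&
        (d$growthModuleIndex < 1 || d$growthModuleIndex > d$nModules))
        stop("growthModuleIndex out of range")
    if (d$replicates < 2L)
        warning("fewer than 2 replicates: variance-based stages are undefined")
    invisible(TRUE)
}

#' Generate a gene annotation on a circular genome
#'
#' Places \code{nGenes} non-overlapping genes on a circular chromosome by
#' partitioning it into equal slots and drawing one gene per slot with a
#' random length (>= 50 bp) and offset. Strand is random. Deterministic for a
#' given seed.
#'
#' @param nGenes number of genes (>= 1).
#' @param genomeLength chromosome length in bp; must be at least
#'   \code{100 * nGenes} so that packing is feasible.
#' @param seed integer seed.
#' @return a \code{GRanges} with \code{gene_id} metadata and the genome
#'   length recorded as the seqlength of \code{"chr"}.
#' @export
generateAnnotation <- function(nGenes, genomeLength, seed = 1L) {
    nGenes <- as.integer(nGenes)
    if (nGenes < 1L) stop("nGenes must be >= 1")
    if (genomeLength < nGenes * 100)
        stop("infeasible packing: genomeLength must be >= 100 * nGenes")
    set.seed(seed)
    slot <- floor(genomeLength / nGenes)
    maxLen <- max(50, min(floor(0.9 * slot), 1500))
    len <- floor(stats::runif(nGenes, min = 50, max = maxLen + 1))
    offset <- floor(stats::runif(nGenes) * (slot - len + 1))
    start0 <- (seq_len(nGenes) - 1L) * slot + offset  # 0-based
    gr <- GenomicRanges::GRanges(
        seqnames = "chr",
        ranges = IRanges::IRanges(start = start0 + 1L, width = len),
        strand = sample(c("+", "-"), nGenes, replace = TRUE),
        gene_id = sprintf("g%05d", seq_len(nGenes)))
    GenomeInfoDb::seqlengths(gr) <- c(chr = as.integer(genomeLength))
    GenomeInfoDb::isCircular(gr) <- c(chr = TRUE)
    names(gr) <- gr$gene_id
    gr
}

#' Gene midpoints on the circular genome
#' @param annot GRanges annotation.
#' @return numeric midpoints (bp, 0-based scale).
#' @export
geneMidpoints <- function(annot) {
    (GenomicRanges::start(annot) - 1 + GenomicRanges::end(annot) - 1) / 2
}

#' The eight synthetic conditions and their design table
#' @param stressor stressor label.
#' @param replicates replicates per condition.
#' @return data.frame with columns sample, genome, stress, evolved, replicate.
#' @export
syntheticDesignTable <- function(stressor = "Thr", replicates = 2L) {
    grid <- expand.grid(evolved = c("anc", "evo"),
                        stress = c("none", stressor),
                        genome = c("N0", "N28"),
                        stringsAsFactors = FALSE)[, 3:1]
    d <- grid[rep(seq_len(nrow(grid)), each = replicates), ]
    d$replicate <- rep(seq_len(replicates), times = nrow(grid))
    d$sample <- paste(d$genome, d$stress, d$evolved,
                      paste0("r", d$replicate), sep = ".")
    rownames(d) <- d$sample
    d[, c("sample", "genome", "stress", "evolved", "replicate")]
}

#' True growth rate for a synthetic condition
#'
#' Deterministic map from design labels to the generating growth rate
#' (per hour), emulating a canceling pattern: the stressor slows the
#' wild-type genome by ~30% but not the ancestral reduced genome, the reduced
#' genome grows ~28% slower, and evolution improves the reduced genome (which
#' thereby regains stressor responsivity).
#'
#' @param genome "N0" or "N28".
#' @param stress "none" or a stressor label.
#' @param evolved "anc" or "evo".
#' @param muBase wild-type regular-condition rate (per hour).
#' @return numeric growth rate.
#' @export
trueGrowthRate <- function(genome, stress, evolved, muBase = 0.7) {
    mu <- rep(muBase, length(genome))
    reduced <- genome == "N28"
    stressed <- stress != "none"
    evo <- evolved == "evo"
    mu[reduced] <- mu[reduced] * 0.72
    mu[evo & reduced] <- mu[evo & reduced] * 1.25
    mu[evo & !reduced] <- mu[evo & !reduced] * 1.05
    responsive <- stressed & (!reduced | evo)
    mu[responsive] <- mu[responsive] * 0.70
    mu
}

#' Single- and dual-interruption contrasts of the 2x2x2 design
#'
#' @param stressor stressor label used in the condition names.
#' @return named list of length-2 character vectors \code{c(from, to)} for
#'   the contrasts G, S, E, GS, GE, ES, all relative to the unperturbed
#'   reference condition.
#' @export
interruptionContrasts <- function(stressor = "Thr") {
    ref <- "N0.none.anc"
    list(G  = c(ref, "N28.none.anc"),
         S  = c(ref, paste("N0", stressor, "anc", sep = ".")),
         E  = c(ref, "N0.none.evo"),
         GS = c(ref, paste("N28", stressor, "anc", sep = ".")),
         GE = c(ref, "N28.none.evo"),
         ES = c(ref, paste("N0", stressor, "evo", sep = ".")))
}

.mixtureEffect <- function(n, frac, sd) {
    hit <- stats::runif(n) < frac
    e <- numeric(n)
    e[hit] <- stats::rnorm(sum(hit), 0, sd)
    e
}

#' Generate a synthetic log-expression experiment with known truth
#'
#' Builds a genes-by-samples log10 expression matrix as
#' baseline + spatial cosine + condition effects + module latent factors +
#' replicate noise. Single interruptions add their own per-gene effects;
#' conditions combining k >= 2 interruptions add
#' \code{alphaTrue * (sum of the k single effects)}, the generative reading
#' of the epistasis regression model. Module latent factors are per-sample;
#' the growth-linked module's factor is the negated standardized condition
#' growth rate, and all other factors are orthogonalized against the
#' growth-rate profile so that only the growth module correlates with growth
#' by construction.
#'
#' @param design a \code{\link{syntheticDesign}}.
#' @return list with elements \code{experiment} (a
#'   \linkS4class{ReorgExperiment}) and \code{truth} (a list recording every
#'   generating value: effects, DEG flags per contrast, module labels,
#'   factors, loadings, growth rates, spatial parameters).
#' @export
generateExpression <- function(design) {
    validateSyntheticDesign(design)
    d <- design
    annot <- generateAnnotation(d$nGenes, d$genomeLength, seed = d$seed)
    set.seed(d$seed + 1L)
    n <- d$nGenes
    tab <- syntheticDesignTable(d$stressor, d$replicates)
    nS <- nrow(tab)

    baseline <- stats::rnorm(n, d$baselineMean, d$baselineSd)
    mids <- geneMidpoints(annot)
    spatial <- d$amp * cos(2 * pi * d$nPeriods * mids / d$genomeLength +
                           d$phase)

    eff <- cbind(G = .mixtureEffect(n, d$fracAffected["G"], d$effectSd["G"]),
                 S = .mixtureEffect(n, d$fracAffected["S"], d$effectSd["S"]),
                 E = .mixtureEffect(n, d$fracAffected["E"], d$effectSd["E"]))

    active <- cbind(G = tab$genome == "N28",
                    S = tab$stress != "none",
                    E = tab$evolved == "evo")
    condEffect <- matrix(0, n, nS, dimnames = list(names(annot), tab$sample))
    for (j in seq_len(nS)) {
        k <- sum(active[j, ])
        if (k == 0L) next
        e <- eff[, active[j, ], drop = FALSE]
        tot <- rowSums(e)
        condEffect[, j] <- if (k >= 2L) d$alphaTrue * tot else tot
    }

    muSample <- trueGrowthRate(tab$genome, tab$stress, tab$evolved)

    nMod <- d$nModules
    moduleLabels <- integer(n)
    assigned <- sample.int(n, sum(d$moduleSizes))
    moduleLabels[assigned] <- rep(seq_len(nMod), times = d$moduleSizes)
    loadings <- numeric(n)
    loadings[assigned] <- stats::runif(length(assigned), 0.5, 1)

    factors <- matrix(stats::rnorm(nS * nMod), nS, nMod)
    gTrend <- as.numeric(scale(muSample))
    if (nMod > 0L) {
        basis <- cbind(1, gTrend)
        proj <- basis %*% solve(crossprod(basis), crossprod(basis, factors))
        factors <- factors - proj
        factors <- sweep(factors, 2, apply(factors, 2, stats::sd), "/")
        if (!is.na(d$growthModuleIndex))
            factors[, d$growthModuleIndex] <- -gTrend
        dimnames(factors) <- list(tab$sample, paste0("M", seq_len(nMod)))
    }

    expr <- matrix(baseline + spatial, n, nS) + condEffect
    inMod <- moduleLabels > 0L
    expr[inMod, ] <- expr[inMod, ] +
        loadings[inMod] * t(factors[, moduleLabels[inMod], drop = FALSE])
    if (d$noiseSd > 0)
        expr <- expr + matrix(stats::rnorm(n * nS, 0, d$noiseSd), n, nS)
    dimnames(expr) <- list(names(annot), tab$sample)

    degFlags <- list(G = eff[, "G"] != 0, S = eff[, "S"] != 0,
                     E = eff[, "E"] != 0,
                     GS = (eff[, "G"] + eff[, "S"]) != 0,
                     GE = (eff[, "G"] + eff[, "E"]) != 0,
                     ES = (eff[, "S"] + eff[, "E"]) != 0)

    condTab <- unique(tab[, c("genome", "stress", "evolved")])
    truth <- list(
        effects = eff, degFlags = degFlags,
        moduleLabels = stats::setNames(moduleLabels, names(annot)),
        loadings = stats::setNames(loadings, names(annot)),
        factors = factors,
        growthModuleIndex = d$growthModuleIndex,
        growthRateSample = stats::setNames(muSample, tab$sample),
        growthRateCondition = stats::setNames(
            trueGrowthRate(condTab$genome, condTab$stress, condTab$evolved),
            conditionLabel(condTab)),
        baseline = stats::setNames(baseline, names(annot)),
        spatial = stats::setNames(spatial, names(annot)),
        nPeriods = d$nPeriods, amp = d$amp, phase = d$phase,
        alphaTrue = d$alphaTrue, design = d)

    re <- ReorgExperiment(expr, tab[, -1], annotation = annot,
                          genomeLength = d$genomeLength)
    list(experiment = re, truth = truth)
}

#' Simulate read counts from log expression
#'
#' Inverse of the FPKM conversion: with per-gene expected counts proportional
#' to linear expression times gene length, a multinomial draw allocates a
#' fixed sequencing depth per sample.
#'
#' @param logexpr genes-by-samples log10 expression matrix (treated as log10
#'   FPKM), or a \linkS4class{ReorgExperiment}.
#' @param lengths gene lengths in bp.
#' @param depth total reads per sample (> 0).
#' @param seed integer seed.
#' @return integer count matrix with the same dimnames.
#' @export
generateCounts <- function(logexpr, lengths, depth = 1e7, seed = 1L) {
    if (methods::is(logexpr, "ReorgExperiment")) {
        if (missing(lengths))
            lengths <- GenomicRanges::width(SummarizedExperiment::rowRanges(logexpr))
        logexpr <- SummarizedExperiment::assay(logexpr, "logexpr")
    }
    if (depth <= 0) stop("depth must be > 0")
    linear <- 10^logexpr
    if (any(!is.finite(linear)) || any(linear < 0))
        stop("expression on the linear scale must be finite and non-negative")
    set.seed(seed)
    w <- linear * lengths
    counts <- vapply(seq_len(ncol(w)), function(j) {
        p <- w[, j]
        if (sum(p) <= 0) stop("sample ", j, " has zero total expression")
        as.integer(stats::rmultinom(1, size = depth, prob = p / sum(p)))
    }, integer(nrow(w)))
    dimnames(counts) <- dimnames(logexpr)
    counts
}

#' Simulate logistic growth curves
#'
#' OD600 follows lag -> exponential (rate \code{mu}) -> saturation at
#' \code{capacity}, sampled at fixed intervals, with optional multiplicative
#' lognormal noise. \code{capacity = Inf} gives a pure exponential.
#'
#' @param mu exponential growth rate (per hour, >= 0).
#' @param lagH lag time in hours.
#' @param capacity carrying capacity (OD600 units).
#' @param od0 initial OD600.
#' @param noiseSd sd of the multiplicative lognormal noise.
#' @param intervalMin sampling interval in minutes (> 0).
#' @param durationH assay duration in hours.
#' @param nWells number of replicate wells.
#' @param seed integer seed.
#' @return data.frame with columns \code{well}, \code{time_h}, \code{od600}.
#' @export
generateGrowthCurves <- function(mu, lagH = 1, capacity = 1.2, od0 = 0.01,
                                 noiseSd = 0, intervalMin = 30,
                                 durationH = 48, nWells = 3L, seed = 1L) {
    if (mu < 0) stop("mu must be >= 0")
    if (intervalMin <= 0) stop("intervalMin must be > 0")
    set.seed(seed)
    t <- seq(0, durationH, by = intervalMin / 60)
    tt <- pmax(t - lagH, 0)
    od <- if (is.infinite(capacity)) od0 * exp(mu * tt)
          else capacity * od0 * exp(mu * tt) /
               (capacity + od0 * (exp(mu * tt) - 1))
    out <- do.call(rbind, lapply(seq_len(nWells), function(w) {
        v <- od
        if (noiseSd > 0) v <- v * exp(stats::rnorm(length(v), 0, noiseSd))
        data.frame(well = sprintf("W%02d", w), time_h = t, od600 = v,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Generate regulon and gene-category membership tables
#'
#' Draws overlapping gene sets emulating a transcription-factor regulon map
#' and a gene-category map. A true enrichment can be planted: members of the
#' named target category are sampled with an odds-ratio weight in favour of a
#' supplied gene set.
#'
#' @param geneIds universe of gene ids.
#' @param nRegulons number of regulons.
#' @param nCategories number of gene categories.
#' @param regulonSizes integer vector (recycled) of regulon sizes.
#' @param categorySizes integer vector (recycled) of category sizes.
#' @param enrichInto optional list \code{list(category=, genes=, odds=)}
#'   planting enrichment of \code{genes} into the category with that id.
#' @param seed integer seed.
#' @return list with data.frames \code{regulons} and \code{categories}
#'   (columns \code{category_id}, \code{gene_id}).
#' @export
generateFunctionMaps <- function(geneIds, nRegulons = 53L, nCategories = 19L,
                                 regulonSizes = c(11L, 15L, 20L, 30L, 45L),
                                 categorySizes = c(31L, 60L, 100L, 150L),
                                 enrichInto = NULL, seed = 1L) {
    if (any(c(regulonSizes, categorySizes) <= 0))
        stop("sizes must be positive")
    if (any(c(regulonSizes, categorySizes) > length(geneIds)))
        stop("requested category size exceeds the number of genes")
    set.seed(seed)
    drawMap <- function(prefix, k, sizes) {
        sizes <- rep_len(sizes, k)
        ids <- sprintf("%s%02d", prefix, seq_len(k))
        do.call(rbind, lapply(seq_len(k), function(i) {
            w <- rep(1, length(geneIds))
            if (!is.null(enrichInto) && ids[i] == enrichInto$category)
                w[geneIds %in% enrichInto$genes] <- enrichInto$odds
            data.frame(category_id = ids[i],
                       gene_id = sample(geneIds, sizes[i], prob = w),
                       stringsAsFactors = FALSE)
        }))
    }
    list(regulons = drawMap("TF", nRegulons, regulonSizes),
         categories = drawMap("GC", nCategories, categorySizes))
}
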