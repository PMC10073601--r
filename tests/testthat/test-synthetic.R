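test_that("annotation generation respects bounds, determinism and spacing", {
    gr <- generateAnnotation(4, 4000, seed = 1)
    expect_length(gr, 4)
    expect_true(all(geneMidpoints(gr) < 4000))
    expect_true(all(GenomicRanges::width(gr) >= 50))
    expect_identical(gr, generateAnnotation(4, 4000, seed = 1))

    big <- generateAnnotation(4000, 4.6e6, seed = 2)
    spacing <- mean(diff(GenomicRanges::start(big)))
    expect_equal(spacing, 4.6e6 / 4000, tolerance = 0.01)
    expect_true(all(GenomicRanges::start(big) >= 1))
    expect_true(all(GenomicRanges::end(big) <= 4.6e6))
    # non-overlapping by construction
    expect_true(all(diff(GenomicRanges::start(big)) >
                    GenomicRanges::width(big)[-4000] - 1))

    expect_error(generateAnnotation(100, 5000), "packing")
})

test_that("degenerate design yields an exactly constant matrix", {
    d <- smallDesign(nGenes = 50L, seed = 3, amp = 0, noiseSd = 0,
                     fracAffectedG = 0, fracAffectedS = 0, fracAffectedE = 0)
    g <- generateExpression(d)
    m <- SummarizedExperiment::assay(g$experiment, "logexpr")
    # every gene constant across samples, equal to its baseline
    expect_equal(apply(m, 1, function(r) diff(range(r))),
                 setNames(rep(0, 50), rownames(m)))
    expect_equal(unname(m[, 1]), unname(g$truth$baseline))
})

test_that("pure spatial cosine peaks at the designed period", {
    d <- smallDesign(nGenes = 800L, genomeLength = 8e5, seed = 4, amp = 1,
                     noiseSd = 0, fracAffectedG = 0, fracAffectedS = 0,
                     fracAffectedE = 0)
    g <- generateExpression(d)
    pr <- chromosomalPeriodicity(g$experiment, condition = "N0.none.anc")
    expect_equal(peakFrequency(pr), 6)
    expect_equal(wavelength(pr), 8e5 / 6)
})

test_that("generator is byte-identical under a repeated seed", {
    d <- smallDesign(seed = 9)
    g1 <- generateExpression(d)
    g2 <- generateExpression(d)
    expect_identical(SummarizedExperiment::assay(g1$experiment, "logexpr"),
                     SummarizedExperiment::assay(g2$experiment, "logexpr"))
    expect_identical(g1$truth$effects, g2$truth$effects)
    gc1 <- generateGrowthCurves(0.5, noiseSd = 0.02, seed = 5)
    gc2 <- generateGrowthCurves(0.5, noiseSd = 0.02, seed = 5)
    expect_identical(gc1, gc2)
})

test_that("through-origin slope on generated deltas recovers alpha_true", {
    d <- smallDesign(nGenes = 3000L, genomeLength = 4.6e6, seed = 7,
                     alphaTrue = 0.5, noiseSd = 0.1)
    g <- generateExpression(d)
    res <- epistasisAnalysis(g$experiment)$GS
    expect_equal(alphaSlope(res), 0.5, tolerance = 0.05 / 0.5)
    expect_equal(epistasisClass(res), "negative")
})

test_that("count simulation conserves depth and concentrates mass", {
    # one dominant gene takes essentially all counts
    le <- matrix(c(6, -4, -4, -4), 4, 1,
                 dimnames = list(paste0("g", 1:4), "s1"))
    cn <- generateCounts(le, lengths = rep(1000, 4), depth = 1e6, seed = 1)
    expect_equal(sum(cn), 1e6)
    expect_gt(cn[1, 1] / 1e6, 0.999)

    d <- smallDesign(nGenes = 200L, seed = 8)
    g <- generateExpression(d)
    w <- GenomicRanges::width(SummarizedExperiment::rowRanges(g$experiment))
    cn <- generateCounts(g$experiment, depth = 5e5, seed = 2)
    expect_true(all(colSums(cn) == 5e5))
    expect_error(generateCounts(le, rep(1000, 4), depth = -1), "depth")
})

test_that("counts -> FPKM -> log round trip recovers expression", {
    d <- smallDesign(nGenes = 300L, seed = 3, noiseSd = 0)
    g <- generateExpression(d)
    le <- SummarizedExperiment::assay(g$experiment, "logexpr")
    w <- GenomicRanges::width(SummarizedExperiment::rowRanges(g$experiment))
    cn <- generateCounts(le, w, depth = 1e7, seed = 4)
    fp <- computeFpkm(cn, w)
    ok <- rowSums(cn >= 10) == ncol(cn)   # genes with quantifiable coverage
    lf <- sweep(log10(fp[ok, ]), 2, colMeans(log10(fp[ok, ])))
    lt <- sweep(le[ok, ], 2, colMeans(le[ok, ]))
    expect_gt(sum(ok), 250)
    expect_lt(sqrt(mean((lf - lt)^2)), 0.05)
})

test_that("growth curve generator covers flat, exponential and noisy cases", {
    flat <- generateGrowthCurves(0, lagH = 0, noiseSd = 0, nWells = 1)
    expect_equal(diff(range(flat$od600)), 0)

    pure <- generateGrowthCurves(0.6, lagH = 0, capacity = Inf, noiseSd = 0,
                                 nWells = 1, durationH = 10)
    mu <- pointwiseRates(pure$time_h, pure$od600)
    expect_equal(mu, rep(0.6, length(mu)), tolerance = 1e-10)

    noisy <- generateGrowthCurves(0.6, noiseSd = 0.01, seed = 11)
    fit <- growthFitness(noisy)
    expect_equal(fit$fitness, 0.6, tolerance = 0.05)
})

test_that("function maps honor sizes and planted enrichment", {
    ids <- sprintf("g%04d", 1:1000)
    fm <- generateFunctionMaps(ids, nRegulons = 10, nCategories = 5,
                               categorySizes = 80L, seed = 2)
    sizes <- table(fm$categories$category_id)
    expect_true(all(sizes == 80))
    expect_error(generateFunctionMaps(ids[1:50], categorySizes = 80L),
                 "exceeds")

    deg <- sample(ids, 100)
    fmP <- generateFunctionMaps(ids, nCategories = 8, categorySizes = 60L,
                                enrichInto = list(category = "GC03",
                                                  genes = deg, odds = 8),
                                seed = 3)
    et <- binomialEnrichment(deg, fmP$categories, ids)
    expect_true(et$significant[et$category_id == "GC03"])

    # without planting, Bonferroni-significant categories are rare
    hits <- vapply(1:10, function(s) {
        fm0 <- generateFunctionMaps(ids, nCategories = 8,
                                    categorySizes = 60L, seed = 100 + s)
        sum(binomialEnrichment(deg, fm0$categories, ids)$significant)
    }, numeric(1))
    expect_lt(mean(hits), 0.3)
})
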