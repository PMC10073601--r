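test_that("rank products have their closed-form extremes", {
    # gene 1 is top-ranked for up-regulation in every comparison
    A <- matrix(0, 5, 2, dimnames = list(paste0("g", 1:5), NULL))
    B <- matrix(rep(c(10, 4, 3, 2, 1), 2), 5, 2,
                dimnames = list(paste0("g", 1:5), NULL))
    rp <- rankProductStat(A, B)
    expect_equal(unname(rp@rpUp[1]), 1)
    expect_equal(unname(rp@rpDown[1]), 5)
    # a consistently median-ranked gene sits at (n+1)/2
    expect_equal(unname(rp@rpUp[3]), 3)
})

test_that("rank products equal hand enumeration of all cross comparisons", {
    set.seed(1)
    A <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("g", 1:5), NULL))
    B <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("g", 1:5), NULL))
    rp <- rankProductStat(A, B)
    upProd <- rep(1, 5); dnProd <- rep(1, 5)
    for (a in 1:2) for (b in 1:2) {
        fc <- B[, b] - A[, a]
        upProd <- upProd * rank(-fc)
        dnProd <- dnProd * rank(fc)
    }
    expect_equal(unname(rp@rpUp), unname(upProd^(1 / 4)))
    expect_equal(unname(rp@rpDown), unname(dnProd^(1 / 4)))
})

test_that("exact p equals exhaustive enumeration of rank tuples", {
    set.seed(2)
    A <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("g", 1:5), NULL))
    b <- matrix(rnorm(5), 5, 1, dimnames = list(paste0("g", 1:5), NULL))
    rp <- rankProdSignificance(rankProductStat(A, b))   # K = 2, exact
    expect_equal(rp@nullMethod, "exact")
    # independent oracle: nested loops over every (r1, r2) tuple
    pOracle <- function(obsRp) {
        cnt <- 0
        for (r1 in 1:5) for (r2 in 1:5)
            if (sqrt(r1 * r2) <= obsRp + 1e-12) cnt <- cnt + 1
        cnt / 25
    }
    for (i in 1:5) {
        expect_equal(rp@pUp[i], pOracle(rp@rpUp[i]))
        expect_equal(rp@pDown[i], pOracle(rp@rpDown[i]))
    }
})

test_that("exact enumeration agrees with full rank-permutation counting", {
    # pooling null rank products over all within-comparison permutations and
    # genes must equal the iid-tuple enumeration, here checked at n = 4, K = 2
    A <- matrix(c(4, 1, 3, 2), 4, 1, dimnames = list(paste0("g", 1:4), NULL))
    B <- matrix(c(1, 2, 6, 3), 4, 1, dimnames = list(paste0("g", 1:4), NULL))
    # build a 2-comparison setup by duplicating the B replicate
    rp <- rankProdSignificance(rankProductStat(A, cbind(B, B + 0.001)))
    perms <- function() {
        p <- list()
        for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
            p[[length(p) + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
        p
    }
    allPerm <- perms()
    nulls <- c()
    for (p1 in allPerm) for (p2 in allPerm) nulls <- c(nulls, p1 * p2)
    for (i in 1:4) {
        obs <- rp@rpUp[i]^2
        expect_equal(rp@pUp[i], mean(nulls <= obs + 1e-9))
    }
})

test_that("permutation p-values are seeded, bounded away from 0 and stable", {
    set.seed(3)
    A <- matrix(rnorm(300), 100, 3); B <- matrix(rnorm(300), 100, 3)
    rownames(A) <- rownames(B) <- sprintf("g%03d", 1:100)
    rp0 <- rankProductStat(A, B)
    rp1 <- rankProdSignificance(rp0, nPermutations = 150, seed = 7,
                                exact = "never")
    rp2 <- rankProdSignificance(rp0, nPermutations = 150, seed = 7,
                                exact = "never")
    expect_identical(rp1@pUp, rp2@pUp)
    expect_true(all(rp1@pUp > 0))
    expect_gte(min(rp1@pUp), 1 / (150 * 100 + 1))
    expect_error(rankProdSignificance(rp0, nPermutations = 50,
                                      exact = "never"), "100 permutations")
})

test_that("rank products are affine-invariant and direction-symmetric", {
    set.seed(4)
    A <- matrix(rnorm(40), 10, 4); B <- matrix(rnorm(40), 10, 4)
    rownames(A) <- rownames(B) <- paste0("g", 1:10)
    rp <- rankProductStat(A, B)
    # fold-change ranks survive any increasing affine rescaling (e.g. a
    # change of log base upstream)
    rpT <- rankProductStat(2.5 * A + 3, 2.5 * B + 3)
    expect_equal(rp@rpUp, rpT@rpUp)
    rpN <- rankProductStat(-A, -B)           # negation swaps directions
    expect_equal(rp@rpUp, rpN@rpDown)
    expect_equal(rp@rpDown, rpN@rpUp)
})

test_that("null data leave the top gene unconvincing", {
    pfps <- vapply(1:30, function(s) {
        set.seed(100 + s)
        A <- matrix(rnorm(10), 5, 2); B <- matrix(rnorm(10), 5, 2)
        rownames(A) <- rownames(B) <- paste0("g", 1:5)
        rp <- rankProdSignificance(rankProductStat(A, B))
        min(rp@pfpUp)
    }, numeric(1))
    # without signal the best gene's pfp stays high on average and rarely
    # dips under an FDR threshold (cross-replicate rank dependence makes it
    # occasionally small, so the bound is on the seed ensemble)
    expect_gt(mean(pfps), 0.3)
    expect_lt(mean(pfps <= 0.05), 0.25)
})

test_that("planted up-regulation is recovered at a low false rate", {
    set.seed(5)
    n <- 1000
    A <- matrix(rnorm(n * 3), n); B <- matrix(rnorm(n * 3), n)
    B[1:50, ] <- B[1:50, ] + 3   # 3-sigma planted shift
    rownames(A) <- rownames(B) <- sprintf("g%04d", 1:n)
    rp <- rankProdSignificance(rankProductStat(A, B), nPermutations = 200,
                               seed = 6, exact = "never")
    deg <- callDegs(rp, 0.05)
    planted <- sprintf("g%04d", 1:50)
    expect_gte(sum(deg$genes %in% planted), 45)
    # false-positive rate over the 950 null genes stays below 5%
    expect_lt(sum(!(deg$genes %in% planted)) / 950, 0.05)
    # threshold 1 calls everything
    expect_length(callDegs(rp, 1)$genes, n)
})

test_that("DEG overlap counts every Venn region", {
    uni <- paste0("g", 1:20)
    s1 <- list(genes = paste0("g", 1:10), universe = uni)
    s2 <- list(genes = paste0("g", 6:15), universe = uni)
    ov <- degOverlap(list(A = s1, B = s2))
    expect_equal(unname(ov$regions[c("A", "A&B", "B")]), c(5, 5, 5))
    expect_equal(ov$pairwise["A", "B"], 0.5)

    same <- degOverlap(list(A = s1, B = s1))
    expect_equal(same$pairwise["A", "B"], 1)
    disj <- degOverlap(list(A = s1,
                            B = list(genes = paste0("g", 11:15),
                                     universe = uni)))
    expect_false("A&B" %in% names(disj$regions))

    set.seed(7)
    r <- lapply(1:3, function(i)
        list(genes = sample(uni, 8), universe = uni))
    names(r) <- c("A", "B", "C")
    ov3 <- degOverlap(r)
    expect_equal(sum(ov3$regions),
                 length(Reduce(union, lapply(r, `[[`, "genes"))))
    expect_error(degOverlap(list(s1, list(genes = "x", universe = "x"))),
                 "universe mismatch")
})

test_that("the Welch substitute flags a planted shift", {
    set.seed(8)
    A <- matrix(rnorm(500), 100, 5); B <- matrix(rnorm(500), 100, 5)
    B[1:10, ] <- B[1:10, ] + 4
    rownames(A) <- rownames(B) <- paste0("g", 1:100)
    out <- welchDeTest(A, B)
    expect_gte(sum(out$significant[1:10]), 8)
    expect_lte(sum(out$significant[-(1:10)]), 3)
})
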