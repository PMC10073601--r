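# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# a small design with no modules and no condition effects unless asked
smallDesign <- function(nGenes = 300L, seed = 1L, ...) {
    args <- list(nGenes = nGenes, genomeLength = max(1e5, nGenes * 120),
                 nModules = 0L, moduleSizes = integer(0),
                 growthModuleIndex = NA, seed = seed)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(syntheticDesign, args)
}

# independent re-implementation of the three-point window rule, used as a
# brute-force oracle against selectGrowthRate
bruteForceWindow <- function(rates, meanTol = 0.01) {
    n <- length(rates)
    means <- vars <- numeric(n - 2)
    for (i in seq_len(n - 2)) {
        w <- rates[i:(i + 2)]
        means[i] <- mean(w)
        vars[i] <- var(w)
    }
    mmax <- max(means)
    cand <- which(means >= mmax - meanTol * abs(mmax))
    best <- cand[order(vars[cand], cand)][1]
    list(mu = means[best], start = best)
}

# direct-formula TOM oracle: triple loop over the textbook definition
directTom <- function(a) {
    n <- nrow(a)
    tom <- diag(n)
    k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        u <- setdiff(seq_len(n), c(i, j))
        l <- sum(a[i, u] * a[u, j])
        tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    tom
}

# binomial upper-tail oracle by explicit summation
binomTailSum <- function(x, n, prob) {
    if (x > n) return(0)
    sum(choose(n, x:n) * prob^(x:n) * (1 - prob)^(n - (x:n)))
}
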