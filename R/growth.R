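#' @include AllClasses.R
NULL

#' Pointwise exponential growth rates from an OD600 time series
#'
#' Between each pair of consecutive measurements the rate is
#' mu_i = ln(C_{i+1}/C_i) / (t_{i+1} - t_i), with C the OD600 readings and t
#' the times in hours. Rates are therefore per hour and invariant to any
#' constant rescaling of the OD values.
#'
#' @param times numeric vector of times in hours, strictly increasing.
#' @param od numeric vector of OD600 values, all positive.
#' @return numeric vector of length \code{length(times) - 1}.
#' @export
pointwiseRates <- function(times, od) {
    if (length(times) != length(od))
        stop("times and od must have equal length")
    if (length(od) < 2L) stop("at least 2 points are required")
    bad <- which(!(od > 0))
    if (length(bad))
        stop("non-positive OD at index ", bad[1])
    if (any(diff(times) <= 0))
        stop("times must be strictly increasing")
    diff(log(od)) / diff(times)
}

#' Select the growth rate by the three-point window rule
#'
#' Scans all windows of three consecutive pointwise rates and returns the
#' mean of the window with the largest mean; among windows whose mean lies
#' within 1\% (relative) of the maximum, the one with the smallest variance
#' wins, and remaining ties go to the earliest window. This picks the steady
#' exponential phase while excluding lag and saturation.
#'
#' @param rates numeric vector of pointwise rates (>= 3 values).
#' @param meanTol relative tolerance defining "tied" window means.
#' @return a \linkS4class{GrowthRateResult}.
#' @export
selectGrowthRate <- function(rates, meanTol = 0.01) {
    n <- length(rates)
    if (n < 3L) stop("at least 3 rates are required")
    idx <- seq_len(n - 2L)
    means <- vapply(idx, function(i) mean(rates[i:(i + 2L)]), numeric(1))
    vars <- vapply(idx, function(i) stats::var(rates[i:(i + 2L)]), numeric(1))
    mmax <- max(means)
    cand <- idx[means >= mmax - meanTol * abs(mmax)]
    best <- cand[order(vars[cand], cand)][1]
    methods::new("GrowthRateResult",
                 mu = means[best], windowStart = as.integer(best),
                 windowRates = rates[best:(best + 2L)],
                 windowVariance = vars[best])
}

#' Growth rate of a single curve
#'
#' Convenience wrapper: pointwise rates followed by the window rule.
#'
#' @inheritParams pointwiseRates
#' @inheritParams selectGrowthRate
#' @return a \linkS4class{GrowthRateResult}.
#' @export
extractGrowthRate <- function(times, od, meanTol = 0.01) {
    selectGrowthRate(pointwiseRates(times, od), meanTol = meanTol)
}

#' Growth fitness over replicate wells
#'
#' Extracts the windowed growth rate per well from a long-format curve table
#' and averages the replicates; the mean over replicates is the growth
#' fitness. Wells whose OD never increases by at least \code{minFold} are
#' reported with status \code{"no_growth"} and excluded from the mean rather
#' than being scored as zero.
#'
#' @param curves data.frame with columns \code{well}, \code{time_h},
#'   \code{od600}.
#' @param minFold minimum max/initial OD ratio for a well to count as grown.
#' @param meanTol passed to \code{\link{selectGrowthRate}}.
#' @return list with \code{fitness} (mean mu over grown wells), \code{wells}
#'   (data.frame of per-well mu and status).
#' @export
growthFitness <- function(curves, minFold = 2, meanTol = 0.01) {
    if (!all(c("well", "time_h", "od600") %in% names(curves)))
        stop("curves must have columns well, time_h, od600")
    wells <- split(curves, curves$well)
    if (!length(wells)) stop("no wells in input")
    per <- do.call(rbind, lapply(names(wells), function(w) {
        cc <- wells[[w]][order(wells[[w]]$time_h), ]
        if (max(cc$od600) / cc$od600[1] < minFold)
            return(data.frame(well = w, mu = NA_real_,
                              status = "no_growth",
                              stringsAsFactors = FALSE))
        res <- extractGrowthRate(cc$time_h, cc$od600, meanTol = meanTol)
        data.frame(well = w, mu = res@mu, status = "ok",
                   stringsAsFactors = FALSE)
    }))
    grown <- per$mu[per$status == "ok"]
    list(fitness = if (length(grown)) mean(grown) else NA_real_, wells = per)
}

#' Pick a stressor concentration from a dose-response curve
#'
#' Returns the smallest tested concentration at which the growth rate has
#' dropped by at least \code{targetFraction} relative to the zero
#' concentration, together with a refined estimate from linear interpolation
#' of the rate curve between the bracketing concentrations at the threshold
#' rate \code{(1 - targetFraction) * rate0}.
#'
#' @param concentrations numeric, tested concentrations including 0.
#' @param rates numeric growth rates matching \code{concentrations}.
#' @param targetFraction target relative decrease (default 0.30).
#' @return list with \code{tested} (the qualifying tested concentration),
#'   \code{refined} (interpolated estimate) and \code{thresholdRate}.
#' @export
doseResponsePick <- function(concentrations, rates, targetFraction = 0.30) {
    if (length(concentrations) != length(rates))
        stop("concentrations and rates must have equal length")
    o <- order(concentrations)
    conc <- concentrations[o]; r <- rates[o]
    if (conc[1] != 0) stop("a rate at concentration 0 is required")
    r0 <- r[1]
    decrease <- 1 - r / r0
    hit <- which(decrease >= targetFraction)
    if (!length(hit))
        stop("target decrease ", targetFraction,
             " never reached; max observed decrease ",
             format(max(decrease), digits = 3))
    i <- hit[1]
    rt <- (1 - targetFraction) * r0
    if (i == 1L) return(list(tested = conc[1], refined = conc[1],
                             thresholdRate = rt))
    refined <- if (r[i - 1] == r[i]) conc[i]
               else conc[i - 1] + (r[i - 1] - rt) / (r[i - 1] - r[i]) *
                    (conc[i] - conc[i - 1])
    list(tested = conc[i], refined = refined, thresholdRate = rt)
}

#' Welch's two-sample t-test p-value
#'
#' Two-sided Welch test between two groups of growth rates. Degenerate
#' zero-variance inputs follow the convention p = 1 for equal means (no
#' evidence of a difference) and p = 0 for separated constant groups.
#'
#' @param groupA,groupB numeric vectors (>= 2 values each).
#' @return two-sided p-value.
#' @export
welchCompare <- function(groupA, groupB) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 values")
    if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0)
        return(if (mean(groupA) == mean(groupB)) 1 else 0)
    stats::t.test(groupA, groupB, var.equal = FALSE)$p.value
}
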