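#' @include AllClasses.R
NULL

# Fill NA runs of a regular circular series by linear interpolation between
# the flanking observed values, wrapping around the origin.
circularInterpolate <- function(v) {
    n <- length(v)
    if (!anyNA(v)) return(v)
    obs <- which(!is.na(v))
    if (!length(obs)) stop("no observed values to interpolate from")
    if (length(obs) == 1L) { v[] <- v[obs]; return(v) }
    x3 <- c(obs - n, obs, obs + n)
    y3 <- rep(v[obs], 3)
    miss <- which(is.na(v))
    v[miss] <- stats::approx(x3, y3, xout = miss)$y
    v
}

#' Spatial expression profile along the circular chromosome
#'
#' Genes are assigned to 1-kb windows by their midpoint; each window's value
#' is the mean expression of the genes whose midpoint falls in a centered
#' circular smoothing span (default 100 kb) around the window. Windows whose
#' span contains no gene are filled by linear interpolation between their
#' circular neighbours, yielding a regular series suitable for the
#' periodogram.
#'
#' @param expr named numeric vector of per-gene expression (typically the
#'   replicate-mean log10 expression of one condition), or a
#'   \linkS4class{ReorgExperiment} (columns are averaged, or restricted to
#'   \code{condition} first).
#' @param annot \code{GRanges} gene annotation (ignored when \code{expr} is a
#'   \code{ReorgExperiment}).
#' @param genomeLength circular chromosome length in bp.
#' @param window sliding distance in bp (default 1000).
#' @param smooth smoothing span in bp (default 1e5); must not exceed the
#'   genome length.
#' @param condition optional condition label to select samples.
#' @return data.frame with columns \code{position} (window start, bp) and
#'   \code{value}; genome length and window kept as attributes.
#' @export
spatialProfile <- function(expr, annot = NULL, genomeLength = NULL,
                           window = 1000, smooth = 1e5, condition = NULL) {
    if (methods::is(expr, "ReorgExperiment")) {
        m <- SummarizedExperiment::assay(expr, "logexpr")
        if (!is.null(condition))
            m <- m[, conditionLabels(expr) == condition, drop = FALSE]
        if (!ncol(m)) stop("no samples for condition ", condition)
        annot <- SummarizedExperiment::rowRanges(expr)
        genomeLength <- genomeLength(expr)
        expr <- rowMeans(m)
    }
    if (is.null(annot) || is.null(genomeLength))
        stop("annot and genomeLength are required")
    if (genomeLength < smooth)
        stop("genomeLength must be at least the smoothing span")
    n <- floor(genomeLength / window)
    mids <- geneMidpoints(annot)
    bin <- (floor(mids / window) %% n) + 1L
    sums <- numeric(n); cnts <- numeric(n)
    for (i in seq_along(bin)) {        # few thousand genes: loop is fine
        sums[bin[i]] <- sums[bin[i]] + expr[i]
        cnts[bin[i]] <- cnts[bin[i]] + 1
    }
    half <- floor(smooth / window / 2)
    kern <- rep(1, 2L * half + 1L)
    rs <- as.numeric(stats::filter(sums, kern, circular = TRUE))
    rc <- as.numeric(stats::filter(cnts, kern, circular = TRUE))
    val <- ifelse(rc > 0, rs / rc, NA_real_)
    val <- circularInterpolate(val)
    out <- data.frame(position = (seq_len(n) - 1L) * window, value = val)
    attr(out, "genome_length") <- genomeLength
    attr(out, "window") <- window
    attr(out, "smooth") <- smooth
    out
}

#' Fisher's g-test for a hidden periodicity
#'
#' g = max(power) / sum(power) over the supplied periodogram ordinates (zero
#' frequency excluded upstream). The exact null p-value under Gaussian white
#' noise is
#' p = sum_{k=1}^{floor(1/g)} (-1)^(k-1) C(n,k) (1 - k g)^(n-1),
#' evaluated term-wise in log space for stability.
#'
#' @param spectrum positive periodogram ordinates (>= 2 values).
#' @return list with \code{g} and \code{p}.
#' @export
fisherGTest <- function(spectrum) {
    n <- length(spectrum)
    if (n < 2L) stop("at least 2 spectral ordinates are required")
    if (any(spectrum <= 0)) stop("spectrum must be positive")
    g <- max(spectrum) / sum(spectrum)
    kmax <- floor(1 / g)
    k <- seq_len(kmax)
    ok <- 1 - k * g > 0
    terms <- numeric(kmax)
    terms[ok] <- exp(lchoose(n, k[ok]) + (n - 1) * log(1 - k[ok] * g))
    p <- sum(terms * (-1)^(k - 1))
    list(g = g, p = min(max(p, 0), 1))
}

#' Least-squares periodic curve fit at a fixed wavelength
#'
#' Fits A cos(2 pi x / lambda + phi) + c by ordinary least squares in the
#' linearized form a cos + b sin + c, then A = sqrt(a^2 + b^2),
#' phi = atan2(-b, a). The linear solve is the global minimizer of the
#' squared error at fixed lambda.
#'
#' @param positions numeric positions (bp).
#' @param values numeric expression values.
#' @param wavelength fixed wavelength (bp).
#' @return list with \code{amplitude}, \code{phase}, \code{offset},
#'   \code{fitted} and \code{residualSS}.
#' @export
fitPeriodicCurve <- function(positions, values, wavelength) {
    theta <- 2 * pi * positions / wavelength
    X <- cbind(cosx = cos(theta), sinx = sin(theta), offset = 1)
    fit <- stats::lm.fit(X, values)
    a <- fit$coefficients["cosx"]; b <- fit$coefficients["sinx"]
    list(amplitude = unname(sqrt(a^2 + b^2)),
         phase = unname(atan2(-b, a)),
         offset = unname(fit$coefficients["offset"]),
         fitted = as.numeric(X %*% fit$coefficients),
         residualSS = sum(fit$residuals^2))
}

#' Periodogram of a spatial profile with max peak and Fisher's g-test
#'
#' Computes the standard periodogram of the mean-removed profile at Fourier
#' frequencies 1..floor(n/2) cycles per chromosome, reports the max-peak
#' frequency and its wavelength, fits the periodic curve at that wavelength,
#' and tests significance with Fisher's g. The g-test uses ordinates
#' 1..floor((n-1)/2) (zero and Nyquist excluded) so its white-noise null is
#' exactly iid exponential.
#'
#' @param profile data.frame from \code{\link{spatialProfile}} (columns
#'   \code{position}, \code{value}).
#' @param genomeLength chromosome length in bp; defaults to the profile's
#'   attribute.
#' @param label optional condition label carried into the result.
#' @return a \linkS4class{PeriodicityResult}.
#' @export
periodogramAnalysis <- function(profile, genomeLength = NULL, label = "") {
    if (is.null(genomeLength))
        genomeLength <- attr(profile, "genome_length")
    v <- profile$value
    n <- length(v)
    if (n < 8L) stop("profile must have at least 8 points")
    v <- v - mean(v)
    if (all(v == 0)) stop("constant profile: no spectrum mass")
    P <- Mod(stats::fft(v))^2 / n
    kmax <- floor(n / 2)
    freq <- seq_len(kmax)
    power <- P[2:(kmax + 1L)]
    peak <- freq[which.max(power)]
    lambda <- genomeLength / peak
    mg <- floor((n - 1) / 2)
    gt <- fisherGTest(power[seq_len(mg)])
    ft <- fitPeriodicCurve(profile$position, profile$value, lambda)
    methods::new("PeriodicityResult",
                 profile = profile[, c("position", "value")],
                 frequencies = as.numeric(freq), power = power,
                 maxPeakFrequency = as.numeric(peak), wavelength = lambda,
                 amplitude = ft$amplitude, phase = ft$phase,
                 offset = ft$offset, fitted = ft$fitted,
                 gStatistic = gt$g, pValue = gt$p,
                 genomeLength = as.numeric(genomeLength),
                 label = as.character(label))
}

#' Chromosomal periodicity of one condition's transcriptome
#'
#' Replicates of the condition are averaged, the circular spatial profile is
#' computed and the periodogram analysed.
#'
#' @param x a \linkS4class{ReorgExperiment}.
#' @param condition condition label (default: all samples averaged).
#' @inheritParams spatialProfile
#' @return a \linkS4class{PeriodicityResult}.
#' @export
chromosomalPeriodicity <- function(x, condition = NULL, window = 1000,
                                   smooth = 1e5) {
    prof <- spatialProfile(x, window = window, smooth = smooth,
                           condition = condition)
    periodogramAnalysis(prof, label = if (is.null(condition)) "" else condition)
}
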