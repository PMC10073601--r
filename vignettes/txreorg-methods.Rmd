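---
title: "Methods: growth fitness and transcriptome reorganization analysis"
author: "txreorg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth fitness and transcriptome reorganization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txreorg)
```

# Scope and model

`txreorg` analyses how a bacterial transcriptome and its growth fitness
reorganize under three kinds of interruption: a genomic one (engineered
genome reduction, wild type N0 versus reduced genome N28), an environmental
one (a growth-inhibiting chemical stressor such as threonine or
chloramphenicol), and an evolutionary one (laboratory adaptive evolution).
The package implements six analysis stages — growth-rate extraction,
expression normalization, chromosomal periodicity, epistasis regression,
Rank Product differential expression with functional enrichment, and
weighted co-expression modules — together with a synthetic-data generator
whose ground truth makes every stage testable end to end.

## Growth rates from OD600 curves

Between consecutive plate-reader measurements the pointwise rate is
$\mu_i = \ln(C_{i+1}/C_i)/(t_{i+1}-t_i)$ (per hour, natural log). The
growth rate of a well is the mean of three consecutive $\mu_i$ chosen by a
windowed rule: take the window with the largest mean; among windows whose
mean is within 1% (relative) of that maximum, take the smallest variance;
remaining ties go to the earliest window. The two criteria can disagree on
noisy curves, so the package fixes this precedence explicitly — the rule's
intent is to find the steady exponential phase, and the variance criterion
only arbitrates between near-equal candidates. Growth fitness of a
condition is the plain mean over replicate wells. Wells whose OD never
doubles are reported as `no_growth` rather than as rate zero: a flat curve
is the absence of measurable exponential growth, not growth at rate 0.
OD values at or below zero are rejected as instrument artifacts rather
than floored.

Stressor working concentrations are picked from a dose-response curve as
the smallest tested concentration whose relative rate decrease reaches a
target (default 30%), refined by linear interpolation of the rate curve at
the threshold rate.

## Expression normalization

Counts convert to FPKM as $\mathrm{count} \times 10^9 / (\mathrm{length_{bp}}
\times \mathrm{depth})$. Expression is analysed as $\log_{10}(\mathrm{FPKM} +
\varepsilon)$ with a per-dataset pseudocount $\varepsilon$ defaulting to the
smallest nonzero FPKM (configurable); the handling of zeros is a genuine
free choice, and a data-driven pseudocount keeps the log scale comparable
across simulated depths. Global normalization shifts each sample additively
on the log scale to the grand mean — equivalently a multiplicative
rescaling of linear values — so downstream statistics that compare samples
see identical location. Sample ordination uses 1 − Spearman correlation
with Ward (ward.D2) agglomeration, and centered, unscaled PCA; PCA signs
follow the convention that each component's largest-magnitude loading is
positive.

## Chromosomal periodicity

The spatial profile assigns each gene to its midpoint on the circular
chromosome and reports, every 1 kb, the mean expression of genes within a
centered 100-kb circular span (a moving average; windows with no gene are
filled by linear interpolation along the circle). Wrap-around smoothing is
used because the chromosome is circular and the coordinate origin is
arbitrary. The periodogram of the mean-removed profile is evaluated at
Fourier frequencies 1..⌊n/2⌋ cycles per chromosome; the max-peak frequency
fixes the wavelength λ = genome length / frequency, and the curve
$A\cos(2\pi x/\lambda + \varphi) + c$ is fitted by least squares in its
linearized form (the global optimum at fixed λ). Significance uses
Fisher's g — the largest ordinate over the spectrum total — with the exact
null p-value $\sum_k (-1)^{k-1}\binom{n}{k}(1-kg)^{n-1}$ evaluated
term-wise in log space. The g-test consumes ordinates 1..⌊(n−1)/2⌋ (zero
and Nyquist excluded) so that its white-noise null is exactly iid
exponential; the max-peak search may still report the Nyquist frequency.
Note that the 100-kb moving average colours the spectrum of pure noise, so
the g-test on smoothed profiles is a test against the smoothed-noise null
only in approximation; for the strong six-cycle signals analysed here the
distinction is immaterial, and the null calibration tests feed unsmoothed
profiles.

## Epistasis regression

Per-gene changes Δ are differences of replicate-mean log expression between
a perturbed condition and the unperturbed reference (ΔG, ΔS, ΔE for single
interruptions; ΔGS, ΔGE, ΔES for dual ones). The epistasis coefficient α
is the through-origin least-squares slope of the simultaneous change on the
sum of the two single changes, $\alpha = \sum xy / \sum x^2$ — the model
ΔGS = α(ΔG + ΔS) has no intercept term, and the package keeps the
interceptless fit as the default while exposing an intercept mode for
sensitivity analysis. α = 1 is additivity; below 1, negative epistasis
(the dual response is damped relative to the sum); above 1, positive.
Classification uses a band of ±0.05 around 1 by default, a reporting
convenience rather than a test. α is invariant to the log base since both
axes rescale together.

## Rank Product differential expression

For two replicate groups, every one-vs-one cross-replicate comparison
(K = n_A × n_B) ranks the genes by fold change — ascending for
up-regulation, reversed for down — and the rank product is the geometric
mean of a gene's ranks, computed in log space, with average ranks on ties.
Significance permutes ranks within each comparison: when the number of
per-gene rank tuples $n^K$ is at most 10^5 the null is enumerated exactly;
otherwise a seeded Monte-Carlo run pools null rank products across genes
and permutations and reports p = (count + 1)/(total + 1), never exactly
zero. The proportion of false predictions, pfp = p·n/rank, is made
monotone along the rank ordering by a step-up pass and clipped to [0, 1].
DEGs are genes whose better direction reaches the pfp threshold (default
0.05; the threshold is configurable because it is an analysis choice, not
a property of the statistic).

One caveat is documented rather than hidden: with cross-replicate pairing
the K fold changes of one gene share replicate values and are therefore
dependent, while the rank-permutation null treats them as independent. A
gene whose replicates happen to be consistently ordered can thus reach a
small p without signal, and the pfp is anticonservative in proportion to
K. The test suite asserts the realistic consequence (a few-percent
false-positive rate among null genes at 3 + 3 replicates) rather than an
idealized zero. A per-gene Welch test with Benjamini–Hochberg adjustment
is included as a clearly labeled substitute branch for count-model
differential expression, which is out of this package's scope.

## Functional enrichment

Regulon and gene-category maps are first intersected with the analysis
universe (the common gene set), then filtered by size: regulons with more
than 10 members (≥ 11) and categories with more than 30 genes (≥ 31), both
read as strict inequalities and both configurable. A gene set of size n
over a universe of size M is tested against a category with m members by
the upper-tail binomial probability with success rate m/M, Bonferroni
corrected over the categories tested together. Module–DEG enrichment uses
the same machinery with modules as categories and Bonferroni over
modules × contrasts.

## Co-expression modules

The unsigned adjacency $|cor|^\beta$ (Pearson) is soft-thresholded at
β = 12 by default; `pickSoftPower()` chooses the smallest candidate whose
scale-free topology fit reaches R² ≈ 0.9, where the fit regresses
log10 p(k) on log10 k over equal-occupancy connectivity bins. The
topological overlap matrix is the standard unsigned TOM
$(l_{ij}+a_{ij})/(\min(k_i,k_j)+1-a_{ij})$. Modules come from
average-linkage clustering of 1 − TOM with a simplified adaptive cut in
place of the published hybrid dynamic tree cut (whose full algorithm is
out of scope): a static cut height is scanned over a grid of merge-height
quantiles, keeping the height that maximizes the number of clusters of at
least `minModuleSize` genes (ties: most genes assigned, then the lower
height), with two guards — heights above 0.99 are not scanned, because a
cluster that only forms at a dissimilarity of essentially 1 has no
topological overlap and is noise; and a membership refinement reassigns
every gene to the module maximizing its mean TOM provided that mean
reaches half the module's median intra-module overlap, which re-attaches
peripheral genes the static cut split off and expels weakly connected
ones. The refinement threshold of one half is a deliberately coarse
cohesion bar: true members sit near the intra-module median while
unconnected genes sit orders of magnitude below it, so the result is
insensitive to the exact factor. Behaviour is validated by
block-recovery adjusted Rand index against planted ground truth, not by
label identity with any particular tree-cut implementation.

Module eigengenes are first principal components of the standardized
member expression, unit variance, sign-aligned to the module mean profile.
Modules whose eigengene dissimilarity (1 − correlation) falls below 0.25
merge iteratively, closest pair first, eigengenes recomputed after each
merge; a second pass changes nothing. Eigengene–trait association uses
Pearson correlation against the per-sample condition growth rate (the
trait is taken at condition level; replicate-level growth measurements are
averaged first) with significance at p < 0.01. Modules are classified from
their DEG-enrichment pattern across the six contrasts: enriched nowhere —
conserved; enriched in the single stress contrast S but in neither GS nor
ES — epistatic (the stress response vanishes under a dual interruption);
any other enrichment — responsive.

# The synthetic-data generator

`generateExpression()` builds log10 expression as

baseline + spatial cosine + condition effects + module factors + noise,

with every generating value recorded in a truth object so downstream
expected values can be computed without re-running the generator. The
defaults encode the study conditions this package targets:

* ~4,000 genes packed without overlap on a circular 4.6-Mb chromosome
  (one gene per equal slot, length ≥ 50 bp, midpoint used as the gene's
  coordinate; intervals are 1-based closed in the `GRanges`
  representation and written 0-based half-open in BED output);
* a six-cycle spatial cosine of amplitude 0.3 log10 units;
* a 2×2×2 condition design (genome × stressor × evolution) in biological
  duplicate, the replicate number the study design uses for most
  conditions;
* per-gene single-interruption effects drawn from a Gaussian of sd 1.2
  log10 units for an affected minority (fractions 0.40/0.35/0.15 for
  G/S/E, chosen to match a DEG fraction of roughly a third of the genome
  with conventional fold changes well above twofold);
* dual (and triple) interruption conditions receive
  `alphaTrue` × (sum of the single effects), the generative reading of the
  epistasis regression, with `alphaTrue` = 0.6 by default (mid-range
  negative epistasis);
* replicate noise sd 0.2 log10 units;
* 11 latent-factor modules with sizes from 30 to 1,118 summing to 3,290
  genes, loadings uniform on [0.5, 1]; the growth-linked module's factor
  is the negated standardized condition growth rate, and all other
  factors are orthogonalized against the growth-rate profile so that
  "uncorrelated with growth" is true by construction rather than only in
  expectation;
* logistic growth curves (lag, exponential phase, saturation) sampled at
  30-min intervals over 48 h with multiplicative lognormal noise;
* a deterministic condition → growth-rate map with a canceling pattern:
  the stressor slows the wild-type genome ~30% but not the ancestral
  reduced genome, the reduced genome grows ~28% slower, and evolution
  improves it while restoring stressor responsivity.

Replicate noise is Gaussian on the log scale — the noise model is not
dictated by the data-processing conventions the package follows, and
lognormal expression noise is the standard assumption at this level of
abstraction. Counts are simulated by a multinomial draw with expectation
proportional to linear expression × gene length, the exact inverse of the
FPKM conversion.

What the generator does **not** emulate: operon and regulon correlation
structure beyond the planted modules, the actual deleted regions of a
reduced genome (gene loss is represented only as a smaller common gene
set), count overdispersion beyond multinomial sampling, and spatial
autocorrelation of expression beyond the single chromosome-scale cosine.
Tests passing on this generator therefore demonstrate correctness of the
computations and recoverability of planted structure, not robustness to
every property of real RNA-seq data.

# Validation scenarios and problem sizes

Each validation scenario enables exactly the generator features the stage
under test consumes, so that recovery checks are well-posed: periodicity
runs use the spatial cosine with replicate noise but no condition effects
or modules (amplitude 0.3, noise 0.3, 100 seeds); epistasis recovery uses
condition effects without modules (3,000 genes, noise 0.1, slopes 0.4–1.3,
20 seeds each); module recovery uses modules without condition effects
(the full 11-module, 3,290-gene layout, 20 seeds), since condition effects
are themselves shared expression patterns that would add unplanted
co-expression structure and make the planted partition an incomplete
description of the truth. Fisher's g calibration uses 10,000 white-noise
profiles at 8, 16 and 32 spectral ordinates; growth-rate recovery uses
rates 0.2–1.0 per hour with 1% multiplicative noise, and the window rule
is checked against an exhaustive window search on 1,000 random rate
sequences. These sizes keep the full suite to a few minutes while leaving
the statistical margins (e.g. ±0.05 on slope recovery, 95% detection
rates) far from their failure boundaries.

# Numerical choices and degenerate inputs

* Fisher's g p-value terms are computed as
  `exp(lchoose(n,k) + (n-1)*log(1-kg))` and the alternating sum is clipped
  to [0, 1]; terms with 1 − kg ≤ 0 vanish.
* The periodic-curve fit solves the linear system (cos, sin, 1) rather
  than optimizing (A, φ) directly; A = √(a²+b²), φ = atan2(−b, a).
* Rank products are accumulated as sums of log ranks; exact-null
  comparisons use a 10⁻⁹ slack so ties count as "at or below".
* Matrix powers |cor|^β use repeated squaring for integer β.
* Degenerate inputs error loudly and early: non-positive OD (with the
  offending index), non-increasing time, constant sample profiles under
  Spearman distance, constant genes in the network, all-zero samples in
  normalization, empty gene intersections, categories empty within the
  universe, a constant trait, and an identically zero additive change in
  the epistasis regression.
* Welch's test on two zero-variance groups returns p = 1 for equal means
  (no evidence) and p = 0 for separated constants.

# Known limitations

* The window rule for growth rates is an extreme-value selection: it takes
  the best of many overlapping three-point windows, so measurement noise
  biases the extracted rate upward, appreciably so for slow growth where
  the exponential phase spans many windows (at 1% OD noise and 30-min
  sampling the bias approaches the noise scale of a single window mean,
  several percent of a 0.2 h⁻¹ rate). Widening the variance-arbitration
  band trades this for a downward bias near saturation at fast growth;
  no setting removes both, which is an intrinsic property of the rule
  rather than of its implementation. The `meanTol` argument exposes the
  trade-off.
* The adaptive tree cut is intentionally simpler than the published
  hybrid algorithm; only partition recovery is claimed, not equivalence.
* The Rank Product permutation null ignores cross-replicate dependence
  (discussed above).
* The binomial enrichment test treats draws as independent
  (with-replacement); for gene sets that are a large fraction of the
  universe a hypergeometric model would be tighter.
* Periodicity smoothing is a moving average; a binned (non-overlapping)
  mean is the main alternative reading of a "100-kb bin" convention and
  yields a coarser but unbiased profile. The moving average was chosen
  for its regular 1-kb output grid; the choice is exposed through the
  `window`/`smooth` arguments.
* Replicates are averaged before profiles and deltas; per-replicate
  pairing is not implemented.
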