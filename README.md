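# txreorg

Growth fitness and transcriptome reorganization analysis for bacterial
genomes under genomic, environmental and evolutionary interruptions.

## The problem

When an *Escherichia coli* genome is experimentally reduced (strain N28 vs
the wild-type N0), exposed to a growth-inhibiting stressor (threonine or
chloramphenicol), or adapted by laboratory evolution, both its growth rate
and its transcriptome reorganize — and when two interruptions act at once,
their effects need not add. `txreorg` provides the complete analysis chain
for quantifying this:

* **Growth fitness** from OD600 microplate curves: pointwise rates
  μᵢ = ln(Cᵢ₊₁/Cᵢ)/(tᵢ₊₁ − tᵢ), with the growth rate taken as the mean of
  the three-point window with the largest mean (smallest variance among
  near-ties), and dose–response picking of stressor concentrations at a
  ~30% rate decrease.
* **Expression processing**: counts → FPKM → log10 with global
  normalization to an identical per-sample mean, common-gene subsetting,
  Spearman/ward.D2 clustering and unscaled PCA.
* **Chromosomal periodicity**: 1-kb sliding / 100-kb smoothed expression
  profile on the circular chromosome, periodogram max peak, least-squares
  cosine fit, and Fisher's exact g-test of periodicity.
* **Epistasis regression**: per-gene changes Δ under single (ΔG, ΔS, ΔE)
  and dual (ΔGS, ΔGE, ΔES) interruptions, with the through-origin slope α
  of ΔGS = α(ΔG + ΔS); α < 1 is negative epistasis (mutual canceling),
  α = 1 additivity, α > 1 positive epistasis.
* **Differential expression** by Rank Product (geometric-mean fold-change
  ranks across all cross-replicate comparisons) with an exact or seeded
  permutation null, pfp-based FDR calls, up/down discrimination and Venn
  overlaps.
* **Functional enrichment** of DEG sets in regulons and gene categories by
  the one-sided binomial test with Bonferroni correction and the
  size filters (> 10 regulatees, > 30 genes).
* **Co-expression modules**: soft-thresholded unsigned adjacency
  (β = 12), topological overlap matrix, adaptive tree cut
  (min module size 50), eigengene merging at height 0.25, growth-rate
  trait correlation, and classification of modules as conserved /
  responsive / epistatic from their DEG-enrichment pattern.
* **A synthetic-data generator** with full ground truth (spatial cosine
  periodicity, tunable epistasis coefficient, planted co-expression
  modules, logistic growth curves) so the whole pipeline is testable
  without any external data.

The central containers are Bioconductor objects: a `ReorgExperiment`
(extending `RangedSummarizedExperiment`) holds log-expression with the
condition design and gene coordinates; S4 result classes
(`PeriodicityResult`, `EpistasisResult`, `RankProdResult`,
`ModuleAssignment`, `GrowthRateResult`) carry accessors and validity
checks.

## Worked example

```r
library(txreorg)

d  <- syntheticDesign(seed = 42)      # the default study-scale design
g  <- generateExpression(d)
re <- g$experiment                    # 4,000 genes x 16 samples

chromosomalPeriodicity(re, condition = "N0.none.anc")
#> PeriodicityResult (N0.none.anc)
#>   profile: 4600 windows over 4,600,000 bp
#>   max peak: 6 cycles; wavelength 766,667 bp
#>   fit: A = 0.312 phase = -0.149 offset = 1.92
#>   Fisher g = 0.8898 , p = 0

epistasisAnalysis(re, pairs = "GS")$GS
#> EpistasisResult (GS ~ G+S)
#>   alpha = 0.4665 -> negative epistasis
#>   n genes: 4000 ; R2 = 0.592

cur <- generateGrowthCurves(mu = 0.7, noiseSd = 0.01, seed = 42)
growthFitness(cur)$fitness
#> [1] 0.688
```

The periodicity readout shows the six-cycle chromosomal wave the generator
plants (wavelength = 4.6 Mb / 6 ≈ 767 kb) detected with overwhelming
significance despite replicate noise. The epistasis slope 0.47 < 1 reads
the generator's built-in negative epistasis (the estimate sits below the
generating coefficient 0.6 because module factors and replicate noise
attenuate the regression; the dedicated recovery scenarios in the test
suite isolate the effect structure and recover α to ±0.05). The growth
fitness 0.688 h⁻¹ recovers the generating rate 0.7 within 2%.

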