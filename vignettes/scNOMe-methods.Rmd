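---
title: "Models and methods in scNOMe"
author: "scNOMe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in scNOMe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scNOMe)
```

# The assay and the computational problem

Single-cell NOMe-seq couples a GpC methyltransferase (M.CviPI) treatment
with bisulfite sequencing: the enzyme methylates cytosines in GpC
dinucleotides wherever chromatin is accessible, so a single bisulfite
library carries two signals — endogenous CpG methylation and enzymatic GpC
accessibility. With a parallel Smart-seq2 readout, the same cell also
yields a transcriptome. Because accessibility is encoded in the conversion
state rather than in read counts, inaccessible chromatin is directly
distinguishable from missing data, and the resolution is set by the
genomic frequency of GpC dinucleotides (about one per 16 bp in a
uniform-composition genome) rather than by fragment size.

The computational framework in this package takes per-cell Bismark-style
cytosine reports, genomic feature annotations, expression counts and QC
statistics, and produces: channel-separated site calls, per-feature rate
matrices for both epigenetic layers, coverage-weighted correlation scans
between layers, single-cell accessibility-profile models around TSSs with
mixture clustering, expression prediction, pseudotime, and
coupling-dynamics tests.

# Separating the two channels

Each cytosine is classified by its trinucleotide, read 5'→3' on the
cytosine's own strand (minus-strand contexts are reverse complements).
A–C–G and T–C–G feed the CpG methylation channel. G–C–A, G–C–C and G–C–T
feed the GpC accessibility channel. G–C–G is discarded from both channels
because endogenous and enzymatic methylation are indistinguishable there;
C–C–G is discarded from the CpG channel to guard against enzyme off-target
activity. Edge cytosines and N-containing contexts classify as `NONE`. The
genome sequence is authoritative; trinucleotides stored in report files
are treated as advisory (`partitionReport` warns or errors on
disagreement, and `trustReport = TRUE` skips the genome lookup).

`contextCensus` scans both strands exhaustively and reports per-label
counts, CpG/GpC dinucleotide totals (so exclusion shares can be quoted
per cytosine or per dinucleotide, whichever a reader needs), and the mean
spacing between consecutive GpC dinucleotides per chromosome.

# Rates

Per site, reads are modelled as Binomial(n, θ) with a Beta(α, β) prior on
θ; the reported rate is the posterior mode (α = β = 1 reduces it exactly
to the empirical proportion) and the standard error is the posterior
standard deviation. The prior hyperparameters default to a per-cell,
per-layer method-of-moments fit: the variance of the raw site proportions
is first corrected for binomial sampling noise using the observed counts
(`v = (v_raw − μ(1−μ)·E[1/n]) / (1 − E[1/n])`), since otherwise shallow
coverage would masquerade as biological spread and the prior would be far
too diffuse. Degenerate spreads fall back to the flat prior with a
warning, and returned hyperparameters are clipped to ≥ 1 so the mode is
interior.

Feature-level rates are inverse-variance-weighted means of the site rates
overlapping the feature (1-based inclusive intervals, boundaries
inclusive), with `se = sqrt(1/Σ se_i⁻²)`. When every site has the same
standard error this is the plain mean. Across cells, features are
summarised with a random-effects model: between-cell variance τ² is
estimated by the DerSimonian–Laird method of moments and the reported sd
is τ, i.e. genuine between-cell spread after subtracting measurement
noise.

CpG strand pairs are quantified separately by default; symmetric merging
(`mergeSymmetricCpG`) is available but off, because merging changes the
effective site count entering coverage weights and the default keeps the
site-level records exactly as reported.

# Quality control and normalisation

`qcFilter` applies per-layer thresholds; a cell passes a layer iff it
violates none of that layer's active thresholds. Two presets are shipped:
`"es"` (minimum 300,000 mapped reads, ≤ 15% mitochondrial reads, ≥ 2,000
genes, ≥ 10% mapping efficiency, ≥ 500,000 CpG and ≥ 5,000,000 GpC sites)
and `"eb"` for shallower libraries (100,000 reads, 300,000 CpG sites, no
GpC minimum).

Expression counts are normalised with median-of-ratios size factors
(geometric-mean reference over genes detected in all cells, library-size
fallback for cells with no such genes, factors rescaled to mean 1)
followed by log2(x + 1). This is a deliberate, simpler stand-in for
pooling-based deconvolution factors; at the cell numbers this package
targets (tens of cells) the median-of-ratios estimate is stable and the
downstream analyses use ranks or correlations that are insensitive to the
residual difference.

# Correlation scans

Associations between layers are tested with a coverage-weighted Pearson
correlation: weights enter every moment, and equal weights reduce it
exactly to the textbook estimator. Whenever methylation participates in a
pair, the CpG coverage is the weight; for accessibility–expression the GpC
coverage is used by analogy (the choice is exposed, not hard-wired).
Weights are rescaled to mean 1 per test.

The locus scan (`acrossCellsScan`, one test per locus) applies the
filters of the study design: entries with fewer than 3 covered sites are
missing; a locus needs at least 20 jointly observed cells; only the top
50% most variable loci per genomic context are tested (ties at the cut
kept), and for expression pairs genes below the median expression
variance are removed first (independent filtering — loci and genes that
cannot vary cannot correlate, and removing them ahead of testing raises
power without touching the null). P-values are two-tailed Student's t and
BH-adjusted within each context; significance is called at FDR < 0.1.

One numerical choice deserves a note: the t-test's degrees of freedom use
the Kish effective sample size `(Σw)²/Σw²` rather than the raw cell
count. Unequal weights inflate the null variance of the weighted
correlation, and in null simulations the raw count produced visibly
anti-conservative p-values (about 6.5% below 0.05 at nominal 5%), while
the effective size restores calibration (per-family false-discovery
proportion 0.085 ± 0.02 at nominal 0.1 over 200 simulated families).

The per-cell scan (`acrossGenesScan`, one test per cell) correlates the
two layers across qualifying loci of one context within each cell, and
also returns the pseudo-bulk correlation computed on cell-mean matrices
with cell-mean weights.

Promoter windows are layer-specific: ±50 bp around the TSS for
accessibility (the NDR is narrow), ±2 kb for methylation, ±200 bp for
single-cell profile fitting. Features are associated to the nearest gene
whose body ±10 kb contains the feature midpoint (±5 kb is the convention
for pseudo-bulk expression stratification).

# Single-cell accessibility profiles

Within ±200 bp of a TSS, the probability that a GpC site at scaled
position x ∈ [−1, 1] reads accessible is modelled as Φ(h(x)ᵀw) — a probit
GLM over M = 9 Gaussian radial basis functions with centres equally
spaced on [−1, 1], width equal to the centre spacing, plus an intercept.
An L2 penalty of λ = 0.01 on the non-intercept weights stabilises sparse
windows without visibly biasing dense fits. The penalised likelihood is
strictly concave, so Fisher scoring (with step-halving and linear
predictors clipped to ±7) converges to the unique optimum and the fit is
seed-free; two arbitrary starts agree in fitted curve to 10⁻⁶. Genes are
eligible for profiling when at least 40% of cells have at least 10
covered GpC sites in the window (both bounds inclusive).

Per gene, cells are clustered by EM over mixtures of profile weight
vectors sharing the Bernoulli/binomial likelihood: a cell's likelihood
under a cluster is the likelihood of its raw observations under the
cluster curve, which automatically weights deeper-covered cells more —
the package's resolution of how per-cell coverage should enter the
mixture. Initialisation is k-means on the per-cell fitted weights with 5
restarts (3 in the large recovery experiments); restarts that collapse a
cluster (mixing proportion < 10⁻⁸) are discarded. K is chosen by BIC
(−2 logL + p log N, p = K(M+1) + K−1, N = cells) over K = 1..6 by
default, ties to the smallest K. The binomial coefficient is omitted from
logL; it is constant across K and cancels in the comparison.

Expression prediction compares two per-cell feature sets across genes —
the scalar window rate versus the fitted profile weights — in a linear
regression per cell, reporting in-sample adjusted R² (which accounts for
the differing feature counts) and 10-fold (5-fold in the shipped
experiments) cross-validated Pearson r. Gene-set enrichment is a 2×2
Fisher exact test per set with BH across sets; odds ratios are the sample
cross-product ratio.

# Pseudotime and coupling dynamics

Pseudotime is computed from expression only: cells are embedded with a
diffusion map over the top overdispersed genes (variance residuals above
a rolling-median mean–variance trend; top 500 by default). The kernel is
Gaussian with locally scaled bandwidths (each cell's scale is its
distance to the 5th nearest neighbour), density-normalised (α = 1);
pseudotime is the min–max-scaled rank of cells along the first
nontrivial eigenvector. Rank, not diffusion distance, is used because a
single linear trajectory is assumed and ranks are robust to density
variation along it. The sign of an eigenvector is arbitrary, so
orientation is fixed by a user-named marker gene expected to decrease (or
increase) along the trajectory; flipping the expected direction maps τ to
1 − τ exactly.

Profile dynamics along pseudotime are tested per gene by projecting the
per-cell fitted profiles onto their first principal axis and correlating
the projection with τ (Spearman), with a permutation p-value (1,000
permutations by default, fixed seed) and BH across genes. The projection
is computed in curve space — the weight vectors mapped through the basis
onto a 25-point grid — rather than on raw weights: the two are the same
linear functional family, but correlated basis functions leave raw
weights with huge variance along near-null directions of the design,
and a PCA on raw weights picks up exactly that noise. This test is the
package's own construction and is documented as such.

Coupling dynamics are summarised by correlating each cell's
methylation–accessibility correlation coefficient with its pseudotime,
per context, with a two-tailed t-test; a negative trend means coupling
strengthens along the trajectory.

# The synthetic generator

The generator emulates the statistical structure the analyses assume, at
two resolutions.

The site-level generator (`simulateCells`) writes per-cell cytosine
reports over a simulated genome: a phased nucleosome array with the
configured repeat length (190 bp default) shared across cells, jittered
per cell by Gaussian noise (sd 10 bp) — so pseudo-bulk profiles keep
repeat-length periodicity while single cells differ; NDRs at promoters
whose openness (probability 0.8 by default, optionally ramped along
pseudotime) is driven by a per-(cell, gene) latent factor; GpC emission
at 0.8 in linker/NDR DNA and 0.1 under nucleosomes (dyad ± 73 bp); CpG
methylation from beta-distributed locus means with logit-scale cell
deviations anti-correlated with the accessibility factor; all
trinucleotide contexts emitted (G–C–G sites superimpose both signals;
partitioning is the pipeline's job); binomial reads at mean depth 5 per
covered site with coverage probability 0.3 and a symmetric conversion
error of 0.005. Reads are simulated at site level, not as fragments,
because the pipeline consumes cytosine reports and fragment simulation
adds no tested behaviour. Only covered sites are emitted.

The rate-level generator (`simulateFeatureRates`) produces the same
latent layer directly at feature resolution — 100 loci over 40 cells by
default, with 20 loci carrying methylation–expression coupling of latent
strength −0.8 and a genome-wide methylation–accessibility coupling of
−0.5 — and is the backbone of the statistical recovery and calibration
experiments. Two of its design choices matter for interpreting those
experiments. First, loci sit on a continuum of between-cell
heterogeneity (logit-scale sds drawn uniformly), and coupled loci occupy
its variable end with intermediate mean rates: a locus whose epigenetic
state genuinely switches between cells is necessarily variable and
mid-range on average, and this is precisely what makes variance-based
independent filtering informative rather than a coin flip. Second, in
trajectory mode half of the genes follow smooth pseudotime trends with
amplitude 3 on the log2 scale (roughly eight-fold across the trajectory,
typical of differentiation markers), with gene 1 a monotone decreasing
marker used for orientation.

What the generator does not emulate: real genome composition and CpG
islands, fragment-level read structure and mapping artefacts,
incomplete-conversion biases beyond a flat flip, copy-number effects, or
doublets. Tests passing on this generator therefore demonstrate that the
estimators and tests recover the structure they are designed for at
realistic noise levels — not that any particular biological dataset will
show that structure.

QC statistics in the site-level output are drawn at realistic magnitudes
(around 10⁶ mapped reads, 10⁶–10⁷ covered sites) so the QC module is
exercisable; they are not derived from the emitted reads.

# Numerical choices and degenerate inputs

* Probit fits: linear predictors clipped to ±7, probabilities to
  [10⁻¹⁰, 1−10⁻¹⁰]; Fisher scoring with step-halving; convergence at
  relative penalised-likelihood change < 10⁻¹¹.
* EM: relative log-likelihood change < 10⁻⁶ or 200 iterations; empty
  clusters trigger a restart; a K whose restarts all degenerate is
  excluded; BIC ties resolve to the smallest K.
* Variance ranking ties at the 50% cut keep both loci.
* Zero-coverage sites are missing values, never errors; zero weighted
  variance makes a correlation undefined and the unit is skipped.
* BED records with start ≥ end are rejected with a warning; coordinates
  are converted exactly between 0-based half-open and the internal
  1-based inclusive convention.
* `simulateTrajectory` requires at least 10 cells; diffusion pseudotime
  errors on a disconnected kernel graph and suggests increasing the
  neighbour index.

# Problem sizes in the shipped checks

The package's own verification experiments run at desk scale, chosen so
the full suite completes in minutes: null FDR calibration uses 20
simulations of 500 loci × 40 cells; power uses 20 simulations of the
default 100-locus condition; cluster recovery uses 20 mixtures of 40
cells with K ∈ {1,2,3} and candidates 1–4 with 3 restarts; periodicity
uses 50 cells over a 20 kb genome; prediction uses 20 replicates of 50
genes × 25 cells; trajectory recovery uses 60 cells. These sizes are the
package's choices for routine verification; all are configurable.

# Known limitations

* The scans test linear association only; nonlinear or conditional
  couplings are out of scope.
* Missing rates are not imputed; loci failing the coverage filters are
  simply untested.
* The trajectory machinery assumes a single linear trajectory; branching
  topologies are not modelled.
* Enrichment is generic over user-supplied gene sets; no ontology
  database ships with the package.
* The number of trajectory-associated genes reported by
  `profileTrajectoryAssociation` depends strongly on coverage and cell
  number and should be read as data-dependent, not as a calibrated
  constant.
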