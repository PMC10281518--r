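---
title: "Simulating and scoring imaging-based high-content RNAi screens"
author: "hcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring imaging-based high-content RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

## The problem

Arrayed RNAi screens read out a per-cell fluorescence phenotype — here,
the nuclear level of an overexpressed, fluorescently tagged centromeric
histone variant (CENP-A), whose nuclear accumulation is a proxy for its
mislocalization to chromosome arms and the chromosomal instability that
follows. A library of several hundred genes is arrayed one siRNA per
well, three independent siRNAs per gene, across 384-well plates with
scrambled negative controls and signal-increasing positive controls in
the last two columns, and the screen is run in two biological
replicates. The analysis must separate genuine gene effects from plate
artifacts (edge gradients, dispenser drift along rows and columns),
measurement noise, and single-oligonucleotide off-target activity.

Raw screen images and measurement tables for such screens are rarely
deposited, so this package makes the entire chain testable on synthetic
data with known ground truth: every stage can be validated against the
generating parameters rather than against an unavailable reference.

## The generative model

Well values are simulated on the **additive scale** (the analysis below
never log-transforms, so the generator is additive too):

$$y_{prc} = \beta + g_{G(s)} \cdot \pi_s + o_s + \rho_{pr} + \kappa_{pc}
+ \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2)$$

where $\beta$ is the baseline intensity (default 1000 a.u.), $g$ an
additive gene effect, $\pi_s \in [0,1]$ the potency of siRNA $s$ for its
target gene (drawn Uniform(0.5, 1) — three siblings of one gene share
$g$ but differ in potency), $o_s$ a per-siRNA off-target effect
(default 0; used to model decoys whose single strong oligonucleotide
should *not* make a gene a hit), and $\rho$, $\kappa$ additive row and
column artifacts drawn per plate and per replicate (defaults
Uniform$[-200, 200]$ and $[-100, 100]$; measurement noise sd defaults
to 10). Positive-control wells get a fixed +300 shift, mirroring a
depletion that increases the readout. Each well's nuclei count is
Poisson with mean `cellsPerWellMean * attrition` (1500 seeded cells,
40% imaged).

Library siRNAs fill columns 1–22 in row-major order, sibling siRNAs
consecutive, spilling across plates (521 genes × 3 siRNAs → 5 plates of
352 library wells, the fifth partially empty). The real fill order of
such libraries is not standardized; row-major is pinned here for
reproducibility and has no effect on the statistics. Column 23 carries
the negative control in odd rows; column 24 alternates two
positive-control siRNAs by row parity.

## Image rendering and quantification

`renderWellImage()` draws non-touching, optionally boundary-perturbed
ellipses (low-frequency radial harmonics scaled by `irregularity`), a
DAPI channel with per-nucleus level jitter and a YFP channel whose
per-nucleus mean is the requested target, then applies Gaussian focus
blur and pixel noise (Gaussian by default, optional Poisson
resampling). The emitted truth table records area, centroid, roundness
and the **mean of the pre-noise (post-blur) YFP channel** over each
truth mask — the exact ground truth of the image as written, equal to
the target when blur and foci are off. Images are unquantized numeric
matrices in memory; the file convention is 16-bit unsigned TIFF
(`writeChannelTiff()`, with a 32-bit float variant where quantization
matters).

Quantification mirrors a high-content pipeline whose internals are
proprietary in the commercial software, so the recipe here is plain and
deterministic: Gaussian smoothing → global Otsu threshold → hole fill →
watershed on the distance transform → minimum-area filter (50 px at the
default 256×256 scale). The smoothing sigma should match the optical
blur of the images; fields with very irregular nuclear outlines warrant
a larger `watershedTolerance` (3 instead of the default 1) to avoid
oversplitting lobed shapes.

**Roundness.** The shape filter is $4\pi A / P^2$, clipped to $[0,1]$,
with holes filled first. The perimeter estimator matters: raw
boundary-pixel or chain-step counts are biased enough that a digitized
disk scores far from 1. We use the Crofton four-direction perimeter
(computed from the sixteen 2×2 pixel configuration counts), under which
a disk of radius 20 px scores ≈ 0.97 and a 1×50 px line ≈ 0.07. Nuclei
with roundness strictly below 0.775 (mostly segmentation artifacts) and
nuclei touching the image border are excluded; a value exactly at the
threshold is kept ("below … excluded" reads as strict-less exclusion).
The threshold is exposed because its effect depends on the estimator;
equivalence with any specific commercial pipeline's per-well numbers is
not claimable.

The well readout is the **unweighted mean of per-nucleus mean YFP**
(each cell weighted equally — not pixel-pooled, not area-weighted),
plus a signal-per-nucleus ratio (summed per-nucleus means over the
total segmented count). Wells with zero kept nuclei propagate as
missing through all downstream statistics.

Coordinates throughout are 1-based (row, column) matrix indices with
the origin at the top-left, the idiomatic R convention; masks and
images share geometry.

## The statistics chain

1. **B-score per plate.** A two-way median polish is fitted to the
   plate's *library wells only* — control and empty wells are treated
   as missing, so an extreme control cannot shift the fit, and the
   polish overall term is the plate's library median (the centrality
   parameter). Residuals against the fitted additive surface are
   computed for every well and divided by $1.4826 \times$ MAD of the
   plate's library residuals (per-plate variance adjustment; the
   constant makes the MAD a consistent Gaussian-sd estimate). A zero
   MAD flags the plate degenerate and zeroes its scores.
2. **Z-score per replicate.** All wells of a biological replicate are
   scored against the replicate's pooled library wells. The robust
   variant (median, $1.4826\times$MAD) is the default, consistent with
   the B-score's philosophy; a classical mean/sd variant is available.
   Whether the original analysis used robust or classical scoring, and
   per-plate or per-replicate references, is not documented anywhere we
   can verify, so both are exposed and the choice is pinned in
   configuration.
3. **siRNA level.** The siRNA-level Z is the arithmetic mean of the
   available replicate Z-scores (normally two).
4. **Gene level.** The gene-level Z is the median of the gene's
   siRNA-level Z-scores — with three siRNAs, the second strongest
   effect, so one strong (possibly off-target) oligonucleotide cannot
   carry a gene. Genes are ranked descending, ties broken on gene id;
   hits are genes at or above a configurable threshold (no fixed cutoff
   is canonical; ranking is the primary output).

**Numerical choices.** Median polish sweeps rows first; sweep order can
change results on pathological grids, so it is pinned. Defaults are 20
sweeps at relative tolerance $10^{-6}$ (scale = MAD of the input).
Convergence is geometric rather than exact, and even-dimension grids
occasionally traverse long plateaus (thousands of sweeps with a small,
constant per-sweep change) before collapsing to the fixed point; the
sweep loop is therefore compiled, and experiments that compare against
an independently converged fit use `maxIter = 5000`, `tol = 1e-12`.
All-missing rows/columns get zero effects with a warning, and the
recentering medians run over fitted rows/columns only, so control
wells on partially filled plates are scored against a sensible
surface. Missing wells stay missing through scoring; a gene's median
uses its available siRNAs.

**What the B-score assumes.** Median polish removes whatever additive
row/column structure it sees — including true signal, if most wells in
a row or column are active. The chain is therefore exactly
rank-preserving only when true effects are sparse relative to rows and
columns; densely active designs are normalized against their own
signal. Conversely, with *zero* measurement noise and sparse effects
the library residual MAD is 0 and the degeneracy rule zeroes the plate.
Both behaviours are inherent to B-scoring, not artifacts of this
implementation.

**What the median-of-three can and cannot do.** A decoy gene whose
single siRNA carries a large effect gets, as its gene median, the
*maximum of its two null siblings* — stochastically above the null
median-of-three. In a 521-gene screen the decoy therefore lands in the
top 20 with roughly 19% probability per decoy (an order-statistics
fact, independent of the normalization scale). The rule reduces, but
does not eliminate, single-oligonucleotide false positives.

## Spot quantification

For metaphase-spread measurements, 8×8 px boxes are placed on listed
spot centers (centromeric = the brightest primary-constriction focus;
non-centromeric = any other arm location) and the box maximum is taken.
Background is the mean of the maxima of four seeded-random, mutually
disjoint 8×8 boxes fully inside the cytoplasm mask, subtracted from
each spot maximum; negative corrected values are kept (clipping would
bias condition means) and flagged. Condition summaries report mean,
s.e.m. (per-spot replication by default) and fold change versus a
reference. Because the readout is a *maximum*, noise adds a positive
bias (≈ 2.5σ on a flat 8×8 background) that partially cancels in the
background subtraction; the recovery experiments therefore use
high-SNR renders (noise sd 1–5 against amplitudes 100–430), matching
the regime in which such box-maximum measurements are meaningful.
Significance testing wraps the two standard procedures: the unpaired
two-tailed Student t-test (pooled variance by default, Welch optional)
and one-way ANOVA with Tukey HSD post hoc comparisons.

## Pipeline, determinism, problem sizes

`runPipeline()` chains simulate → (optional render + quantify) → score
→ report under one global seed; per-stage seeds derive from it by a
fixed affine hash (`stageSeed()`), so stages can be rerun in isolation.
Reruns are bit-identical on every CSV output. The image path renders
each measured well at its simulated value and re-quantifies it; with
zero render noise and blur this path reproduces the direct path's gene
ranking exactly, a two-route consistency check on the whole chain.

The validation experiments use: 100 random 8×12 grids (10% missing) for
the polish oracle; one fully measured 16×24 plate for artifact removal
and control immunity; the full 521×3×2 design over five seeds for
hit/decoy recovery; 20 rendered wells of 30–80 nuclei at 256×256 for
the image stage; a 20-gene screen for the two-path comparison; and ~100
rendered spots per spot-recovery condition. These sizes keep every
experiment comfortably reproducible on a laptop while leaving the
statistics well out of the small-sample regime.

## What the synthetic data does not model

Single-plane 2D rendering only (no z-stacks, no PSF beyond Gaussian
blur); no transfection-efficiency or cell-cycle heterogeneity; no
illumination or camera-background artifacts (assumed corrected
upstream); nuclei are perturbed ellipses, not real nuclear morphology;
spots are isotropic Gaussians on a flat background rather than
chromosomes. Passing the recovery experiments therefore demonstrates
the correctness of the *analysis chain* under the stated generative
model, not the performance of the segmentation or spot measurement on
real micrographs.
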