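---
title: "Methods: from single-cell morphology to NF-kB localization"
author: "morphloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell morphology to NF-kB localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphloc)
```

## Overview

`morphloc` implements a single-cell morphometry pipeline for high-content
screens that relate cell shape and microenvironmental context to the
nuclear localization of a transcription factor (the NF-kB subunit
p65/RelA being the motivating case). The pipeline has five analysis
stages — feature extraction, well profiling, dependency-network
inference, shape-response regression, and translocation dynamics — plus a
synthetic-data stage that generates images, single-cell tables,
fold-change panels and oscillation traces with known ground truth, so
every downstream stage is testable without access to screen data.

## The NF-kB ratio and the region model

Each cell is partitioned into nucleus, cytoplasm, membrane band and
perinuclear ring. The activation proxy is

$$ \mathrm{tf\_ratio} = \frac{\overline{I_{TF}}(\mathrm{nucleus})}
   {\overline{I_{TF}}(\mathrm{perinuclear\ ring})}, $$

the ratio of mean TF-channel intensity over the nucleus to that over the
perinuclear ring (the cytoplasmic reference just outside the nucleus).
Ratios are reported in log10, matching the order-of-magnitude spread seen
across single cells. Cells whose ring carries no signal are flagged and
excluded.

Region construction choices (configurable):

* perinuclear ring width `ring_width = 4` px, membrane band width
  `band_width = 3` px; the original screen's values are unpublished.
* Ring/band morphology uses an exact Euclidean disc structuring element
  with a quarter-pixel radius augmentation, which compensates the mean
  raster-boundary deficit of digitized regions; a 4-px ring around a
  20-px nucleus then has close to $\pi(24^2-20^2)$ pixels.
* Cytoplasm for the area ratio is `cell - nucleus`, so
  $A_{nuc}/A_{cyto} = A_n/(A_c - A_n)$. This is one of two possible
  conventions; it is applied consistently in the generator and extractor.

## Segmentation

Nuclei are found on the nuclear stain by Otsu thresholding, opening,
hole filling, and distance-transform watershed splitting of touching
nuclei (EBImage). Cell bodies are grown from the nuclei by seeded
Voronoi propagation on the body stain (`EBImage::propagate`,
`lambda = 1e-4`), masked to above-threshold pixels. Cells touching the
image border are flagged but retained by default. Blank channels yield
an empty result rather than an error.

## The 77-feature catalog

`feature_catalog()` defines 77 features in five categories: cell and
nuclear geometry (areas, chain-code perimeters, isoperimetric roundness
$4\pi A/P^2$, fitted-ellipse length/width and eccentricity, extent,
solidity, equivalent diameter, area ratios), protrusion (boundary arcs
whose radial distance exceeds a circularly Gaussian-smoothed outline,
$\sigma = 10$ px, by more than 15%), polarity (nucleus-to-cell centroid
distance, absolute and relative), context (neighbor fraction, neighbor
count, colony size and area, edge/border flags, nearest-neighbor
distance), and intensity (per-region mean/SD/total for both channels,
membrane ruffliness, and the TF ratios). The exact definitions of the
original screen's catalog are unpublished; the names and categories here
follow its published description and the definitions are package
conventions, stated in the function documentation.

Neighbor fraction (NF) is the fraction of a cell's boundary pixels whose
8-neighborhood touches a different cell label — 0 for an isolated cell,
approaching 1 for a fully enclosed one. Colonies are connected
components of the contact graph. A cell is a colony-edge cell when its
NF falls below 0.5 or it touches the image border.

The perimeter estimator is the 8-connected chain code with corrected
step weights (0.948 axial, 1.340 diagonal), which gives digitized disks
of radius 20 px and above roundness indistinguishable from 1 at the 5%
level.

Ruffliness is the coefficient of variation of body-channel intensity
over the membrane band, a proxy for membrane ruffling; the original
operator ("variations in membrane intensity") is unpublished.

## The synthetic scene generator

Cells are rendered as radially perturbed ellipses: a base ellipse of
specified area and eccentricity, multiplied by smooth random harmonics
(orders 3–8, normalized to the requested ruffle amplitude) and optional
Gaussian protrusion lobes. Colonies are laid out on hexagonal shells;
contested pixels between abutting cells are resolved by the smaller
normalized radius, so contacting cells share boundaries and never
overlap. Nuclei are offset ellipses constrained to fit strictly inside
their cell ($f_{radius} + f_{offset} < 0.9$); nucleus pixels always
belong to their own cell, and cross-cell nucleus overlap raises a
placement error.

The TF channel paints the cytoplasm at a baseline intensity and the
nucleus at baseline x ratio, where each cell's ratio is the planted
target times optional lognormal cell-to-cell noise (the distributional
form of cell-to-cell NF-kB heterogeneity is not established, so it is a
parameter, not a fixed model). The body channel modulates the membrane
zone with the same harmonic pattern that perturbed the boundary, so
rendered ruffliness tracks the ruffle amplitude. Because abutting
cells would otherwise be separated by a perfectly flat stain — an
optically invisible boundary no segmenter could recover — the generator
renders a subtle junctional intensity dip (0.72x) along shared
boundaries, as real membrane stains resolve cell-cell junctions.

Ground truth: analytic feature values are not well-defined once abutting
claims are resolved pixel-wise, so the truth table records the catalog
measured on the *true* label images, plus the planted per-cell TF ratio.
Extractor-vs-truth tests therefore measure the fidelity of the full
segmentation + measurement path; on 9-cell colony scenes the worst-case
disagreement is below 1% for area, 0.04 for NF and 1% for the TF ratio,
within the stated tolerances (2%, 0.05, 5%).

What the generator does **not** emulate: point-spread functions, shot
noise, uneven illumination, 3D structure, mitotic/apoptotic debris and
segmentation-confusing textures. Passing tests demonstrate correctness
of the measurement definitions and pipeline plumbing on resolvable
scenes, not robustness to real microscopy artifacts.

## Well profiling, PCA and clustering

Cells aggregate to per-well feature means; features are standardized as
$(x - \bar x)/\mathrm{SD}$ with the population (divisor-$n$) SD,
matching the screen's printed Z-score formula. PCA is the
eigendecomposition of the covariance of the Z matrix (scores on the
first 8 PCs by default); whether the original analysis used correlation
or covariance of Z-scores is ambiguous, but the two coincide when the
SD scaling is exact, and Z + covariance is the default here. Cell lines
are clustered on mean PC scores with distance = 1 − Pearson correlation
of centered score vectors and centroid linkage, mirroring the
centered-correlation/centroid-linkage configuration of the Cluster 3.0
tool used by the screen. `hclust`'s centroid method formally expects
squared Euclidean distances; applying it to correlation distances
reproduces that tool's behaviour and can produce inversions, which are
tolerated.

## Discriminative feature selection

Within each line/condition, cells are split into high vs low TF
log-ratio groups at the upper and lower quartiles (the screen's split
rule is unpublished; quartiles are robust and keep groups balanced).
Each feature is compared between groups with a Welch t-test; a group
votes for a feature when $P < 0.01$ (the screen's pervasive significance
convention), and no multiplicity correction is applied at the voting
stage because cross-line vote counting is itself the robustness
mechanism. Features are ranked by votes (ties: mean |t|, then name) and
the top 17 form the network node set.

## Dependency networks

The 17 features plus the TF log-ratio are quantile-discretized into 3
states. For each of B = 100 bootstrap resamples, a DAG is learned by
greedy hill climbing (add/delete/reverse moves, 5 random restarts, at
most 3 parents per node) maximizing the BDeu score with equivalent
sample size 1 — the standard score-based choice for discretized
single-cell data; the screen's exact learner is unpublished. Edge
confidence is the fraction of resamples containing the adjacency in
either orientation; an edge is reported directed only when at least 70%
of its supporting resamples agree on direction, mirroring the published
networks' undirected lines where "the dependency cannot be determined".
Dependencies are reported at confidence > 0.6 (the published display
cutoff), with > 0.9 available where a stricter call is wanted. An
option treats the TF node as a sink (no outgoing edges) for sensitivity
analysis; it is off by default. Oriented consensus edges are kept
acyclic by demoting (to undirected) any orientation that would close a
cycle, in decreasing confidence order.

The hill climber is validated against exhaustive enumeration of all 25
DAGs on three nodes, scored by an independently written BDeu
implementation. A note on planted-structure tests: a *continuous*
linear chain X→Y→Z discretized to 3 levels genuinely loses the
conditional independence of X and Z (coarse binning leaks information
around the middle variable), so structure-recovery tests plant the chain
at the discrete level (a 3-state noisy channel), where the Markov
property holds exactly.

## Shape-response regression

Per-condition fold changes are treated/control ratios of well-average
values (raw, not log-transformed, following the published phrasing; a
log-scale fit is a trivial user-side variant). The model is OLS with
intercept:

$$ \Delta tf = c_0 + c_{NF}\,\Delta NF + c_{ruff}\,\Delta ruffliness
   + c_{ratio}\,\Delta(A_{nuc}/A_{cyto}) + \varepsilon $$

reporting $R^2$, residual (error) variance, the overall F-test P value
and a residual-normality check. Tenfold cross-validation uses seeded
simple random fold assignment (the original assignment rule is
unspecified); the CV error is the mean absolute held-out error per fold
("average error"; MAE matches the printed magnitude's scale, and RMSE is
reported alongside). Outliers are conditions outside the full-fit 95%
*prediction* interval — the statistically coherent reading of a "95%
confidence interval of the predicted value" applied to individual
conditions.

The synthetic fold-change panel draws predictors lognormally around 1
(`sdlog = 0.15`) and uses default coefficients
`(1.0, -0.30, +0.25, -0.35)` whose signs encode the screen's finding
(NF and the area ratio suppress, ruffliness enhances the NF-kB
response). `panel_noise_for_r2()` solves the noise SD for a target
population $R^2$ in closed form; at the screen's scale (176 conditions,
$R^2 = 0.37$) the fitted $R^2$ across seeds concentrates around the
target with SD ≈ 0.06. The printed regression coefficients of the
original screen are not recoverable from the main text, so no numeric
coefficient values are asserted anywhere — only sign structure and fit
quality on calibrated synthetic panels.

## Translocation dynamics

`simulate_trace()` is anchored at its examples: the deterministic part
rises from the baseline at t = 0 along a quarter-sine ramp to exactly
`baseline + amplitude` at `first_peak_time`, then follows
$\cos(2\pi(t-t_1)/P)$ under an envelope $e^{-(t-t_1)/\tau}$. A single
global exponential envelope with a cosine phase would neither start at
the baseline nor peak at the stated height, so the envelope is applied
after the first peak; successive maxima are then spaced exactly one
period apart. Defaults encode the study conditions: baseline 1.0, first
peak at 30 min, period 115 min (midpoint of the reported 110–120
band), damping timescale 100 min, 5-min sampling over 6 h.

First-peak metrics: the first local maximum whose topographic prominence
exceeds 3x the robust noise SD (MAD of first differences / sqrt(2));
amplitude is peak minus the value at t = 0 (stimulation occurs
essentially at movie start). Traces still rising at the last sample are
flagged `boundary`; monotone decreasing traces `no_peak`.

Wavelet analysis: linear detrend, then a Morlet continuous wavelet
transform (center frequency $\omega_0 = 6$, the default of the wavelet
toolbox family used in this literature) over 60 log-spaced periods
spanning 30–240 min, computed by the standard FFT formulation with
zero padding. The cone of influence is the $\sqrt{2}s$ e-folding
distance from either edge; dominant periods are argmax of power outside
the COI, and instantaneous amplitude is recovered from |W| with the
analytic Morlet normalization (a pure sinusoid of amplitude A returns
~A, with a modest negative bias from zero padding that cancels in
relative comparisons). Near the COI edge the dominant period of any CWT
estimator necessarily tracks the largest unmasked scale, so
"interior" in the recovery guarantees means times where the true
period's scale is itself outside the COI. For a 6-h trace that leaves
roughly t in [160, 200] min usable at 115-min periods — which is why
period histograms are evaluated at a late fixed time on longer traces,
and why null-instability is measured across independent traces at a
fixed time rather than along a single trace.

## Determinism and problem sizes

Every generator takes an explicit seed and restores the caller's RNG
state; the pipeline derives one seed per stage from a master seed and
writes a manifest with seeds, thresholds and md5 hashes, and rerunning
a configuration reproduces every CSV/JSON byte-identically. The test
suite exercises the stages at deliberately desk-sized conditions — 9-
and 100-cell rendered scenes, 5,000-cell planted tables, 3-node network
oracles, 176-condition panels, 40-trace panels — chosen to make the
statistical contracts (confidence > 0.9 on planted edges, 3-SE
parameter recovery, one-grid-step period recovery) sharp while keeping
the full suite in the minutes range.

## Known limitations

* The scene generator's optics are idealized (no PSF/shot noise); the
  extractor's robustness to real microscopy artifacts is untested here.
* `hclust` centroid linkage on correlation distances can invert; use
  average linkage if monotone dendrograms are required.
* The BDeu learner caps parents at 3 by default; dense dependency
  structures would need a higher cap and more restarts.
* Wavelet period estimates are unavailable within the cone of
  influence; 6-h traces constrain long-period (>130 min) estimates to a
  narrow mid-trace window.
* The discretization-leakage effect means continuous chain structures
  are not expected to yield exactly the generative skeleton; this is a
  property of discrete structure learning in general, not of this
  implementation.
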