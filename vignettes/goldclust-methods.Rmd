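---
title: "Immunogold nanocluster statistics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunogold nanocluster statistics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldclust)
```

## The measurement and its model

Immunogold EM of intact plasma-membrane sheets yields, per image, a set of
gold-particle coordinates $(x_i, y_i)$ in nanometres inside a rectangular
observation window of area $A$ (canonically the 1 µm² sheet,
`spatial_window(0, 1000, 0, 1000)`). Each particle marks one
antibody-labelled protein copy; the question is whether the labelled
protein clusters with itself (nanoclustering, homodimerization) or with a
second protein labelled by a different gold size (coclustering,
heterodimerization).

`goldclust` answers both with second-order point-pattern statistics:

$$K(r) = \frac{A}{n^2} \sum_{i \ne j} w_{ij}\,
  \mathbf{1}\!\left(\lVert x_i - x_j \rVert \le r\right), \qquad
  L(r) - r = \sqrt{K(r)/\pi} - r,$$

evaluated on a 1 nm grid from 1 to 240 nm. Under complete spatial
randomness (CSR) the expectation of $K(r)$ is $\pi r^2$ and $L(r)-r$ is
centred at zero; clustering drives it positive. For two species ("big"
gold, count $n_b$, and "small" gold, count $n_s$, sharing one window) the
cross functions

$$K_{bs}(r) = \frac{A}{n_b n_s} \sum_{i=1}^{n_b} \sum_{j=1}^{n_s}
  w_{ij}\, \mathbf{1}(d_{ij} \le r), \qquad
  K_{biv}(r) = \frac{n_b K_{sb}(r) + n_s K_{bs}(r)}{n_b + n_s}$$

and $L_{biv}(r)-r = \sqrt{K_{biv}(r)/\pi} - r$ measure coclustering;
independence of the two populations gives expectation $\pi r^2$ for
$K_{biv}$.

### Edge correction

Particles near the window boundary have unobserved neighbours, which
biases the raw pair counts downward. The default weight $w_{ij}$ is
Ripley's isotropic correction: the reciprocal of the fraction of the
circle centred at $x_i$ with radius $d_{ij}$ that lies inside the window,
computed in closed form by inclusion–exclusion over the four window edges
and corners. This form is exact as long as no circle engulfs an entire
window side, which always holds on the 1–240 nm grid in windows at least
480 nm wide; weights are only evaluated for pairs with $d_{ij}$ inside
the grid, since farther pairs never enter the indicator sum. A toroidal
(wrap-around metric) correction is available as an option; it makes all
pair weights exactly symmetric, which is what gives the exact label-swap
invariance of $K_{biv}$ and the exact equality $K_{bs} \equiv K_{sb}$
asserted in the tests.

### Monte Carlo envelopes and standardization

Significance is assessed per image against seeded Monte Carlo null
simulations matched to the image's own particle count and window:

* univariate null: CSR (uniform points), pointwise **99th** percentile of
  $L(r)-r$ across simulations (default 1000, minimum 100);
* bivariate null: spatial independence, implemented by default as random
  toroidal shifts of the small-gold pattern (uniform shift vector with
  wrap-around, big gold fixed). This preserves each species' internal
  clustering and destroys only the cross-correlation, which is the
  correct independence null when species self-cluster; a CSR resampling
  null is available for parity with the univariate analysis. Pointwise
  **95th** percentile.

Percentiles interpolate linearly between order statistics (R's default
type-7 estimator), and the simulation seed is recorded in the envelope.
The observed curve is divided pointwise by the envelope, so 1.0 marks the
confidence boundary at every $r$. As $r \to 0$ the envelope approaches
zero and the ratio would explode; grid points where the envelope falls
below $\varepsilon = 10^{-3}$ nm are flagged undefined and excluded from
summaries, and the Lmax search starts at $r = 10$ nm for the same reason.
Pointwise division is the only normalization consistent with a constant
significance threshold of 1.0 at all $r$, which is why it was adopted.

### Summary statistics

* **Lmax** — the maximum of the standardized univariate curve over
  10–240 nm (ties broken toward smaller $r$); `significant` means
  strictly greater than 1.0.
* **LBI** — the trapezoidal integral of the standardized bivariate curve
  over the fixed 10–110 nm range on the 1 nm grid. The trapezoidal rule
  with included endpoints was chosen because a curve lying exactly on the
  envelope (unit integrand) then integrates to exactly 100, the published
  significance threshold; `significant` means LBI > 100. Undefined grid
  points inside the range raise an error rather than being interpolated.
  Negative standardized values are integrated as-is: segregation lowers
  LBI below zero rather than being clipped.

Multi-image studies analyze each sheet independently with its own
image-matched envelope and pool summaries as mean ± SD, retaining
per-image records — the per-sheet-then-combine design used for this kind
of data. A single-image study reports SD 0 with a warning.

## Oligomer classification

The per-particle local function
$K_i(r) = A (n-1)^{-1} \sum_{j \ne i} w_{ij} \mathbf{1}(d_{ij} \le r)$
(and its $L_i(r)-r$ transform) diagnoses each particle's neighbourhood
crowding. Classification itself uses a deliberately simple, fully
specified rule: link every pair closer than a **link radius**, take
connected components (single linkage; components delegated to `igraph`),
and report per-particle fractions in components of size 1 (monomer), 2
(dimer) and ≥ 3 (higher-order oligomer). The link radius is taken from
the data — the radius of the standardized global peak, clamped to
10–50 nm — with a 30 nm fallback for non-significant patterns, roughly
the span of a primary antibody plus gold conjugate on both partners.

Two error modes are inherent to any linkage rule at realistic labelling
densities (~170 particles/µm²): *splits* (labelling jitter pushes a true
pair beyond the radius) and *chance mergers* (independent clusters land
within the radius of one another). At 170/µm² with a 20 nm radius,
mergers inflate the oligomer class of an individual image by up to
~0.15–0.19; no radius removes both error modes. Per-image fractions are
therefore best treated like the other per-image statistics: pooled across
sheets. Pooled over 20 replicate sheets the class fractions are within
±0.1 of the generator truth at ~120 particles/µm² (the package's
parameter-recovery test condition), and the bias shrinks further at lower
density. The peak-based automatic radius can also overshoot the true
spacing on sparse, noisy patterns (the standardized curve stays elevated
beyond the clustering scale); when the spacing is known, supplying the
radius directly is preferable.

## Synthetic generators: what they emulate and what they do not

The generators reproduce the statistical structure the estimators assume,
at the study's labelling densities (~169–186 particles/µm², default 170):

* `generate_csr` — the null model itself.
* `generate_oligomer_mixture` — cluster anchors uniform in the window;
  members of a size-$k$ cluster on a regular $k$-gon of side `spacing`
  (nearest within-cluster neighbour exactly `spacing` when jitter-free)
  plus isotropic Gaussian labelling jitter (default 0 for analytic tests;
  3 nm for realism, the nm-scale antibody–gold linkage displacement).
  Truth labels are attached for recovery tests.
* `generate_thomas` — parents uniform, Poisson offspring displaced by an
  isotropic Gaussian; offspring wrap toroidally into the window so the
  realized density equals the nominal one (clipping would thin edges).
  Large $\sigma$ approaches CSR.
* `generate_bivariate` — independent CSR pairs; linked patterns placing a
  fraction of small particles at a fixed distance from distinct big
  partners (the heterodimer-like alternative); segregated half-window
  patterns.

All generators are deterministic under a fixed seed and validate counts
and window containment. They do **not** emulate micrograph pixelation,
gold-particle detection error, steric exclusion between gold conjugates,
labelling efficiency below 100%, or membrane curvature — so passing
recovery tests demonstrate correctness of the estimators and
classification logic under the stated point-process models, not
robustness to those instrument effects on real micrographs.

## Numerical choices and degenerate inputs

* Distances are continuous nm values; no pixel quantization. Coincident
  points are legal (two particles can project to the same position) and
  contribute indicator 1 at all $r$ with weight 1.
* $K$ estimators require $n \ge 2$ (each species $\ge 1$ for the cross
  functions); envelopes require $\ge 100$ simulations.
* When no window is supplied with a coordinate table, the bounding box of
  the points is used and should be considered a fallback: it
  underestimates the sampled area, so supplying the true sheet window is
  always better.
* Seeds: every stochastic operation accepts a seed; multi-image studies
  derive independent per-image seeds from one master seed; `NULL` seeds
  draw from (and advance) the current RNG stream so envelope loops can
  run inside one outer seed.
* Prey identity in the set operations is the symbol after case
  normalization and whitespace trimming; SAINT-score thresholds are
  inclusive (≥); reported percentages are rounded to integers for prose
  parity, with unrounded values retained.

## Problem sizes used in the packaged checks

The test suite and the reproduction script favour moderate, seeded
problem sizes chosen to exercise every code path with stable statistics:
envelopes of 100–200 simulations in tests (1000 in the reproduction
script, where the 99th/95th percentiles are well estimated), 500 CSR
simulations for the null-centering check, 10–20 replicate sheets for
calibration and recovery properties, and patterns of 40–170 particles
per µm². The identities at the significance boundaries (standardized
envelope ≡ 1.0; LBI of the boundary curve = 100) are exact by
construction and independent of simulation count.

## Known limitations

* The isotropic correction's closed form assumes the circle never
  contains an entire window side — satisfied on the default grid for
  windows ≥ 480 nm wide, but very small windows with large grids are not
  supported.
* Inhomogeneous intensity (varying labelling density across the sheet) is
  not modelled; the K-estimators assume stationarity within the window.
* LBI magnitude is not a stoichiometry estimate: it grows with both the
  linked fraction and the tightness of linkage, so equal LBIs do not
  imply equal dimer fractions.
* Single-image significance calls inherit the multiple-comparison
  looseness of maximizing (Lmax) over the $r$ grid; the per-image false
  positive rate under CSR is above the nominal pointwise 1% and is
  bounded in the tests only as a smoke property (≤ 20%).
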