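---
title: "Radar image reconstruction for breast microwave sensing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radar image reconstruction for breast microwave sensing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmsradar)
```

## The imaging problem

Breast microwave sensing (BMS) probes the breast with microwaves and exploits
the dielectric contrast between malignant and healthy tissue. In a monostatic
radar configuration a single antenna is stepped around the breast on a
circular arc; at each position $a$ the complex reflection coefficient
$S_{11}(a, f)$ is recorded over a stepped-frequency sweep. The reconstruction
task is to map these measurements to a spatial image of scattering strength —
the *reflectivity profile* $\sigma(\mathbf r)$ — in the imaging plane.

All methods in this package share one signal model. Assuming straight-ray
propagation at a homogeneous speed $v$, the one-way time of flight from the
antenna at $\mathbf a$ to a point $\mathbf r$ is
$t(\mathbf r, \mathbf a) = |\mathbf r - \mathbf a| / v$, and a monostatic
measurement accumulates the round-trip phase $2t(\mathbf r, \mathbf a)$. The
first-order (Born-style, single-scattering) forward model is

$$
S_{\mathrm{fwd}}(a, f; \sigma)
  = \int_V \mathrm d\mathbf r\, \sigma(\mathbf r)\,
    e^{-2\pi j f\, 2 t(\mathbf r, \mathbf a)} ,
$$

discretized by the midpoint rule over the pixel centres of a regular
Cartesian grid with quadrature weight $\Delta A$ (the pixel area), so that
$S_{\mathrm{fwd}} = \Delta A \sum_p \sigma_p e^{-2\pi j f\,2 t_p}$. The
midpoint rule is the simplest quadrature consistent with the model and makes
the single-measurement identity below *exact on the grid*, not merely
approximate.

This model deliberately ignores antenna beam patterns, frequency-dependent
gain, distance attenuation, transmission losses at interfaces, and
propagation-speed heterogeneity. Those omissions are exactly why one-step
reconstructions degrade on measured data; the optimization formulation exists
to make the model explicit and improvable.

## One-step beamformers

**DAS.** The delay-and-sum beamformer compensates each measurement for the
round-trip phase to the candidate pixel and sums coherently:

$$
I(\mathbf r) = \sum_a \sum_f S(a, f)\, e^{+2\pi j f\, 2t(\mathbf r, \mathbf a)} .
$$

**Phase-sign convention.** The forward model delays with
$e^{-2\pi jf\,2t}$; image formation must *undo* that delay, so the
beamformer multiplies by the complex conjugate phasor $e^{+2\pi jf\,2t}$.
With this convention DAS is exactly the adjoint of the discretized forward
operator (up to the weight $\Delta A$), which yields two identities the test
suite verifies to machine precision:

* for a single measurement $(a_0, f_0)$, the profile
  $\sigma_D(\mathbf r) = \tfrac1V S(a_0, f_0) e^{+2\pi j f_0 2t(\mathbf r,
  \mathbf a_0)}$ — i.e. DAS scaled by $1/V$, $V$ the domain area — fits the
  measurement *exactly*, driving the data-fit loss to zero; and
* $\langle \mathrm{forward}(\sigma), S\rangle = \Delta A\,\langle \sigma,
  \mathrm{DAS}(S)\rangle$ for all $\sigma, S$ (the adjoint identity that
  underpins the optimization gradient).

One sometimes sees the DAS sum written with the same phasor sign as the
forward model; that variant fails both identities, so this package uses the
phase-compensating form throughout.

**DMAS.** The delay-multiply-and-sum beamformer multiplies delay-compensated
signal pairs from *distinct* antenna positions before summation. With
$x_{a,f}(\mathbf r) = S(a,f) e^{+2\pi jf\,2t(\mathbf r, \mathbf a)}$,

$$
I(\mathbf r) = \sum_f \sum_{a \ne a'} x_{a,f}(\mathbf r)\, x_{a',f}(\mathbf r)
  = \sum_f \Big[ \big(\textstyle\sum_a x_{a,f}\big)^2
    - \textstyle\sum_a x_{a,f}^2 \Big] .
$$

The autoproduct terms $a = a'$ are excluded, following the DMAS literature;
the square-of-sum-minus-sum-of-squares closed form implements the exclusion
exactly (verified against the explicit double loop). Products are taken per
frequency before the frequency sum. A single-position scan therefore has an
identically zero DMAS image, and the constructor refuses it with an error.

Neither beamformer applies any normalization ($1/V$ or otherwise) —
normalization is a display concern, and both metrics used here (SCR, LE) are
invariant under global positive scaling.

## The optimization-based reconstruction (ORR)

ORR poses reconstruction as complex least squares:

$$
\sigma_{\mathrm{img}} = \arg\min_\sigma\; \ell(\sigma), \qquad
\ell(\sigma) = \sum_a \sum_f
  \big| S_{\mathrm{fwd}}(a, f; \sigma) - S_{\mathrm{expt}}(a, f) \big|^2 ,
$$

solved by gradient descent from the all-zero profile. Because the residual
is complex, the descent direction is the Wirtinger gradient with respect to
the conjugate variable; for the linear model $S_{\mathrm{fwd}} = \Delta A\,
A\sigma$ it is the adjoint applied to the residual,

$$
\bar\nabla \ell = \Delta A \sum_{a,f}
  e^{+2\pi jf\,2t(\mathbf r,\mathbf a)}
  \big( S_{\mathrm{fwd}} - S_{\mathrm{expt}} \big)(a, f) ,
$$

so the very first ORR step is a scaled DAS image, and subsequent steps
refine it against the data. The iteration stops when the relative change of
the loss between successive iterates is at most `stop_tol_percent` (default
0.1, i.e. 0.1%), read as an *absolute* relative change since descent makes
the raw difference negative. A `max_iterations` cap (default 500) guards
runs that never reach the tolerance, and a loss of exactly zero terminates
immediately (the relative criterion is undefined at zero).

**Step size.** The step size is not fixed by the method, so two modes are
provided. The default is Armijo backtracking (shrink 0.5,
sufficient-decrease constant $10^{-4}$) started at $1/\hat L$, where
$\hat L$ estimates the largest eigenvalue of the normal operator by 20 power
iterations from a deterministic start vector — this keeps every trace
bit-reproducible and guarantees a monotone non-increasing loss sequence. A
fixed-$\alpha$ mode mirrors plain gradient descent literally; it detects
divergence (a configurable number of consecutive loss increases, default 5)
and aborts with advice to reduce $\alpha$ or switch to backtracking.

Because $\ell$ is a linear least-squares objective, gradient descent from
zero converges to the minimum-norm least-squares solution; on small dense
instances the converged loss matches an independent normal-equations solve
to well within 1% (tested), and it can never exceed the loss of the
$1/V$-scaled DAS profile (also tested). $\sigma$ stays complex throughout;
displayed images are magnitudes $|\sigma|$.

**Operator handling.** The flattened phase matrix
(`(positions × frequencies) × pixels`) is precomputed when it fits a byte
budget (default 512 MiB) and otherwise applied frequency-by-frequency in a
streaming loop; both paths agree to rounding error and the tests check it.

**Second-order model.** An optional forward model adds double-scattering
paths antenna → $\mathbf r'$ → $\mathbf r$ → antenna with phase
$e^{-2\pi jf[t(\mathbf r',\mathbf a) + t(\mathbf r,\mathbf r') +
t(\mathbf r,\mathbf a)]}$ and one factor of $\Delta A$ per integral. Its
cost scales with the pixel count squared, so a guard refuses oversized
grids. In this package it is used as a *data generator*, not a
reconstructor: data simulated with second-order scattering and reconstructed
with first-order algorithms carry a controlled model mismatch that stands in
for the non-idealities of measured data.

## Image metrics and the detection rule

**SCR** $= 20\log_{10}(T_{\max}/C_{\max})$ in dB, with $T_{\max}$ the
maximum image magnitude in the target region and $C_{\max}$ the maximum in
the clutter region. Design decisions, since the defining ratio leaves both
regions open:

* *Target region*: the disc of radius $r_{\mathrm{tum}} + \delta r$ about
  the known tumour centre, where $\delta r$ is the tumour-positioning
  uncertainty (default 4 mm). Using the same radius as the localization
  acceptance rule keeps the two criteria consistent.
* *Clutter region*: all pixels inside the breast-boundary circle and outside
  the target disc; evaluating over the whole image is a config option.
* *Healthy images*: a healthy phantom has no tumour, so its metadata carries
  the *nominal* tumour geometry of its paired tumour scan (the emulated
  protocol fixes the tumour position per phantom), and the same geometric
  rule applies.
* *Degenerate images*: a zero clutter maximum gives $+\infty$ with a
  warning; an image that is identically zero over the evaluation region has
  no target response and gives $-\infty$ (not a detection).

**LE** $= |\mathbf r_{\max} - \mathbf r_{\mathrm{tum}}|$, the distance from
the global magnitude maximum to the known tumour centre. Ties at the maximum
break deterministically (lowest row, then column) with a warning.

**Detection rule** (threshold 1.5 dB by default): healthy images with
SCR ≥ threshold are false positives, otherwise true negatives. Tumour images
with SCR < threshold are false negatives; with SCR ≥ threshold, an
LE ≤ $r_{\mathrm{tum}} + \delta r$ (boundary inclusive) is a true positive
and anything farther counts as a false negative in the sensitivity. The
threshold comparison is taken as ≥ (the rule-statement form) where prose
descriptions sometimes say "greater than". Sensitivity is
TP/(TP+FN), specificity TN/(TN+FP); empty denominators are flagged
undefined rather than silently zero. The ROC sweep re-applies the rule at
1000 linearly spaced thresholds in [0, 30] dB with the LE rule unchanged,
which makes both sensitivity and false-positive rate non-increasing in the
threshold.

Note a geometric consequence of the target-region choice: when the target
disc radius equals the LE tolerance, SCR ≥ 0 dB already implies the global
maximum lies in the target disc, so the "localized too far" miss branch is
reachable only through explicit metric tables (it is still implemented and
exhaustively tested at the rule level).

## The synthetic scan generator

The generator emulates the *structure* of an open-access monostatic BMS
phantom dataset so the whole stack runs without downloads: circular-arc
scans (full preset: 72 positions over 355°, 1001 frequencies over 1–9 GHz),
layered phantoms (adipose disc, fibroglandular inclusions, optional tumour
with diameters from {10, 15, 20, 25, 30} mm, fixed per-phantom tumour
position), a per-scan reference triplet (healthy, adipose-only, empty
chamber), 4 mm positioning uncertainty, and per-phantom healthy scans.
Cohort geometry is randomized from documented ranges (breast radius
45–65 mm, centre jitter ±10 mm, fibroglandular radius 10–20 mm) with the
tumour kept at least one largest-tumour radius inside the breast disc.
Rasterization sums tissue amplitudes where discs overlap, except that the
tumour *replaces* the tissue it displaces. Noise is complex circular
Gaussian per component, default 0 (noiseless baseline; the realistic level
of a VNA measurement is instrument-specific and is left as a free
parameter).

Reflectivity amplitudes are free parameters of the emulation — the physical
phantoms they imitate have material properties, not reflectivities. The
defaults (adipose 10, fibroglandular 30, tumour 50, arbitrary units) encode
two choices made once: tumour > fibroglandular > adipose contrast, and an
absolute scale at which second-order scattering contributes roughly 10–20%
of the reference-subtracted signal, so that order-2 data exercises a
mismatch comparable in spirit to the strong model violations seen in
measured scans. The propagation speed defaults to $c_0/\sqrt{\bar\epsilon}$
with $\bar\epsilon = 3$ (a mostly-air path with partial tissue traversal)
and the antenna arc radius to 0.15 m; both are configuration parameters, as
neither is fixed by the method.

**What passing tests do and do not show.** The generator produces data from
the package's own forward models, so noiseless first-order tests verify the
*algorithms* (adjoint consistency, convergence, localization) — they cannot
validate the physics against real tissue. Second-order generation probes
robustness to one specific, controlled model violation; real measurements
violate the model in several additional ways (beam patterns, attenuation,
dispersion, skin reflections) that this simulator deliberately does not
emulate. Headline sensitivity/specificity numbers from physical datasets are
therefore not reproduction targets here; the package reproduces the
*analytic* identities exactly and the qualitative ordering of the methods
under controlled mismatch.

## Problem sizes used in the shipped analyses

Desk-scale sizes, chosen as the package's own defaults for
simulation-based analyses:

* *Scaled protocol* (default): 24 positions over 355°, 51 frequencies over
  1–9 GHz, 40×40 grid over a 16 cm square (4 mm pixels). The full 72×1001
  protocol remains available as a preset.
* *Recovery analysis*: 3 phantoms, 15 mm tumours, noiseless first-order
  data, adipose reference; all three algorithms localize to within one
  pixel diagonal and classify as true positives.
* *Mismatch study*: 20 healthy phantoms, 16 positions, 21 frequencies,
  30×30 grid, second-order generation, first-order reconstruction, adipose
  reference. The false-positive comparison is directional only (the
  beamformers jointly false-alarm more than ORR); individual rates are
  seed-dependent.

## Known limitations

* 2D imaging plane only; the "volume" of the single-measurement identity is
  implemented as domain area, matching the planar reconstruction setting.
* The forward models are scalar and lossless; no antenna model, no
  dispersion, no skin layer.
* Plain gradient descent only — the optimization formulation admits better
  optimizers and regularization, but the shipped method commits to the
  unregularized least-squares objective.
* The adapter for externally measured datasets is a documented manifest
  schema (`cohort_manifest()`) plus delimited-text S-parameter I/O; it has
  not been validated against any specific archive's files.

## A minimal worked example

```{r example, eval = FALSE}
proto <- scan_protocol(scaled = TRUE)
grid <- image_grid(c(-0.08, 0.08), c(-0.08, 0.08), 40, 40)
spec <- phantom_spec(
  breast_radius = 0.055, breast_amplitude = 10,
  tumour = list(centre = c(0.02, 0.01), radius = 0.0075, amplitude = 50))
rec <- simulate_scan(spec, proto$geometry, proto$freqs, grid, seed = 7)
data <- subtract_reference(rec$target, rec$adipose_ref)

fit <- orr_reconstruct(data, grid)
fit$trace
classify_detection(fit$image, rec$metadata)
```
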