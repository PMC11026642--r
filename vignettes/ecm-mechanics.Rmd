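---
title: "Models and methods: lung ECM mechanics and imaging quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: lung ECM mechanics and imaging quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmech)
```

This vignette is the package's account of its science: the models it
fits, the assumptions and numerical choices behind them, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where the underlying analysis tradition leaves options open.

## The measurement problem

Decellularized lung ECM is very soft (hundreds of Pa) and is probed by
AFM with a compliant cantilever (k = 0.03 N/m) carrying a 5 µm silica
bead. Sections are measured both collapsed (residual volume, RV) and
inflated (functional volume, FV), in young and aged animals, so the
scientific questions are factorial: does age change stiffness, does
inflation, and does the effect of one depend on the other? Alongside
mechanics, the composition of the ECM is read out from
immunofluorescence stains, and the behaviour of reseeded stromal cells
from nuclear, proliferation and viability stains.

## Force-curve mechanics

### Forward model

For a rigid sphere of radius $R$ on an elastic half-space the Hertz
relation is

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

where $\delta$ is the indentation. On a soft sample with a compliant
lever the piezo displacement divides between cantilever bending $F/k$
and indentation, so the observable relation is implicit:
$\delta = (z - z_0) - F/k$. The synthetic generator solves this per
sampled $z$ by bracketed root finding (the residual
$g(F) = a(\mathrm{d}z - F/k)^{3/2} - F$ is monotone, so the bracket
$[0, \min(k\,\mathrm{d}z,\ a\,\mathrm{d}z^{3/2})]$ always contains the
root; tolerance $10^{-15}$ N). At ~0.5 kPa and 1 µm indentation the
bending correction is tens of nm — small but not negligible, which is
why both the generator and the fit carry it.

Assumptions inherited from the Hertz model: linear elasticity, small
strain, a semi-infinite sample, no adhesion inside the contact. Finite
section thickness ("bottom effect") and adhesive-contact models
(JKR/DMT) are out of scope; the fit window below mitigates the former.

### Contact point

The contact point $z_0$ must be estimated per curve. Threshold or
first-crossing heuristics fail at sub-kPa moduli because the initial
contact force rises as $\delta^{3/2}$ from zero. The package instead
minimizes the *whole-curve* residual over candidate contact points: for
each candidate, a straight baseline is fit to the pre-contact samples, a
Hertz power law (with the compliance correction, amplitude constrained
non-negative) to the post-contact samples, and the summed squared
residual is the objective. The search evaluates a grid of candidate
sample positions (~120 candidates) and then refines between samples by
golden-section/parabolic minimization (`stats::optimize`). On noiseless
synthetic curves the recovered $z_0$ is within a few nm of truth; the
test suite also checks the search against an exhaustive
every-sample-position oracle.

A curve is declared "no contact" when the best joint fit fails to reduce
the residual by at least 10% relative to a single straight line through
the whole approach, or when the fitted Hertz amplitude is non-positive.
Such curves are flagged, never silently dropped: flags propagate to the
aggregation stage, which counts them in a QC report.

### Modulus fit

Given $z_0$ and the baseline, force–indentation pairs are formed and $E$
is estimated by closed-form linear regression of $F$ on $\delta^{3/2}$
(the slope maps to $E$ through the prefactor). Choices:

- **Poisson ratio** $\nu = 0.5$ by default (incompressible), the
  convention for hydrated soft ECM; configurable.
- **Fit window** $\delta \in [10\%, 90\%]$ of the maximum indentation:
  the lower cut avoids contact-point noise, the upper cut limits
  substrate influence on thin (~20 µm) sections.
- **QC rule**: curves (not individual indentations) are the unit of
  exclusion; the default threshold is fit $r^2 < 0.8$, configurable in
  `afm_options()`.

### Viscosity index and adhesion

Viscous dissipation is summarized by the dimensionless hysteresis ratio:
the area between the approach and withdrawal force–indentation traces
divided by the area under the approach trace, computed by trapezoidal
integration on a shared 256-point indentation grid over the common
contact interval, with negative forces clipped to zero. It is explicitly
a proxy index — 0 for a fully elastic cycle, larger with more
dissipation — not an absolute viscosity.

Adhesion is the magnitude of the most negative baseline-corrected force
on the withdrawal trace, zero when the trace never pulls below baseline.

### Aggregation

The sampling design is nested: ~5 repeated indentations per point,
several points (≥ 20 µm apart) per region, several regions per animal.
Averaging proceeds level by level (replicates → point → region →
animal), and the group summary reports mean ± SE with the **animal** as
the unit of replication — pseudoreplication at the indentation level
never inflates the group n.

## Synthetic force curves

The generator's defaults are the study conditions: $k = 0.03$ N/m,
$R = 2.5$ µm, $\nu = 0.5$, a 3 µm ramp crossing the contact point at
2 µm (≈ 1 µm maximum indentation — the ramp depth is not dictated by the
measurement protocol, so a value typical for soft-tissue AFM was chosen
once), 400 samples per segment, and 5 pN additive Gaussian force noise.
Withdrawal hysteresis is modeled by scaling the withdrawal contact-force
*law* by $(1-h)$ — implemented as an effective modulus $(1-h)E$ in the
implicit solve — so that the analyzed loop-area ratio equals $h$
exactly; scaling forces at matched piezo position instead would bias the
recovered ratio by a few percent through the compliance term. Adhesion
is a negative Gaussian well on the withdrawal only, centred two well
widths before the contact point (snapped to the sampling grid so the
injected depth is realized exactly). Batches derive a child seed per
(region, point, replicate) from the batch seed, giving bit-reproducible
batches with independent noise and jittered contact points.

Not emulated: piezo creep, thermal drift beyond a linear baseline,
cantilever tilt, finite sample thickness, true viscoelastic rate
dependence (the ramp speed enters no formula). Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to every instrument artifact.

## ECM intensity quantification

Each stain image is summarized by a Gaussian KDE of its pixel
intensities (`stats::density`, Silverman's rule, 256-point grid spanning
the bit-depth range; samples above $10^5$ pixels are subsampled with a
fixed seed for speed). Within a user-supplied lower/upper threshold
window the profile reports the areas under the density before and after
the peak, each normalized by the total thresholded area (so weak +
intense = 1), and the **activated fraction**: the fraction of pixels
inside the window, computed by direct counting — the KDE never enters
it, and a test pins the two pathways together. Thresholds are explicit
inputs, not auto-estimated, because they are an acquisition-dependent
user choice; group comparisons default to the activated fraction as the
per-image scalar (the choice is recorded in the output row) with the
weak/intense areas available behind the same switch. Degenerate
constant images are flagged rather than erroring.

Numerical notes: with sharply peaked densities the 256-point trapezoid
integral of the KDE differs from 1 at the $10^{-3}$ level; normalization
is therefore checked analytically (Gaussian mixture mass inside the
intensity range) in the tests. The Silverman bandwidth depends on sample
size, so profiles of tiled copies of an image agree in their scalar
summaries but not bin-for-bin.

The image generator draws a continuous fiber texture (randomly oriented
anisotropic Gaussian streaks), marks exactly
`round(activated_fraction_true · n_pixels)` of the brightest texture
pixels as signal, and adds intensity noise — so the ground-truth
activated fraction is exact by construction. It emulates the
*distributional* properties the KDE pipeline consumes, not the spatial
statistics of real fiber networks (no porosity, orientation order, or
fiber thickness distributions).

## Cell imaging

Nuclei: threshold, 8-connected component labeling, region properties
(area, centroid, major axis from normalized second moments, equivalent
circular diameter), then a minimum-diameter filter interpreted on the
equivalent diameter. 8-connectivity is the tolerant choice for round
nuclei; touching nuclei merge (no watershed), which the synthetic fields
avoid by a minimum centre separation. Ki67 positivity uses
dilation-based colocalization: a nucleus is positive when ≥ 1
thresholded Ki67 pixel falls inside its footprint dilated by a disk
(default radius 2 px, compensating small stain offsets). Because the
disk is symmetric, dilating the Ki67 mask once is equivalent to dilating
every nucleus footprint, and a pixel in two dilated footprints counts
for both; per-nucleus overlap counts are exported so stricter rules can
be applied downstream. Viability applies the same segmentation to the
live and dead channels and reports `100 · live / (live + dead)`.

## Statistics

Group comparisons follow the two branches of the design. Two-sample
comparisons use the pooled-variance Student t-test (Welch behind a
flag); zero-variance degeneracies are handled explicitly (equal means →
p = 1; unequal → p = 0, flagged). The factorial analysis is a two-way
ANOVA with interaction; **Type II** sums of squares are used because the
animal counts are unbalanced between age groups and Type II is the
conventional choice absent interaction-driven main-effect hypotheses —
it reduces to the classical orthogonal partition when the design is
balanced, which the tests verify against a nested-model residual-SS
oracle. No multiple-testing correction is applied by default, mirroring
the analysis tradition this package serves; group summaries are
mean ± SE with the n − 1 standard deviation.

## Validation problem sizes

The test suite and the acceptance script exercise the pipeline at sizes
chosen to give tight Monte-Carlo error while remaining quick on one CPU:
200 curves per modulus level (5 × 8 × 5 hierarchy) at 5 pN noise for
recovery of each group-mean modulus and adhesion depth; 10 images per
group for the ±19%/−15% activated-fraction shift recoveries; 20 fields
of 100 cells for viability; 10,000 replicates for the t-test type-I
calibration. At these sizes the recovered group means sit well within
the 5% / 2-point acceptance tolerances.

## Known limitations

- No bottom-effect correction: moduli of very thin sections are upper
  bounds.
- The viscosity index is a relative proxy; it should not be compared
  across labs as an absolute quantity.
- Merged touching nuclei bias counts downward in dense fields; the
  generator enforces separation, real fields may not.
- Thresholds (intensity, minimum diameter, dilation radius) are
  user-defined acquisition-dependent choices; defaults here are
  documented starting points, not calibrated constants.
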