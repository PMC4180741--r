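---
title: "saxspipe: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{saxspipe: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxspipe)
```

This vignette is the package's own account of the science it implements:
the pixel-to-reciprocal-space model, the integration scheme, the peak
models, the bone-tissue T and ρ parameters, the pipeline semantics, and —
because several of these were genuinely open design choices — why each
convention was fixed the way it was.

## Geometry model

A flat detector sits orthogonal to the incident beam at distance $D$ (mm),
with pixel pitch $(p_x, p_y)$ (mm) and the direct beam at fractional pixel
coordinates $(x_0, y_0)$. Pixel coordinates are 0-based, $x$ along
columns, $y$ along rows, origin at the top-left of the image; "up" on the
detector is decreasing row index. These match how the supported image
formats store their arrays, and they are fixed once, here, rather than
configurable.

**Transmission.** A pixel at in-plane distance $r$ from the beam centre
scatters at $2\theta = \arctan(r/D)$ and carries
$q = (4\pi/\lambda)\sin\theta$ (nm$^{-1}$). The azimuth $\chi$ is measured
counterclockwise from the $+x$ detector axis, in degrees in $[0, 360)$;
at the beam centre it is undefined and reported as 0. Exact trigonometry
is used rather than the small-angle shortcut $q \approx 2\pi r/(\lambda D)$
— at the largest angles the default synthetic geometry reaches (~12°), the
shortcut would already be off by ~1%.

**Grazing incidence.** With in-plane angle $\psi = \arctan(\Delta x/D)$
and exit angle $\alpha_f = \arctan(\Delta y_{up}/D) - \alpha_i$ measured
from the direct-beam spot,

$$q_y = \frac{2\pi}{\lambda}\sin\psi\cos\alpha_f, \qquad
  q_z = \frac{2\pi}{\lambda}(\sin\alpha_i + \sin\alpha_f).$$

This is standard GISAXS kinematics; $q_x$ is neglected, which is the usual
small-angle contract and accurate to second order in the scattering
angles. The beam centre in grazing mode is the *direct-beam* spot, not the
specular reflection (the specular condition $\alpha_f = \alpha_i$ then
sits at $q_z = (4\pi/\lambda)\sin\alpha_i$, which is one of the geometry
tests). Detector tilt, refraction below the critical angle, and
polarization/solid-angle corrections are out of scope; maps are cached per
(geometry, shape) because they are by far the most expensive geometric
object.

## Integration scheme

All reductions use pixel-centre histogramming ("simple box integration"):
each unmasked pixel contributes its full intensity to exactly the bin its
centre falls in, with no pixel splitting. Bins are half-open $[lo, hi)$
with the last bin closed. This minimal scheme has two properties the test
suite exploits:

* **Exact conservation.** $\sum_i y_i n_i$ over bins equals the plain sum
  of contributing pixel intensities, so every profile is checked against a
  loop-based pixel oracle with the same binning rule, to within floating
  point rounding.
* **Mask locality.** Enlarging the mask can only change bins that lose
  pixels.

Empty bins carry `NaN` (not zero) so downstream fits drop them instead of
being biased toward zero. GISAXS cuts group pixels by detector column
(horizontal cuts, abscissa $q_y$) or row (vertical cuts, abscissa $q_z$)
within the ROI band; an arbitrary-direction cut projects onto the stated
axis and histograms the signed distance with pixel-scale bins. A `median`
reduction is available on cuts for robust ("median intensity") profiles;
the mean is the default because it keeps the conservation property and
propagates uncertainties.

**Uncertainties.** The error model is Poisson counting statistics
assigned at read time, $\sigma = \sqrt{\max(N, 1)}$ per pixel (the floor
avoids zero weights on empty pixels), propagated to first order through
subtraction, normalization, binning and bin averaging. The model feeds
the weighted fits; nothing else depends on it. Background-subtracted
intensities may go negative and are *not* clipped — clipping would bias
every downstream bin mean upward.

## Peak models and fitting

Peaks are parameterised by height $A$, centre $x_0$ and FWHM $w$:

* Gaussian: $A\exp(-4\ln 2\,(x-x_0)^2/w^2)$, area $Aw\sqrt{\pi/(4\ln2)}$;
* Lorentzian: $A\,(w/2)^2/((x-x_0)^2+(w/2)^2)$, area $Aw\pi/2$;
* pseudo-Voigt: $\eta L + (1-\eta)G$ with shared $A, x_0, w$ — the common
  powder-diffraction form, chosen because the profile name alone does not
  pin down a parameterisation.

The background catalogue is constant / linear / quadratic / power-law.
Fitting is deterministic Levenberg–Marquardt (minpack.lm) on weighted
residuals $(y - f)/\sigma$, with box bounds and linear parameter ties
(`target = scale·source + offset`); tied parameters are eliminated before
optimization, and their uncertainties inherit $|scale|$ times the source
uncertainty. Initial values outside the bounds are rejected *before*
optimization — a misconfiguration, not a data problem. Standard errors
come from the local curvature scaled by the reduced chi-square, the
conventional weighted-least-squares estimate; a simulation test checks
that ~95% of Poisson replicates put the true centre and width within
three standard errors.

Non-convergence is **data, not failure**: `fitCurve()` returns a result
with `converged = FALSE` and the inputs echoed, and `fitSeries()` falls
back to the initial model and continues — essential when thousands of
frames are processed sequentially and a handful are hopeless. With
`propagate = TRUE` each frame is initialized from the previous converged
fit, which is what lets a slowly drifting side maximum be tracked with a
single initial guess. There are no stochastic restarts, so series runs
are bit-reproducible.

An optional `period` (360° for azimuthal profiles) evaluates every peak
also shifted by ±one period. Truncating the wrap at one period is exact
to $\exp(-4\ln2\,(360/w)^2)$ relative — below machine precision for any
width up to the fitter's 170° bound.

## The T parameter

For a two-phase system with sharp interfaces, the high-$q$ tail follows
Porod's law $I \to P/q^4 + B$. Regressing $Iq^4$ on $q^4$ over the tail
gives $B$ as the slope and $P$ as the intercept; a non-positive $P$ flags
the pattern as not Porod-like rather than producing a nonsense thickness.

The invariant $J = \int_0^\infty (I - B)\,q^2\,dq$ is evaluated as a
trapezoid over the measured range, plus a constant low-$q$ extension
$(I(q_{min}) - B)\,q_{min}^3/3$, plus the analytic tail $P/q_{max}$. The
constant extension (rather than a Guinier fit) is deliberately simple; its
bias is $O(q_{min}^3)$ and below 1% of $J$ at the measured $q_{min}$ of
the synthetic setups. The integrand subtracts $B$ consistently in all
three pieces.

The thickness parameter is the stereological relation

$$T = \frac{4J}{\pi P}.$$

Derivation sketch: for a dilute two-phase system, $J \propto \phi(1-\phi)$
and $P \propto S/V$ (interface area per volume), and the ratio reduces to
the volume-to-surface chord length $4V/S$ of the particles. A sphere of
radius $R$ gives $T = 4R/3$; intensity-weighted polydispersity turns this
into $(4/3)\langle R^3\rangle/\langle R^2\rangle$. Intensity units cancel,
so $T$ is invariant under rescaling of $I$ — asserted on random
rescalings. The end-to-end test generates a 2-D sphere pattern, reduces
and analyses it, and requires the analytic value within 5% (binning,
counting noise and the residual oscillation of the sphere form factor
around its Porod asymptote share that budget).

## The ρ parameter

Oriented mineral platelets make the azimuthal profile $I(\chi)$ of a
centrosymmetric pattern show two peaks 180° apart. The analysis fits a
constant background plus two Gaussians constrained to equal amplitude and
width with centres $\chi_0$ and $\chi_0 + 180°$ (wrapped at the period),
and reports the oriented fraction

$$\rho = \frac{A_{peaks}}{A_{peaks} + A_{bg}}, \qquad
  A_{peaks} = 2Aw\sqrt{\pi/(4\ln2)}, \quad A_{bg} = 360\,b,$$

which lies in $[0, 1]$: 0 for an isotropic pattern, 1 for peaks on zero
background. The phrasing "ratio between the area under the peaks and the
background" admits a second reading, $A_{peaks}/A_{bg}$; that alternative
is exposed as `denominator = "background"` but is unbounded above and not
the default. Gaussian peak shapes are a choice (the profile used for this
analysis is not standardised); the wrapped-Gaussian area over one period
equals the full Gaussian area, so the closed forms above are exact.

The predominant particle orientation is perpendicular to the azimuthal
intensity maximum (the SAXS streak of a platelet is normal to its long
axis): $(\chi_0 + 90°) \bmod 180°$.

**Annulus choice.** The azimuthal profile should be taken over a $q$
annulus narrow enough that the radial envelope of the pattern is nearly
constant across it. With a wide annulus, the discrete pixel composition
of each $\chi$ bin weights the radial envelope slightly differently per
bin (a four-fold grid modulation), which biases the fitted
peak-to-background ratio at the percent level and breaks rotation
invariance. The package's tests and examples therefore use
$q \in [0.8, 1.6]$ nm$^{-1}$ on the default synthetic geometry; with that
choice ρ recovery is within 2% and rotation invariance within 1%, which
the acceptance tests assert. Real analyses should follow the same rule of
thumb: prefer a narrow annulus centred on the oriented signal over a wide
one, unless counting statistics force the trade the other way.

## Pipeline semantics

Plug-ins declare parameters, typed inputs and typed outputs (types:
scalar, curve, image-ref, text); a pipeline is a named set of plug-in
instances wired output-to-input into an acyclic graph rooted at a reader
consuming the reserved `source.path`. All wiring is type-checked *before*
any data flows, so a post-validation run cannot raise type errors
mid-series. Outputs are namespaced `node.output` in the result table,
which resolves name collisions between instances of the same plug-in.

Execution is strictly sequential, one data set at a time, in input order
— determinism over throughput. One frame yields exactly one row; a
plug-in failure yields NaN/empty cells for its outputs (and its
dependents) plus an entry in the `errors` column, while a *reader*
failure skips the data set with a log line, since nothing downstream
could run. Images are stored in the table as path references, never as
pixels.

**Online mode** polls a directory: a file becomes eligible only when its
size is unchanged across two consecutive polls (the completeness
heuristic for partially written frames — arrival time and name say
nothing about whether a detector has finished writing), files are
processed exactly once in name-sorted order within each arrival batch,
unreadable files are retried once and then marked failed, and a stop
drains the queue first. Overwriting a file after its first version was
processed does not reprocess it. The invariant — asserted with 50 frames
dropped mid-run — is that the online table equals the offline table on
the final file set. The watcher accepts an `onPoll` callback, used by the
tests to drop files between polls from the same process; polling
semantics are identical with or without it.

## Synthetic data: what it emulates, and what it does not

* `spherePattern()` — dilute-particle SAXS with a Porod tail:
  $I(q) = \text{flux}\cdot\langle R^6 F^2(qR)\rangle/\langle R^6\rangle + b$
  with the sphere form factor $F(x) = 3(\sin x - x\cos x)/x^3$ and a
  Schulz size distribution (closed-form moments; default 10% relative
  width, enough to damp form-factor oscillations so Porod fits are
  stable). The $R^6$ (volume-squared) weighting is the physical intensity
  weighting; it is what makes the planted thickness
  $(4/3)\langle R^3\rangle/\langle R^2\rangle$. The planted Porod
  constant is $\text{flux}\cdot\tfrac92\langle R^2\rangle/\langle
  R^6\rangle$. Size averaging uses 41-node Gauss–Legendre quadrature over
  the Schulz density; the truth record uses the closed-form moments, so
  the two routes are independent.
* `anisotropicPattern()` — a separable pattern
  $S(q)\,[b + a(g(\chi;\chi_0) + g(\chi;\chi_0{+}180°))]$ with wrapped
  Gaussian peaks and $S(q) = 1/(1+(q\xi)^2)$; the planted ρ follows from
  the closed-form areas and is cross-checked against numerical quadrature
  of the generator function itself.
* `gisaxsSeries()` — symmetric Lorentzian side maxima at $\pm q_y^*(k)$
  on an exponentially decaying diffuse background, with a per-frame
  trajectory, written as 16-bit TIFFs plus a manifest: the shape of an
  in-situ deposition series where the in-plane correlation peak drifts as
  clusters grow.

Counting noise is Poisson with an explicit seed (the caller's RNG state
is saved and restored); the noiseless expectation is available for exact
tests. Default geometries are realistic beamline numbers: λ = 0.1 nm,
D = 500 mm, 1 mm pixels (transmission, q up to ~10 nm⁻¹ on 160×160
pixels, enough Porod tail for 2 nm particles); λ = 0.096 nm,
α_i = 0.5°, 0.172 mm pixels, D = 1000 mm (grazing, $q_y$ spanning
±0.9 nm⁻¹ on 160 columns).

What the generators do *not* emulate — and hence what passing tests do
not show about real data: detector artefacts (flat-field structure, dead
zones beyond simple masks, zingers), instrumental smearing, sample
absorption and multiple scattering, inter-particle interference
(structure factor), the Yoneda enhancement and refraction effects in
GISAXS, and drifting incident flux. The monitor/ background machinery is
exercised with synthetic values, not with a beamline's real monitor
chain.

## Problem sizes and runtimes

The test suite runs at deliberately desk-scale sizes, chosen as the
smallest that leave each statistical tolerance comfortable: 160×160
(sphere/T chain) and 128×128 (ρ chain) synthetic frames, 20 seeded ρ
replicates, 80 coverage replicates for the fit uncertainties, a 200-frame
GISAXS series for sequential tracking, and 50 frames for the
online/offline equivalence; the whole suite completes in well under a
minute on a single core.

## Known limitations

* TIFF support covers uncompressed grayscale (8/16/32-bit); EDF covers
  the common single-image dialect with configurable monitor/exposure
  header keys. No cbf/mar/HDF5.
* The constant low-$q$ invariant extension underestimates $J$ when the
  profile still rises steeply at $q_{min}$ (interacting or very large
  particles); the bias bound is tested only for the dilute case.
* ρ assumes full azimuthal coverage up to a configurable gap fraction
  (default 20%); heavily shadowed detectors need a widened gap or a
  restricted fit the package does not automate.
* The watcher's stable-size heuristic can mis-fire on writers that pause
  longer than one poll interval mid-file; choose the poll interval above
  the writer's worst pause.
* WAXS crystallographic analysis (unit-cell work), fluorescence, absolute
  intensity calibration and model-based form-factor fitting are out of
  scope.
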