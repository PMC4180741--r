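# saxspipe

Reduction and analysis of scanning SAXS/WAXS and GISAXS detector data in R:
a plug-in pipeline that turns streams of 2-D scattering frames into
calibrated 1-D profiles, fitted peak parameters, and tissue-scale parameter
maps — offline on a file list or online on a directory that is still being
filled by a detector.

It is aimed at users of scanning small-angle scattering beamlines (bone and
tissue nanostructure mapping, in-situ GISAXS film growth, microfluidic
orientation mapping) who need fast, scriptable data reduction with a typed
result table rather than a GUI.

## What it computes

**Geometry.** Detector pixels map to momentum transfer with
q = (4π/λ)·sin θ, 2θ = atan(r/D) (transmission), or to the GISAXS
components q_y = (2π/λ)·sin ψ·cos α_f, q_z = (2π/λ)·(sin α_i + sin α_f)
(grazing incidence). Units are nm, mm, nm⁻¹ and degrees throughout.

**Reduction.** Radial profiles I(q), azimuthal profiles I(χ) over an
annulus, and GISAXS line cuts (out-of-plane along q_y, detector cuts along
q_z, or arbitrary directions) averaged over a region of interest, with
masks, Poisson uncertainties, background/monitor/binning corrections, and
brute-force-verified box integration.

**Peak fitting.** Weighted least squares of arbitrary sums of Gaussian,
Lorentzian and pseudo-Voigt peaks (amplitude A, centre x₀, FWHM w; the
pseudo-Voigt is η·L + (1−η)·G) on constant/linear/quadratic/power-law
backgrounds, with parameter ties and bounds, propagated sequentially across
frame series so a drifting peak is tracked from frame to frame.

**Bone nanostructure.** From a radial profile, the Porod analysis
I·q⁴ = P + B·q⁴ gives the Porod constant P; the scattering invariant
J = ∫(I−B)·q² dq and P give the mean mineral-platelet thickness parameter
T = 4J/(πP). From an azimuthal profile, a constrained two-peak fit (peaks
180° apart) gives the degree of alignment ρ = A_peaks/(A_peaks + A_bg) ∈
[0, 1] and the predominant particle orientation. Per-frame results
assemble into scan-grid maps.

**Framework.** Plug-ins declare typed inputs/outputs and are wired into a
validated acyclic graph; every processed frame appends one row to a typed
table (scalar / curve / image-reference / text columns) that exports to
tab-separated spreadsheets and dense grid maps. An online mode polls a
directory and processes each file exactly once, once its size is stable,
producing a table identical to the offline run on the same files.

A synthetic-data module generates dilute polydisperse-sphere patterns,
centrosymmetric anisotropic patterns and GISAXS series with drifting side
maxima — all with analytic ground truth, so the whole chain is testable
without beamline data.

## Worked example

```r
library(saxspipe)

# Dilute Schulz-polydisperse spheres, R0 = 2 nm, 10% width, Poisson noise
geom    <- synthGeometry("transmission")
sp      <- spherePattern(geom, radius = 2, poly = 0.1, seed = 1)
qmap    <- buildQMap(c(160, 160), geom)
profile <- radialProfile(sp$frame, qmap, seq(0.2, 9.8, length.out = 140))
res     <- boneTParameter(profile, qFitRange = c(5, 9))
sprintf("T = %.3f nm (planted %.3f nm)", res$T, sp$truth$T)
#> "T = 2.782 nm (planted 2.720 nm)"

# Oriented pattern: degree of alignment and predominant orientation
geom2 <- synthGeometry("transmission", c(128, 128))
ap <- anisotropicPattern(geom2, c(128, 128), chi0 = 40, a = 5, b = 1,
                         seed = 1)
az <- azimuthalProfile(ap$frame, buildQMap(c(128, 128), geom2),
                       c(0.8, 1.6), seq(0, 360, by = 2))
r  <- rhoParameter(az)
sprintf("rho = %.4f (planted %.4f), chi0 = %.2f deg", r$rho,
        ap$truth$rho, r$chi0)
#> "rho = 0.4722 (planted 0.4701), chi0 = 40.06 deg"
```

The T value is the mean chord length of the mineral phase: for spheres
4R/3 scaled by the ⟨R³⟩/⟨R²⟩ polydispersity moments (2.720 nm planted
here); recovery is within the 5% end-to-end tolerance. ρ is the planted
oriented-area fraction of the azimuthal intensity; χ₀ the fitted peak
centre, with the second peak constrained 180° above.

A command-line wrapper lives in `inst/scripts/saxspipe` with subcommands
`run`, `integrate`, `fit-series`, `bone-map` and `synth`, each driven by a
YAML config carrying the geometry block and (for `run`) the plug-in
pipeline; see the header of that file for usage.

## Documentation

Function-level documentation is in the roxygen comments in `R/`; the
methods vignette (`vignettes/saxspipe-methods.Rmd`) describes the models,
conventions, numerical choices and limitations in detail.
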