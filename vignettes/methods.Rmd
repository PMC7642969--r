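---
title: "Methods: energy-dispersive spectral imaging analysis in spexim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-dispersive spectral imaging analysis in spexim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spexim)
```

## The measurement model

A bent-Laue crystal diffracts a polychromatic fan so that photon energy is
correlated with exit angle; at the detector this becomes a vertical
position–energy correlation, while the horizontal axis resolves sample
position along the focal line. For a sample containing materials with mass
attenuation coefficients $(\mu/\rho)_i(E)$ and projected densities
$(\rho t)_i$ (density × path length, g/cm²), the flat/dark-normalized
negative-log transmission at detector pixel $(p, c)$ is

$$A(p, c) = -\ln\frac{N_{tomo}(p,c) - N_{dark}(p,c)}{N_{flat}(p,c) -
N_{dark}(p,c)} = \sum_i \left(\frac{\mu}{\rho}\right)_i\!\big(E(p,c)\big)
\,(\rho t)_i(c).$$

Each detector column is an independent over-determined linear system (a few
hundred energy samples, a handful of materials) solved by ordinary least
squares. Everything else in the package exists to make the two maps in that
equation trustworthy: the per-pixel energy $E(p,c)$ and the references
$(\mu/\rho)_i(E)$ at the instrument's actual energy resolution.

Assumptions: a cubic monochromator crystal (silicon by default); attenuation
only (no refraction or scatter-into-detector); references that are
"distinctively different" over the measured band — the fit checks the design
matrix and refuses rank-deficient reference sets, and warns above a condition
number of 1e8.

## Energy calibration

**Edge localization.** The absorption edge of an elemental reference film is
located per column as the peak of the magnitude of the first difference of
the boxcar-smoothed attenuation (window `smooth_window`, default 3 px),
refined to subpixel by a parabola through the three samples around the
maximum. Columns whose peak prominence is below 5× the MAD of the derivative
are flagged invalid. The per-column trace follows the beam's bow from
non-uniform crystal bending.

**One-point map.** With the edge row $p_K$ known and the edge energy
$E_K$ given, a ray hitting pixel $p$ makes the angular offset
$\alpha = \arctan[(p - p_K)\,s/F]$ with the K-edge ray ($s$ pixel size, $F$
focus-to-detector distance), and its Bragg angle is taken as
$\theta = \theta_K \pm \alpha$ (the sign is the `energy_direction` flag,
configurable because detector orientation is installation-specific). The
offset is applied 1:1 to the Bragg angle, consistent with rays diverging
from a line focus.

**Two-point map.** When a speciation reference with two known absorption
features is available (selenate: 12.667 and 12.681 keV), the per-column
feature rows $(p_1, p_2)$ and their Bragg angles $(\theta_1, \theta_2)$
replace the assumed $F$ by an effective focus distance

$$F_{\mathrm{eff}} = s\,(p_1 - p_2)/\tan(\theta_1 - \theta_2), \qquad
\theta(p) = \theta_1 + \arctan[(p - p_1)\,s/F_{\mathrm{eff}}],$$

which reproduces both anchors exactly and is smooth in between. Any
formulation with those properties would do; this one is closed-form and
directly testable. Two-point calibration is the recommended mode: it removes
the dependence on the assumed focus-to-detector distance, and in simulation
it reproduces the generating energy map to about 1e-4 keV inside the beam.

**Energy resolution.** The FWHM of the derivative of the edge profile
measures the combined core-hole and monochromator width. The median
per-column FWHM (robust to bow-induced outliers at the beam edges) is
deconvolved from the estimator's own kernel — first difference plus boxcar —
by numerically inverting the kernel's exact response to a Gaussian edge;
below ≈0.5 px the response saturates (a 3-px boxcar answers "3 px" to any
sharper edge) and the estimate is floored there. The result, as a Gaussian
σ, is used to blur the references before fitting, matching what the
instrument sees. The core-hole natural width is *not* deconvolved: the
references are blurred by the measured total width directly.

## Statistical choices

**Poisson log bias.** For $N \sim \mathrm{Poisson}(\lambda)$,
$E[-\ln N] = -\ln\lambda + 1/(2\lambda) + O(\lambda^{-2})$: low-count pixels
(strong absorption above the edge, beam-profile flanks) carry a systematic
positive attenuation bias that the fit misreads as material — at 10⁴ flat
counts this alone distorts insert recoveries by several percent. The
pipeline therefore subtracts the plug-in correction $1/(2(N_{tomo}-D)) -
1/(2 n_{flat} (N_{flat}-D))$ during normalization (`debias = TRUE` in
`analyze_scan()`; `normalize_attenuation()` defaults to the plain
negative log). Pixels with non-positive count differences are masked and
dropped from the fit, never imputed.

**Least squares.** Unconstrained OLS is the default so that absent
constituents diagnose themselves by near-zero coefficients; a Lawson–Hanson
non-negative mode is available for noisy low-concentration work. Columns are
fitted independently — no spatial regularization. Pixels are unweighted; a
photon-statistics weighting would be a natural extension but is not needed
for the package's validation targets.

## CT

**Decay correction.** Storage-ring flux decay multiplies counts, hence adds
a constant per projection in attenuation. With empty columns on both sides
of the field of view, each projection's offset is the mean attenuation over
the margin pixels (restricted to the useful beam rows) and is subtracted
from the whole projection. A scalar per projection is deliberate: per-row
offsets would fit noise.

**Rotation center.** The first projection is correlated against the
horizontally flipped member of the nearest pair 180° apart, over integer
lags with parabolic refinement. On an exact 0…179° grid the nearest pair is
1° short of opposition; the search accepts a deviation up to 1.5× the
angular step, which costs well under half a pixel for realistic objects.

**Filtered back projection.** The band-limited discrete ramp kernel
(h(0)=1/4, h(odd n)=−1/(πn)², h(even)=0) is applied in the frequency domain
with power-of-two zero padding, optionally windowed (shepp-logan, cosine,
hamming, hann), followed by linear-interpolation back projection scaled by
π/(2·n_angles). Sinograms carry g/cm²; dividing by the column spacing (cm)
makes voxels g/cm³. Pixels outside the inscribed circle are zeroed. On an
analytic uniform-disk sinogram the interior mean is reproduced to well
within 2%.

## The synthetic beamline

The simulator generates everything the analysis consumes: dark frames
(offset 100 counts, Gaussian read noise σ=2), flats with a near-Gaussian
vertical profile (default FWHM 30% of the detector rows), an elemental-film
edge image and a two-peak selenate speciation image, and CT projections
with `counts = dark + (flat-dark)·flux·exp(-Σ (μ/ρ)(E)·ρt)` where the ρt
are *analytic* chord integrals through a disk phantom (a raster-based
projector exists as a cross-check). The per-column energy axis follows the
one-point map with a quadratic edge bow (default 1e-4 px/col²); references
are pre-blurred by the resolution σ before exponentiation; Poisson noise is
optional and fully determined by the seed.

Deliberate stylizations: the species near-edge spectra (selenate, selenite,
selenomethionine) are parametric — an error-function edge jump modulated by
a smooth post-edge decline plus Gaussian white lines at the literature peak
positions, with realistic few-eV widths — not ab-initio XANES. They are used
identically on the forward and inverse paths, so the tests validate the
*pipeline*, not atomic physics. Likewise the packaged element tables are a
parameterized compilation (per-branch power-law photoelectric plus
Klein–Nishina scattering anchored at published values) adequate for the
smooth matrix background; a production deployment at a beamline would swap
in authoritative tables, which slot into the same text fixture format. Not
emulated: source spectra, detector PSF, scatter, harmonics, refraction.
Passing tests therefore demonstrate correct calibration, decomposition and
reconstruction under realistic counting statistics, beam decay and beam
bow — not robustness to every detector pathology of real beamline data.

### Study conditions and defaults

| parameter | default | why |
|---|---|---|
| detector | 400 × 1024 px, 9 µm pitch | typical area-detector crop; full scan simulates in seconds |
| focus-to-detector | 500 mm | gives ≈1.4 eV/px dispersion at the Se edge |
| flat counts | 10⁴ at beam peak | realistic exposure; σ(A) ≈ 1% per pixel |
| dark/flat frames | 10 each | standard correction-stack depth |
| resolution σ_E | 5.4e-4 keV | edge transition ΔE/E ≈ 1e-4 |
| beam bow | 1e-4 px/col² | ≈26 px bow across the field, well inside the beam |
| CT | 180 angles over [0°, 180°) | standard parallel-beam sampling |
| flux decay | to 0.90 over a scan | typical storage-ring decay over ~10 min |
| phantom | 7 mm water holder; 1.6 mm inserts; 100 mM species / 7 mg·cm⁻³ seedpod | solution phantom with sample-free margins for decay correction |
| tunables | threshold_fraction 0.10, smooth_window 3 px, min region height 8 px | recorded in every settings record |

The validation suite runs these conditions end-to-end (two noisy 180-angle
CT studies take a few minutes on one CPU); unit tests use smaller cuts of
the same generator.

## Storage

A session archive stores every mid-way result (energy map, beam region,
edge trace, references in use, corrected attenuation, per-material maps or
sinograms) plus the settings record. The container is a purpose-built keyed
binary format ("XSAR": an 8-byte magic, a JSON table of named entries, then
raw little-endian payloads) chosen over language-specific serialization for
portability and safety; doubles round-trip bit-exactly. Final maps are also
written as 32-bit float TIFFs (by a small built-in writer, since the CRAN
`tiff` writer only stores [0,1]-scaled integer samples), and count images
as 16-bit TIFFs.

## Known limitations

* Cubic crystals only; dynamical-diffraction effects (rocking widths,
  focal-size optimization) are out of scope.
* The beam bow is calibrated at the detector; its (smaller) effect at the
  sample plane is not corrected.
* Energy resolution below ≈0.5 detector pixels is reported at the
  measurement floor rather than extrapolated.
* Ring artifacts other than global flux decay, and misalignments beyond a
  global center shift, are not corrected.
* The element tables bundled for the matrix background are best-effort
  parameterizations, not metrology-grade data.
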