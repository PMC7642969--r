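# spexim

Analysis of **spectral K-edge subtraction (KES)** and **wide-field
energy-dispersive XAS (EDXAS)** imaging data in R.

## The problem

A bent-Laue monochromator focuses a polychromatic synchrotron fan into a line
beam in which Bragg diffraction correlates photon energy with exit angle.
Behind the sample, an area detector therefore records — in a single exposure —
a full absorption spectrum for every horizontal sample position: energy varies
along the detector rows, sample position along the columns. Near the K edge of
a contrast element (selenium here), the attenuation of each candidate compound
has a distinctive energy signature, so the measured spectrum of every column
can be decomposed into quantitative **projected densities** ρt (g/cm²) of each
candidate material. Scanning the sample vertically yields 2-D maps; rotating
it yields per-material sinograms and, after filtered back projection, 3-D
density maps (g/cm³).

For a transmission measurement through materials with mass attenuation
coefficients (μ/ρ)ᵢ(E),

    -ln[(N_tomo - N_dark) / (N_flat - N_dark)] = Σᵢ (μ/ρ)ᵢ(E) · (ρt)ᵢ ,

which is linear in the unknown (ρt)ᵢ once the per-pixel energy E is known: an
over-determined system solved per column by least squares. The package
implements the full chain:

* **geometry** — arrangement-file parsing and Bragg-law conversions
  (`E = hc / (2 d_hkl sin θ)`, cubic `d_hkl = a₀/√(h²+k²+l²)`);
* **calibration** — flat/dark normalization, useful-beam-region detection,
  per-column absorption-edge localization (subpixel derivative peak),
  one-point and two-point per-pixel energy maps, and energy-resolution
  estimation from the edge width (FWHM of the derivative);
* **references** — packaged element μ/ρ tables with log-log interpolation and
  edge-aware branches, the elemental mixture rule, measured-spectrum loading,
  Gaussian resolution blurring;
* **unmixing** — per-column least squares (optionally non-negative),
  assembly into maps and sinograms, molar-concentration conversion;
* **tomo** — beam-decay correction from empty margins, automatic
  rotation-center finding, filtered back projection (ramp, shepp-logan,
  cosine, hamming, hann);
* **synthetic** — a forward simulator of the whole instrument (beam profile,
  energy dispersion with bow, stylized near-edge species spectra, Poisson
  noise, storage-ring flux decay) with complete ground truth.

## A worked example

Simulate a noisy 180-angle CT scan of a phantom containing three selenium
species at 100 mM, analyze it with two-point calibration, and reconstruct:

```r
library(spexim)

geometry <- default_sim_geometry()     # Si(111), Se K edge 12.658 keV
phantom  <- make_demo_phantom("three_species_disks")
sim <- simulate_scan(phantom, geometry, n_angles = 180, noise = TRUE,
                     decay_to = 0.90, seed = 11)

ana <- analyze_scan(sim$stacks, geometry, references = phantom$materials,
                    mode = "ct", calibration = "two_point",
                    margins = c(100, 100))
rec <- reconstruct_session(ana, geometry)

for (k in seq_len(nrow(phantom$inserts))) {
  ins  <- phantom$inserts[k, ]
  dens <- region_mean(rec[[ins$material]], ins$cx, ins$cy, ins$r)
  cat(sprintf("%-18s %6.2f mM (prepared: %.0f mM)\n", ins$name,
      to_concentration(dens, 1, phantom$materials[[ins$material]]),
      ins$concentration_mM))
}
```

Output from this run:

```
selenate           100.78 mM (prepared: 100 mM)
selenite           102.21 mM (prepared: 100 mM)
selenomethionine   103.15 mM (prepared: 100 mM)
```

i.e. each insert's interior-mean concentration is recovered within a few
percent despite Poisson noise at 10⁴ flat counts and a 10% flux decay across
the scan (corrected from the empty margins). `analyze_scan(..., out_dir =)`
additionally writes a session archive with every mid-way result (energy map,
beam region, edge trace, blurred references, attenuation, sinograms), one
float TIFF per material, and a plain-text settings record.

A thin command-line front end is included at `inst/cli/spexim`
(`spexim simulate | analyze | reconstruct`) for driving the same pipeline
from disk directories of TIFF stacks.

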