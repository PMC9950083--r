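# domescatter

Infrared extinction of dome- and semi-capsule-shaped scatterers, and the
sphere-subspace (ME-EMSC meta-model) reconstruction experiment.

## The problem

Single biological cells measured in infrared transmission produce an apparent
absorbance `Z = -log10(I/I0)` that mixes molecular absorption with Mie
scattering. With a sample of geometric cross section `g` inside a detector
aperture `G >> g`,

    Z = -log10(1 - (g/G) * Qext)  ≈  (1/ln 10) (g/G) Qext,

so the extinction efficiency `Qext(ν)` carries the scattering distortion that
preprocessing must remove. Cells on a substrate deform: they flatten into
**domes** (hemispheres, flat face down) or elongate into **semi-capsules**
(a dome stretched by a half-cylinder of length `L`). State-of-the-art scatter
correction (ME-EMSC) models `Qext` with a PCA subspace built from *sphere*
solutions — this package computes the deformed-shape extinction curves and
tests whether that sphere subspace still reconstructs them.

## What it computes

* **Closed-form anomalous-diffraction (van de Hulst) extinction.** Rays cross
  the scatterer undeflected, acquiring phase `2πν (m-1) t` over the local
  chord `t`. With size parameter `x = 2πνR` and phase parameter
  `ρ = 2x(m-1)`:
  * sphere: `Q = 4 Re{1/2 + e^{-w}/w + (e^{-w}-1)/w²}`, `w = -iρ`
    (`qext_vdh_sphere`)
  * dome: the sphere curve at half phase — the chord is halved
    (`qext_dome`)
  * semi-cylinder: `Q = π Re{H₁(c) - i J₁(c)}`, `c = x(m-1)`, with Struve
    `H₁` and Bessel `J₁` of complex argument (`qext_semicylinder`)
  * semi-capsule: projected-area-weighted mix of dome and semi-cylinder over
    the stadium footprint (`qext_semicapsule`)
* **A brute-force quadrature oracle** (`qext_ada_numeric`) that integrates
  the ADA integral adaptively over any chord profile; every closed form is
  tested against it to 1e-6 (observed ~1e-9).
* **Exact Mie series** for spheres with complex index (`qext_mie_exact`),
  the electromagnetic reference.
* **Synthetic chemistry**: Lorentzian absorption bands plus a
  Kramers-Kronig-consistent real index about a constant offset
  (`synth_refractive_index`), validated against the analytic Lorentz
  oscillator.
* **The sphere-subspace experiment**: 100 van de Hulst sphere curves
  (offsets 1.3-1.7 × radii 5-10 µm), mean-centered PCA, projection of the
  semi-capsule curve onto the leading components, and a peak-shift negative
  control (`build_training_set`, `fit_subspace`, `reconstruct`,
  `peak_shift_experiment`, `run_pipeline`).

## Worked example

```r
library(domescatter)

grid <- default_grid()                  # 1000-6000 cm^-1, step 2
chem <- default_chemistry()             # bands at 1500, 2010, 3000, 5400 cm^-1
m <- synth_refractive_index(chem, grid)
m
#> refindex_spectrum: 2501 points, 1000-6000 cm^-1, n in [1.446, 1.558], max k 0.1004

q <- qext_semicapsule(m, R = 10, L = 10)
q
#> extinction_spectrum [semi-capsule, vdh-closed-form]: 2501 points, Q_ext in [1.414, 3.243]

curves <- build_training_set(chem, training_grid(), grid)   # 100 sphere curves
basis <- fit_subspace(curves, max_comp = 20)
vapply(sweep_ncomp(q, basis, c(5, 8, 12)), `[[`, numeric(1), "rel_rmse")
#> [1] 0.0538 0.0233 0.0126

ps <- peak_shift_experiment(chem,
        c("1500" = 1520, "2010" = 1950, "3000" = 3500, "5400" = 5350),
        basis, scatterer_geometry("semi-capsule", 10, L = 10),
        n_comp = 12, grid = grid)
ps$total_ratio
#> [1] 13.4
```

Reading the numbers: the relative reconstruction error of the semi-capsule
extinction curve falls from 5.4 % with 5 sphere components to 1.3 % with 12 —
the sphere subspace captures the deformed-sphere curve increasingly well,
with the remaining error localized at the absorption bands. When the band
positions are moved and the curve is reconstructed with the
original-chemistry basis, the residual energy in windows around the moved
bands is 13 times that of the unshifted run: the subspace is specific to the
chemistry it was trained on.

The full pipeline (index synthesis → training set → PCA → reconstruction
sweep → negative control → reports) runs from one configuration:

```r
summary <- run_pipeline(default_pipeline_config(), out_dir = "pipeline-out")
```

or from the shell via `inst/scripts/run_pipeline.R` with an optional YAML
configuration. Outputs (`summary.json`, `basis.csv`, spectra as CSV or
JCAMP-DX) are byte-deterministic for identical configurations.

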