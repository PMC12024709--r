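---
title: "Mapping tDCS-induced fields in a spherical phantom: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tDCS-induced fields in a spherical phantom: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomEF)
```

## The measurement model

A head phantom (a conducting sphere of roughly head size; in practice a
watermelon-class fruit works, being dielectrically skin-like at the peel
and brain-like in the pulp) is stimulated through surface pads while a
probe records the voltage difference ΔV (mV) against a reference electrode
taped to one stimulating pad. The probe visits the 21 standard 10–20
positions at four insertion depths along the radial line: the surface
(`Z0`), one third and two thirds of the diameter (`Z33`, `Z66`), and the
full diameter (`Z100`). The field estimate at each site is

$$\mathrm{EF} = \frac{\Delta V}{\lVert E - R \rVert},$$

the measured voltage difference divided by the straight-line distance from
the recording site $E$ to the reference origin $R$ — an average-magnitude
scalar (the discrete counterpart of $dV/ds$), not a vector field. This
assumes the medium is isotropic and homogeneous enough that the chord
distance is a meaningful path length; that assumption is part of the
phantom methodology, not something the package can check.

## Spherical 10–20 geometry

The phantom is idealised as a perfect sphere of radius $R$ (the frame:
+x right preauricular, +y nasion, +z vertex). Electrodes are placed by
elevation $\lambda$ above the equatorial plane and azimuth $\alpha$ from
the nasion toward the right:

$$E = \mathrm{center} + R\,(\cos\lambda\sin\alpha,\ \cos\lambda\cos\alpha,\ \sin\lambda).$$

The angle table is a design choice of this package: published phantom
coordinate tables print Cartesian coordinates, not angles, so the angles
were fixed by inverting chord lengths on the sphere. The result is a
three-ring layout — the 12 circumferential electrodes at 18° elevation
with azimuths on the conventional percentage spacings (0, ±18, ±54, ±90,
±126, ±162, 180°), the parasagittal row (F3/F4/P3/P4) at 36° elevation and
±36°/±144° azimuth, the coronal row (Fz, C3, C4, Pz) at 54°, and Cz at the
pole. On a 240.80 mm sphere this reproduces a published 84-row coordinate
table to better than 0.005 mm, which is why the package treats ±0.05 mm as
its round-trip tolerance everywhere.

Depths are implemented as exact thirds (not 0.33/0.66): published
distances behave as $R/3$ multiples (e.g. an insertion depth of
80.27 mm = 240.80/3), so "33%" is read as rounded presentation of 1/3.
The four depths live on concentric spheres: radius $R$ for `Z0`/`Z100`
and $R/3$ for `Z33`/`Z66`.

### The deep-point transform

For depths past the half-diameter, the physically radial continuation of
the insertion line crosses to the contralateral side: a rod pushed through
C3 exits under C4. Published tables, however, book-keep the deep points
ipsilaterally: the deepest C3 point is printed at (0, 0, −194.81) — under
C3, not C4. The package therefore applies, by default, the transform
$M(x,y,z) = (x,-y,-z)$ — a 180° rotation about the left–right axis — to
the radial unit vector at `Z66`/`Z100` (`deep_projection = "mirror"`).
The physically radial alternative (`"antipode"`, $-\hat u$) is available;
for midline electrodes the two coincide. Which one a given laboratory's
bookkeeping used is worth checking before comparing tables.

## Imputation under the pads

Sites under stimulating pads cannot be recorded. Two rules apply:

* **Voltage imputation** (`impute_pad_voltages()`): a pad site's ΔV at
  each depth is the arithmetic mean of its neighbours' ΔV at that depth.
  The default neighbour sets for the central pads are the five
  same-hemisphere adjacent electrodes, midline excluded — C3 →
  {F7, F3, T3, P3, T5}, C4 → {F8, F4, T4, P4, T6} — chosen because they
  reproduce published imputed pad fields at the three inserted depths to
  within 0.01 mV/mm. Other pads fall back to their five nearest
  recordable electrodes by great-circle distance; the rule is
  user-overridable per pad.
* **Reference-surface imputation** (`impute_reference_surface()`): the
  reference's own surface site has distance zero, so ΔV/distance is
  undefined there; the field is imputed as the mean of the neighbours'
  surface fields instead, flagged `imputed_ef`.

A non-reference pad's surface site has a positive distance, and the
default recomputes ΔV-mean/distance there. Some published tables print a
0 placeholder at that cell instead; `build_field_table(strict = TRUE)`
reproduces that convention. Missing ΔV at a non-pad electrode is always an
error, never silently imputed.

One published inconsistency is worth knowing about: in the monopolar
reference table this package uses as its test oracle, the field column for
F3, F4, P3 and P4 disagrees with those rows' own printed ΔV and distance
(the implied distances suggest a transcription slip), and consequently the
printed reference-surface value (404.08 mV/mm) — a mean over two of those
rows — differs from the recomputed one (≈382 mV/mm). The package always
reproduces the self-consistent arithmetic (EF·distance = ΔV holds
identically on its output) and the test suite excludes those four
electrodes from numeric comparison while asserting the identity instead.

## The synthetic phantom

`simulate_recordings()` emulates the measurement with a quasi-static
point-source forward model: each pad is discretised into an $n \times m$
grid of point sources (default 3×3) sharing the pad current equally,
inset 2 mm below the surface to avoid singularities at surface recording
sites, and the potential is the free-space monopole superposition

$$V(p) = \frac{1}{4\pi\sigma}\sum_k \frac{I_k}{\lVert p - p_k\rVert},$$

with a single scalar conductivity $\sigma$ (default 0.5 S/m, a standard
brain-tissue order of magnitude). ΔV is $|V(E) - V(\text{pickup})|$ with
the pickup at the centre of the reference pad's grid, mimicking the
reference electrode taped to the pad. An extracephalic return is a single
point 20 mm below the bottom pole (it sits in the water bath, not on the
peel). Readout noise is multiplicative Gaussian, $(1+\varepsilon)$,
$\varepsilon \sim N(0, \mathrm{cv})$ with cv = 0.05 by default — large
enough to exercise the imputation and summary stages, small enough to
avoid sign flips — with an optional rounding step to mimic a coarse
oscilloscope readout.

The montage presets follow the three validation experiments: A —
monopolar, anodes over C3/C4 (7×5 cm, 1 mA each, 2 mA total),
extracephalic return (8×6 cm), reference on C3; B — fronto–occipital,
anodes Fp1/Fp2, returns O1/O2 (5×5 cm, 0.7 mA per pad), reference on O1;
C — latero–lateral, anodes F7/T5, returns F8/T6, reference on T6.

**What the simulator is and is not.** The free-space kernel ignores the
insulating boundary (no image sources), the two-layer peel/pulp
conductivity contrast, electrode–gel interface impedance and the bath
geometry. It produces the right *qualitative* spatial structure —
1/r decay, superposition, montage symmetry — which is what the analysis
stages need for testing. Simulator output is validated by those
properties, never against measured magnitudes, and passing tests say
nothing about quantitative field prediction in real phantoms. The kernel
is isolated in `potential_at()`, so a boundary-corrected Green's function
could be substituted without touching the pipeline.

## Visualisation

ΔV and EF are drawn on the four concentric spheres as orthographic discs
(anterior = viewed along −y, posterior = along +y, superior = along −z),
with warm colours for high values. Shading between electrodes is
inverse-distance weighting (power 2) over the projected 2-D positions,
masked to the disc — a deliberately simple scheme with no claim of
physical interpolation. Electrodes on the hidden hemisphere are drawn
hollow and excluded from the shading. The default colour scale is shared
across the four depths of one figure so depths are comparable;
`scale = "per-depth"` or explicit bounds override it. Four-panel figures
order the depths Z0, Z33, Z66, Z100 as panels (A)–(D).

## Numerical choices and degenerate inputs

* Units are exactly as recorded: ΔV in mV, distances in mm, EF in mV/mm;
  no SI rescaling. Angles are degrees at the interface, radians
  internally.
* Exported CSVs round to two decimals (presentation style); all
  comparisons and downstream arithmetic use unrounded values.
* On-sphere membership is checked at 1e−6 relative tolerance before depth
  projection; layout invariants (points on sphere, mirror symmetry of
  homologues) hold to 1e−9 relative.
* Zero distance yields `NaN` from `compute_ef()` and is resolved by the
  reference-surface rule; an all-zero recording set maps to an all-zero
  field table.
* Simulation problem sizes are small by construction (≤ 36 point sources,
  84 field points), so the whole suite — including end-to-end pipeline
  runs for the three montages — computes in seconds on one CPU.

## Worked example

```{r example}
rec <- load_recordings(phantom_example("condition_a_recordings.csv"),
                       phantom_example("condition_a_meta.json"))
tab <- build_field_table(rec)
summarize_field_table(tab, include_imputed = FALSE)
```

```{r simulate}
lay <- montage_layout(240.80)
sim <- simulate_recordings(stimulus_montage("B"), lay,
                           forward_model_params(noise_cv = 0, seed = 1))
simtab <- build_field_table(sim, lay)
head(summarize_field_table(simtab), 4)
```

## Known limitations

* Only the 21-electrode 10–20 montage; no 10–10/10–5 extensions, no
  ellipsoidal or mesh-based phantom geometry, no MRI registration.
* The field estimate is scalar; no directional field estimation or
  finite-element solving.
* The simulator is qualitative (see above); no tissue layering, no
  time-varying waveforms.
* Statistical comparison across phantoms is out of scope: the pipeline
  analyses one recording set at a time.
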