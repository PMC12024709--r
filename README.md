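# phantomEF

Transcranial direct current stimulation (tDCS) injects a weak direct
current (1.4–2 mA) through scalp pads, and the electric field (EF) it
induces at depth is hard to measure in people. A cheap alternative is a
physical head phantom — a roughly head-sized conducting sphere
instrumented at the 21 standard 10–20 electrode positions — in which one
records, during stimulation, the voltage difference ΔV between an inserted
probe and a reference electrode taped to a stimulating pad, at four
insertion depths (the surface Z0 and 1/3, 2/3 and the full diameter:
Z33, Z66, Z100).

`phantomEF` turns those recordings into depth-resolved field maps. It is
aimed at neurostimulation researchers who run phantom validation
experiments (or want to design them) and need the geometry, arithmetic and
graphics handled reproducibly.

The core quantities:

* **Geometry.** The phantom is approximated by a perfect sphere of radius
  *R*. Each 10–20 electrode has fixed elevation/azimuth angles; its
  surface position is `center + R(cos λ sin α, cos λ cos α, sin λ)`. The
  four depths live on concentric spheres (radius *R* for Z0/Z100, *R*/3
  for Z33/Z66); depths past the half-diameter use the transform
  M(x, y, z) = (x, −y, −z), keeping deep points book-kept ipsilaterally.
  All coordinates are re-centred on the recording reference, and each
  site's distance to that origin is the field denominator.
* **Field estimate.** EF = ΔV / distance (mV/mm) — an average-magnitude
  scalar estimate, not a vector field.
* **Imputation.** Sites under stimulating pads cannot be recorded; their
  ΔV is the arithmetic mean of surrounding electrodes at the same depth
  (for the central pads, the five same-hemisphere neighbours). At the
  reference's own surface site the distance is zero, so the field there is
  the mean of the neighbours' surface fields instead.
* **Simulator.** A quasi-static point-source forward model on a
  homogeneous conducting sphere (V = I/4πσr, superposed over discretised
  pads) generates synthetic recording sets for the standard montages, so
  every stage is testable without hardware.

## Worked example

The package bundles a measured recording set for the monopolar montage
(anodes over C3 and C4, extracephalic return, 2 mA; recording reference on
the C3 pad; 240.80 mm sphere):

```r
library(phantomEF)

rec <- load_recordings(phantom_example("condition_a_recordings.csv"),
                       phantom_example("condition_a_meta.json"))
tab <- build_field_table(rec)
d <- as.data.frame(tab)
d[] <- lapply(d, function(x) if (is.numeric(x)) round(x, 2) else x)
subset(d, electrode %in% c("Cz", "C3") & depth == "Z100")
#>    electrode depth  x_mm y_mm    z_mm distance_mm delta_v_mV     status ef_mV_per_mm
#> 40        C3  Z100  0.00    0 -194.81      194.81      42800 imputed_dv       219.70
#> 44        Cz  Z100 70.77    0 -217.81      229.01      52000   measured       227.06
```

Cz at the deepest level sits 229.01 mm from the reference origin and its
measured 52,000 mV yields 227.06 mV/mm; the pad-covered C3 site is imputed
from its five neighbours (mean ΔV 42,800 mV → 219.70 mV/mm).

```r
s <- summarize_field_table(tab, include_imputed = FALSE)
subset(s, depth == "Z0" & quantity == "delta_v")
#>   depth quantity  min argmin   max argmax     mean mean_left mean_right
#> 1    Z0  delta_v 8080    Fpz 39600    Fp2 27256.84  29342.86   28171.43
```

The surface maximum is at Fp2 (39,600 mV) and the minimum at Fpz
(8,080 mV). Topographic maps on the four concentric spheres:

```r
render_map(tab, "ef", depth = "all", view = "superior", out = "ef_maps.png")
```

To simulate instead of measure, and run everything end to end:

```r
res <- run_pipeline(condition = "B", seed = 7, noise_cv = 0.05,
                    out_dir = "out", plots = TRUE)
```

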