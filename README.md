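# scratchkin

Quantification of *in vitro* scratch (wound-healing) assays from
fluorescence time-lapse images, based on single-nucleus recognition.

In a scratch assay, a cell-free gap is introduced into a confluent
epithelial monolayer and its repopulation — re-epithelialization — is
imaged at fixed intervals. `scratchkin` turns per-well folders of
nuclear-stained TIFF series into re-epithelialization kinetics:

1. **Nuclei segmentation** — an illumination function is estimated per
   frame from block minimum intensities, smoothed with a Gaussian filter
   and subtracted; nuclei are identified by a global Otsu threshold,
   declumped with an intensity watershed (nuclei are brighter toward
   their interior than their edges), and filtered to a per-well
   equivalent-diameter range. Centroid, area, eccentricity and mean
   intensity are extracted per nucleus.
2. **Scratch-band detection** — the horizontal cell-free band is found
   automatically from the cell-frequency histogram along the image rows
   at the first timepoint: the largest run of empty bins, extended by
   merging nearby small gaps across bins that hold only straggler cells.
   Vertical or diagonal scratches are handled by a per-well clockwise
   rotation given in the plate index file.
3. **Infiltration counting** — nuclei are classified inside/outside the
   band (by centroid, half-open interval) in every frame, producing a
   per-well count series over time.
4. **Kinetic modelling** — the count of infiltrating cells follows a
   sigmoidal curve, modelled by the modified Gompertz function

   N(t) = A · exp( − exp( (μ_m · e / A) · (λ − t) + 1 ) )

   fitted by Levenberg–Marquardt nonlinear least squares. The three
   parameters are biologically interpretable: **λ** (minutes) is the lag
   before cells start infiltrating (negative if migration began before
   imaging), **μ_m** (cells/minute) the maximum repair rate — the slope
   at the inflection point — and **A** (cells) the plateau count, a
   proxy for wound-closure status. Fits with R² < 0.9 or without
   convergence are flagged for inspection; a characteristic cause is an
   adverse (cytotoxic) treatment whose counts decline after an early
   plateau, which the monotone model cannot track. Plate quality across
   positive/negative controls is summarised by the Z′ factor.

A ground-truthed synthetic plate generator (confluent monolayer,
scratch band, Gompertz-driven infiltration, realistic background ramp
and noise) makes every stage testable without any image download.

## Worked example

Simulate a two-well plate (600 × 800 px frames, band at rows 220–420,
16 timepoints every 20 minutes) and run the full pipeline on it:

```r
library(scratchkin)

spec <- plate_spec(n_wells = 2L, seed = 42L)
sim  <- simulate_plate(spec, "demo_plate")
res  <- run_pipeline(sim$index, "demo_plate", "demo_out")
print(res)
#> plate_result: 2 well(s), 0 flagged, 0 failed

print(res$wells$W01$band)
#> scratch_band: rows [210, 438) (228 px high), 3 merged gap(s)

print(res$wells$W01$fit)
#> kinetic_fit [W01]: A = 300 cells, mu_m = 1.999 cells/min, lambda = 29.91 min
#>   R^2 = 1.0000, RMSE = 0.244 over 16 points, converged
```

The generating parameters of this plate were A = 300 cells,
μ_m = 2 cells/min, λ = 30 min: the detected band brackets the true
rows [220, 420) (bin resolution plus half-nucleus margins), and the
fitted kinetics recover the truth to a fraction of a percent.
`demo_out/` now holds per-well feature tables (`features_<well>.tsv`),
the infiltration counts (`counts.tsv`), band geometry (`bands.tsv`),
kinetic parameters with flags (`parameters.tsv`), one fitted-curve PNG
per well, and a static `report.html`.

Screening quality from control wells, e.g. fitted μ_m values of
positive controls with mean 100 and sd 5 versus negative controls with
mean 20 and sd 5:

```r
z_prime(c(95, 100, 105), c(15, 20, 25))
#> [1] 0.625
```

A shell front end wrapping the same functions is installed with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/scratchkin.R", package="scratchkin"))') \
    run --index demo_plate/index.tsv --out demo_out
```

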