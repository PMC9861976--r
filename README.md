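# gaquant

Automated detection and quantification of **geographic atrophy (GA)** on
spectral-domain OCT macular cubes, from multi-layer boundary
segmentations.

GA — the late lesion of dry age-related macular degeneration — has a
clean geometric signature once a segmentation platform has placed the
ellipsoid zone (EZ), retinal pigment epithelium (RPE) and Bruch's
membrane (BM) boundary lines on each B-scan: where photoreceptors and
RPE are lost, the EZ–RPE and RPE–BM thicknesses are zero and the three
lines become **confluent**. `gaquant` builds a full quantification
pipeline on that rule:

* **Per B-scan**: flag columns where `rpe_row − ez_row ≤ tol` and
  `bm_row − rpe_row ≤ tol` (default tol 0.5 px), and dilate them into a
  10-pixel ground-truth band centred on the BM line.
* **En face**: reduce each mask by a depth-wise maximum, resize
  horizontally by block maximum, and stack one row per B-scan into a
  top-down GA map; project maps back onto B-scans along the BM line.
* **Lesions**: 8-connected components; per-lesion greatest linear
  dimension in µm, computed as the image-moments major axis
  `4·sqrt(λ_max)` of the covariance of pixel centers *scaled to µm per
  axis* (en face grids are ~12 µm × ~47–62 µm anisotropic); CAM grading
  — **cRORA** if the dimension meets the 250-µm threshold, **iRORA**
  otherwise; GA area as % of scan area with and without sub-threshold
  lesions.
* **Evaluation**: confusion metrics (accuracy, sensitivity,
  specificity, precision, F-score), Pearson r, two-way
  absolute-agreement single-measure ICC with F-based confidence
  intervals, and pooled pixel-wise ROC/AUC.
* **Learning demonstrator**: a from-scratch encoder–decoder
  segmentation network (5×5 kernels, BCE loss, RMSProp at 1e-4, batch
  40, 200 samples/epoch, early stopping at patience 7) with
  30th-percentile hard-example retraining and patient-grouped
  train/val/test splitting.
* **Phantoms**: a synthetic macular-cube generator (two device
  geometries, elliptical lesions, boundary confluence, sub-BM
  hypertransmission) with an analytic truth footprint, so every stage is
  testable end to end without clinical data.

## Worked example

```r
library(gaquant)

g  <- oct_geometry("spectralis")            # 97 x 512 over 6 x 6 mm
ph <- simulate_phantom(g, n_lesions = 3, seed = 7, render = FALSE)
map <- compile_enface(mask_volume(ph$layers, g), g)
measure_lesions(map, g)
#> <lesion_report> 3 lesion(s): 2 cRORA, 1 iRORA (threshold 250 um)
#>   GA area: 0.864% of scan (all), 0.822% (cRORA only)
#> # A tibble: 3 x 5
#>   label area_px area_um2 gld_um cam_class
#>   <int>   <int>    <dbl>  <dbl> <chr>
#> 1     1     247  179043.   596. cRORA
#> 2     2      21   15222.   188. iRORA
#> 3     3     161  116704.   500. cRORA
```

Three simulated lesions are recovered as three en face components; the
two whose greatest linear dimension meets 250 µm are graded cRORA (their
analytic major axes were 594, 186 and 496 µm — the moments measurement
recovers them to within the grid's quantization). Excluding the iRORA
lesion lowers the GA area summary from 0.864% to 0.822% of scan area,
the direction the cRORA-only convention always takes.

`autoplot()` methods render en face maps, graded lesion overlays, ROC
curves and training histories; `tidy()`/`glance()` give tibble views of
reports. A thin CLI covering
`simulate | mask | enface | lesions | evaluate | split | train |
predict | pipeline` lives at `inst/cli/gaquant.R`:

```sh
Rscript inst/cli/gaquant.R pipeline --preset spectralis --lesions 3 \
    --seed 7 --out-dir out/
```

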