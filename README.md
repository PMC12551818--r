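# drgvol

Volumetric MRI analysis of mouse dorsal root ganglia (DRGs).

In Fabry disease, globotriaosylceramide (Gb3) accumulates in DRG sensory
neurons and enlarges the whole ganglion, making DRG size a non-invasive
imaging biomarker for disease progression and treatment response. In mice
the lumbar DRG lies directly against the ventral-lateral spinal cord with no
T2 contrast between the two, so it cannot be segmented directly. This
package implements a spinal-cord-referenced measurement for axial
T2-weighted stacks, for imaging scientists running preclinical longitudinal
studies:

1. integer-pixel dorso-ventral alignment of the slices,
2. averaging of the two cord-only slices rostral to the ganglion,
3. cord edge detection on the averaged reference (smoothed-gradient
   magnitude, innermost closed contour),
4. maximum intensity projection (MIP) over the ganglion-bearing slices,
5. zeroing of the cord region and intensity-based delineation of the
   remaining hyperintense ganglion.

The delineated pixels are summed into the cross-sectional area

    CSA = pixel_count x pixel_area,       pixel_area = (FOV_lr/n_lr)(FOV_dv/n_dv)

(0.0061035 mm^2 at the default 2 x 1.5 cm FOV, 256 x 192 matrix), the
maximal axial cross-section used as the volume surrogate. Around the
measurement sit:

* **Reliability statistics** — one-way random-effects ICC
  `(MSB - MSW)/(MSB + MSW)`, Bland-Altman bias and 95% limits of agreement
  `bias +/- 1.96 SD(diff)`, and per-unit relative differences
  `100 (test_px - retest_px)/pair mean`, computed on integer pixel counts.
* **Longitudinal cohort statistics** — group pooling, two-sided
  pooled-variance Student's t-tests under a closed testing procedure
  (endpoint first; step back in time only while p < alpha), and the
  histology positivity formula `100 x positive_px/total_px`.
* **A synthetic phantom generator** — analytic cord/DRG/fat-ring anatomy
  rasterized on the acquisition grid with Rician noise, repositioning
  jitter, and longitudinal cohorts with group-specific CSA trajectories;
  it emits exact ground-truth pixel counts, so every pipeline stage is
  validated against a closed-form oracle without any scan data.

## Worked example

```r
library(drgvol)

# a synthetic scan with known anatomy (cord SNR 10)
ph <- render_phantom(phantom_spec(noise_sigma = 40, seed = 1))
ph$truth$sides$left$true_pixel_count
#> [1] 49

res <- run_pipeline(ph$stack)
res$records
#> # A tibble: 2 x 6
#>   animal_id side  timepoint group   pixel_count csa_mm2
#>   <chr>     <chr>     <dbl> <chr>         <int>   <dbl>
#> 1 animal    left         NA unknown          46   0.281
#> 2 animal    right        NA unknown          47   0.287
```

The measured 46/47 px sit within the truth's 20-px boundary-perimeter band
of the 49-px ground truth — whole-pixel delineation can never be closer
than the partial-volume boundary allows.

```r
# test-retest reliability of the bundled ten-DRG wild-type table
tt <- testretest_csa()
pairs <- test_retest_pairs(paste(tt$mouse, tt$side),
                           tt$csa_test_mm2, tt$csa_retest_mm2)
reliability_report(pairs)
#> <reliability_result> n = 10 DRG units, k = 2
#>   mean CSA: test 0.258, retest 0.255 mm^2
#>   ICC (one-way random effects): 0.904
#>   bias 0.003 mm^2, SD of differences 0.032, LoA [-0.060, 0.066] mm^2
#>   mean relative difference 2.480%
```

An ICC of 0.90 with limits of agreement of about +/-0.06 mm^2 around a
0.003 mm^2 bias: the measurement repeats well against its ~0.26 mm^2 scale.

## Analysis workflow

The `analysis/` scripts are thin drivers over the package, writing their
tables and figures under `results/`:

| script | what it does |
|---|---|
| `analysis/01_testretest_reliability.R` | reliability report, scatter and Bland-Altman figures from the bundled test-retest table |
| `analysis/02_phantom_recovery.R` | noiseless and 50-seed SNR-10 phantom recovery against the rasterization oracle |
| `analysis/03_cohort_longitudinal.R` | synthetic four-group cohort, pooling, closed-testing comparisons, trajectory figure |

## Method and design notes

`vignettes/drg-volumetry.Rmd` documents the model and its assumptions, the
delineation rule that replaces the manual step, what the phantom does and
does not emulate, the statistical forms used, numerical edge cases, and
known limitations.
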