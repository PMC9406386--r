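# icgperf

Quantitative indocyanine-green (ICG) fluorescence angiography for perfusion
assessment: an analytic inflow-curve model, parameter extraction from
time–intensity recordings or image stacks, a calibrated synthetic cohort
generator, and the statistical battery used to relate perfusion parameters
to anastomotic-leak outcomes.

## The science in brief

After an intravenous ICG bolus, the fluorescence intensity of a tissue
region rises from a baseline to a peak as dye washes in; how *fast* and how
*high* it rises reflects local perfusion. icgperf models this inflow as a
gamma-variate indicator-dilution curve and quantifies each recording with
five parameters:

* **Fmax** (AU) — peak intensity above baseline,
* **Tmax** (s) — time from fluorescence onset to the peak,
* **T½** (s) — time from onset to half-maximum on the rising limb,
* **Slope** (AU/s) — Fmax/Tmax, the mean inflow rate,
* **TR** — T½/Tmax, a dimensionless rise-shape ratio.

In a four-group rodent colonic-ischemia design (healthy control plus three
increasing devascularisation grades), Slope falls and T½ stretches
monotonically with ischemic severity, Slope correlates positively with
anastomotic bursting pressure, and a Slope cutoff of 0.4 AU/s classifies
anastomotic-leak outcomes with 75% sensitivity and 81.4% specificity on the
emulated cohort counts. Since per-animal recordings from such studies are
rarely published, the package ships a seeded generator calibrated to the
group-level figures so the entire chain — curve files in, statistical
report out — runs reproducibly from scratch.

## Worked example

Calibrate a control-grade curve, sample it with 2% acquisition noise, and
extract the parameters back:

```r
library(icgperf)

spec <- calibrate_gamma(fmax = 176, tmax = 192, t_half = 8.8)
spec
#> <gamma_spec>
#>   baseline      5 AU
#>   amplitude     176 AU (analytic Fmax)
#>   t_onset       10 s
#>   t_peak_offset 192 s (analytic Tmax)
#>   shape         0.3256

curve <- gamma_curve(spec, dt = 1)
set.seed(2)
curve$intensity_au <- curve$intensity_au + rnorm(nrow(curve), 0, 0.02 * 176)
extract_parameters(curve)
#> # A tibble: 1 × 10
#>   baseline baseline_sd t_onset  fmax  tmax t_half slope     tr flag_max_at_end
#>      <dbl>       <dbl>   <dbl> <dbl> <dbl>  <dbl> <dbl>  <dbl> <lgl>
#> 1     4.88        3.40    7.82  179.  234.   10.7 0.763 0.0459 FALSE
```

Or run the whole study emulation — simulate the four-group cohort to
per-animal CSV files, re-extract every parameter from the files, and run
the full statistical analysis:

```r
dir <- tempfile("icg-demo-")
report <- run_pipeline(seed = 1, out_dir = dir)
report
#> <icg_report>
#>   35 animals, 4 groups; 0 excluded, 0 missing outcomes
#>   Slope ROC AUC = 0.816; at cutoff 0.4 AU/s: sens 66.6%, spec 75.8%
#>   note: all tests two-sided at alpha = 0.05; no multiple-testing correction

tidy(report)
#> # A tibble: 4 × 9
#>   group       n  fmax  tmax t_half slope     tr bursting_pressure_mmhg leaks
#>   <chr>   <int> <dbl> <dbl>  <dbl> <dbl>  <dbl>                  <dbl> <int>
#> 1 Control    10 183.   202.   10.8 0.929 0.0542                  167.      0
#> 2 Group1      9  99.9  178.   22.2 0.574 0.126                    99.5     1
#> 3 Group2      8  95.7  199.   37.0 0.496 0.191                    85.8     1
#> 4 Group3      8  66.5  233.   69.1 0.287 0.299                    83.4     4
```

`report.json` is written next to the curve files; re-running with the same
seed reproduces it byte for byte. The same stages are scriptable from the
shell via `inst/cli/icgperf.R` (`simulate`, `extract`, `analyze`,
`run-all`).

ROI extraction from image stacks is supported directly: pass a multi-page
TIFF (or a directory of frames) plus a pixel `roi_spec()` to
`extract_roi_series()` and feed the resulting curve to
`extract_parameters()`.

## License

MIT — see `LICENSE`.
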