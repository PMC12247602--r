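# prefmorph

Tools for studies that link **economic preferences** — risk tolerance and
delay discounting estimated from binary choice tasks — to **cortical
surface morphometry**. The package covers the full analysis chain:

* **Choice modeling.** Power-utility valuation of gambles
  (`SV = p·A^α`), hyperbolic discounting of delayed rewards
  (`SV = A/(1+kD)`), and hyperbolic probability discounting
  (`SV = A/(1+h·(1−p)/p)`), all fitted per subject by softmax maximum
  likelihood (`P(accept) = 1/(1+exp(−β·ΔSV))`) with multi-start bounded
  optimization, McFadden pseudo-R², model-free choice proportions, and the
  standard screening rules (one-sided choosers; α outside [0.34, 1.32]; k
  outside [0.0017, 0.077]).
* **Surface statistics.** Mass-univariate vertex-wise regression with
  covariates, threshold-free cluster enhancement (TFCE, compiled),
  Freedman–Lane permutation inference, per-tail Benjamini–Hochberg FDR,
  directional conjunction analysis, cluster tables (peak coordinate, TFCE
  value, extent k) and a top-N peak-area multi-measure regression.
* **Mesh utilities.** Icosphere construction, adjacency and connected
  components, FWHM-calibrated surface smoothing, spherical and geodesic
  ROIs, GIFTI and plain-array surface I/O.
* **Synthetic cohorts.** Generators for choice data, covariates and smooth
  vertex-metric maps with planted effects, calibrated to published sample
  descriptives — so the entire pipeline runs, and is tested, without any
  imaging data.

## Worked example

Simulate a cohort, fit both tasks for every subject, and run the surface
pipeline with a planted conjunction effect:

```r
library(prefmorph)

# one subject first: fit risk tolerance from 120 simulated choices
coh  <- generate_cohort_choices(cohort_spec(n_subjects = 156, seed = 11))
est  <- fit_preference(coh$datasets[["sub-001"]]$risky)
est
#> <preference_estimate> power: parameter = 0.9153, beta = 0.1547, pseudo-R2 = 0.337

# the whole cohort, with exclusions
fits <- fit_cohort(coh$datasets)
summary(fits$alpha)
table(fits$included)
#> FALSE  TRUE
#>     4   152

# end-to-end surface analysis (simulation mode)
report <- run_pipeline(run_config(seed = 7, output_dir = "out"))
report
#> <pipeline_report> 149 subjects included of 156 fitted
#>   complexity   conjunction vertices: 24
#>   gyrification conjunction vertices: 0
#>   sulcal_depth conjunction vertices: 0
#>   thickness    conjunction vertices: 0
#>   gmv          conjunction vertices: 0
#>   1 conjunction cluster(s); top peak TFCE 308.9 (k = 24)
report$clusters[, c("peak_x", "peak_y", "peak_z", "peak_tfce", "extent_k")]
#>               peak_x   peak_y    peak_z peak_tfce extent_k
#> complexity -49.25136 62.70744 -6.486903  308.9033       24
```

The report says: of 156 simulated subjects, 149 survive the screening
rules; only the measure carrying the planted effect (`complexity`) shows a
conjunction — vertices where *both* a higher risk tolerance and a steeper
discount rate independently predict lower metric values at FDR q ≤ .05 —
and its single cluster (24 vertices) peaks inside the planted disc. The
accompanying peak-area regression (`report$peak_area`) shows the carrying
measure dominating all others. Maps, tables and a JSON report land in
`out/`.

A thin command-line wrapper with `simulate`, `fit-behavior`, `vertexwise`,
`conjunction` and `run` subcommands is installed at
`system.file("cli", "prefmorph.R", package = "prefmorph")`.

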