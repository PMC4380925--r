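# morphloc

Single-cell morphometry → transcription-factor localization analysis.

High-content screens can measure, for hundreds of thousands of single
cells, both the shape and microenvironmental context of each cell and
the nuclear localization of a transcription factor such as NF-κB
(p65/RelA), whose activation is proxied by the ratio of nuclear to
perinuclear fluorescence intensity. `morphloc` provides the full
analysis chain for such screens, for computational biologists who want
to relate morphology to TF activation:

* **Synthetic data with ground truth** — rendered two-channel scenes
  (abutting cells in colonies, offset nuclei, planted TF ratios),
  single-cell feature tables generated from planted structural
  equations with morphological state mixtures and treatment shifts,
  fold-change panels, and damped oscillatory translocation traces.
* **Feature extraction** — watershed/propagation segmentation into
  nucleus, cytoplasm, membrane band and perinuclear ring (EBImage), and
  a 77-feature catalog: geometry, protrusions, polarity, context
  (neighbor fraction `NF`, colonies), and intensities including
  ruffliness and `tf_ratio` = mean nuclear / mean perinuclear TF
  intensity.
* **Profiling** — per-well means, population-SD Z-scores, PCA
  morphospace (first 8 PCs), hierarchical clustering of cell lines
  (centered correlation, centroid linkage), and selection of the 17
  features most frequently significantly different (Welch t, P < 0.01)
  between high- and low-ratio cells across lines.
* **Dependency networks** — per line/condition Bayesian networks over
  the 17 features + TF log-ratio: quantile discretization, BDeu-scored
  hill climbing, bootstrap edge confidence (B = 100), undirected edges
  where orientation is unstable, and cross-line dependency-frequency
  summaries at confidence > 0.6.
* **Shape-response regression** — the three-predictor multilinear model
  Δtf = c₀ + c_NF ΔNF + c_ruff Δruffliness + c_ratio Δ(A_nuc/A_cyto) + ε
  with tenfold cross-validation and 95%-prediction-interval outlier
  flagging.
* **Translocation dynamics** — first-peak amplitude/time and Morlet
  continuous-wavelet estimation of instantaneous oscillation periods
  (30–240 min grid, cone-of-influence masking), with per-condition
  period-frequency histograms at a fixed time.

See `vignettes/morphloc-methods.Rmd` for the model assumptions, every
tunable parameter with its default and rationale, and known
limitations.

## Worked example

```r
library(morphloc)

# a 9-cell two-colony scene with planted TF ratio 1.6 (+/- lognormal noise)
sc <- simulate_scene(scene_spec(
  image_size = 384L,
  colony_plan = data.frame(x = c(110, 270), y = c(110, 260),
                           n = c(4, 5), spacing = 0.95),
  tf_ratio_target = 1.6, tf_ratio_sd_log10 = 0.08, seed = 42L))
cells <- extract_feature_table(sc$nucleus, sc$body, sc$tf)
cells[1:3, c("cell_area", "neighbor_fraction", "ruffliness",
             "area_nuc_cyto", "tf_ratio")]
#>   cell_area neighbor_fraction ruffliness area_nuc_cyto tf_ratio
#> 1  1658.313             0.286      0.164         0.271    1.493
#> 2  1543.393             0.430      0.167         0.284    1.344
#> 3  1578.460             0.299      0.156         0.263    1.589
```

Cell areas are in µm² (pixel size 0.65 µm/px); `neighbor_fraction` is
the fraction of each cell's boundary in contact with neighbors (higher
for the interior cells of a colony); `tf_ratio` scatters around the
planted 1.6 because of the per-cell lognormal heterogeneity.

```r
# shape-response regression on a 176-condition synthetic panel whose
# noise is calibrated to population R^2 = 0.37
co <- default_panel_coefficients()          # signs: c_nf < 0, c_ruff > 0, c_ratio < 0
panel <- simulate_fold_change_panel(co, 176L,
                                    panel_noise_for_r2(co, 0.37), seed = 1L)
cv <- crossvalidate_and_flag_outliers(panel, folds = 10L, seed = 2L)
cv$model
#> ShapeResponseModel (n = 176): R^2 = 0.327, error variance = 0.01161, P = 1.04e-14
#>   d_tfratio = 0.777 -0.179 d_nf +0.299 d_ruffliness -0.310 d_anucacyto
sprintf("CV error (MAE): %.4f +/- %.4f; outliers: %d",
        cv$cv_mae_mean, cv$cv_mae_sd, cv$n_outliers)
#> "CV error (MAE): 0.0880 +/- 0.0098; outliers: 7"
```

The fitted signs reproduce the planted (and biological) structure: the
NF-κB response falls with cell–cell contact and nuclear/cytoplasmic
area ratio, and rises with membrane ruffliness. Seven of 176 conditions
lie outside the 95% prediction interval, consistent with the interval's
nominal coverage.

```r
# damped translocation oscillation: first peak and wavelet period
tr <- simulate_trace(oscillation_params(period = 115, noise_sd = 0))
pk <- first_peak_metrics(tr)
sp <- wavelet_periods(tr)
sprintf("first peak: amplitude %.2f at %d min; modal period %.1f min",
        pk$amplitude, pk$time, modal_period(sp))
#> "first peak: amplitude 0.50 at 30 min; modal period 114.5 min"
```

The modal instantaneous period recovered outside the cone of influence
(114.5 min) falls in the 110–120 min band characteristic of NF-κB
nuclear import/export cycling; the 0.6% offset from the planted 115 min
is the logarithmic period grid's resolution.

An end-to-end run (profiling + networks + regression + dynamics on
bundled synthetic inputs, with a seed/hash manifest) is

```r
run_screen(list(stages = c("profile", "networks", "regression", "dynamics"),
                out_dir = "run1", seed = 7L))
```

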