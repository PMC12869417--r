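# mriuq — conformalized quantile-regression uncertainty for accelerated MRI

Undersampled (parallel-imaging) MRI reconstructions degrade as the
acceleration factor grows, and in the absence of a fully-sampled reference
there is no direct way to see *where* a reconstruction went wrong. `mriuq`
implements a conformal quantile-regression framework for pixelwise
uncertainty quantification that can wrap any reconstruction method, together
with a self-contained multi-coil Cartesian k-space simulator so the whole
stack runs on a laptop with no external data. It is aimed at researchers in
MRI reconstruction and distribution-free uncertainty quantification.

## Method

For a reconstruction magnitude image `x`, two sigmoid-bounded per-pixel
offset fields `s_l, s_u ∈ [0,1]` parameterize raw quantile bounds

```
l̃(x) = x − s_l·x,    ũ(x) = x + s_u·x
```

trained with the pinball (quantile) loss at levels `a/2` and `1 − a/2`
(`a = 1 − coverage`, coverage 0.90 by default), or — as the ResM baseline —
a single symmetric half-width fitted to `|x − y|` by least squares. Because
trained quantiles are not automatically valid, a conformal calibration step
rescales the offsets by the smallest λ whose Hoeffding-corrected miscoverage
bound on a held-out calibration set stays below `a`:

```
l̃_b = x − λ·(x − l̃),   ũ_b = x + λ·(ũ − x),
λ* = min { λ : R̂(λ) + sqrt(log(1/δ) / (2I)) ≤ a }
```

The evaluation suite produces the uncertainty map `q̃ = ũ_b − l̃_b` (no
ground truth needed), the error map `ẽ = |x − y|`, Gaussian-blurred (σ = 2)
Pearson/Spearman correlations between them, 100-region block-averaged
variants, empirical coverage, normalized uncertainty percentages, and
threshold maps against a reference acceleration.

Modules: phantom/coil/k-space simulation (`make_phantom`, `make_coil_maps`,
`simulate_kspace`, `make_split_dataset`), Cartesian masks with protocol ACS
fractions (`protocol_acs_fraction`, `make_cartesian_mask`, `apply_mask`),
reconstruction operators and baselines (`reduce_operator`,
`expand_operator`, `rss`, `data_consistency`, `zero_filled_rss`,
`unrolled_reconstructor`, `ssim`), the uncertainty module (`quantile_bounds`,
`pinball_loss`, `qr_total_loss`, `resm_loss`, `feature_predictor`,
`train_uq`), conformal calibration (`interval_at_lambda`,
`miscoverage_risk`, `hoeffding_upper_bound`, `calibrate_lambda`), metrics
(`uncertainty_map`, `error_map`, `gaussian_blur`, `pearson`, `spearman`,
`region_correlations`, `coverage`, `threshold_map`), and I/O plus an
end-to-end pipeline (`run_pipeline`, YAML configs, NPY/JSON serialization,
a thin CLI at `inst/cli/mriuq`).

## Worked example

Simulate a small study, reconstruct zero-filled at 4× acceleration, train
quantile offsets, calibrate, and evaluate:

```r
library(mriuq)
cfg <- run_config(anatomy = "synthetic", acceleration = 4,
                  n_train = 12, n_cal = 30, n_test = 6, seed = 7)
res <- run_pipeline(cfg, run_dir = file.path(tempdir(), "demo"))
print(res$calibration)
#> Conformal calibration (pooled, I = 30 images, 122880 pixels)
#>   alpha = 0.1, delta = 0.1, grid [0, 4] (401 points)
#>   chosen lambda = 1.02 (risk 0.0726, bound 0.0756)
round(res$report_df[, c("slice", "coverage", "pearson", "region_pearson",
                        "uncertainty_mean_pct", "ssim")], 3)
#>   slice coverage pearson region_pearson uncertainty_mean_pct  ssim
#> 1     1    0.947   0.595          0.736               14.419 0.553
#> 2     2    0.953   0.588          0.685               15.196 0.611
#> 3     3    0.853   0.769          0.835               13.429 0.519
#> 4     4    0.969   0.424          0.473               17.559 0.654
#> 5     5    0.910   0.648          0.757               15.240 0.539
#> 6     6    0.914   0.649          0.757               14.721 0.557
```

Reading the output: the raw quantile offsets needed only a 2% widening
(λ* = 1.02) to reach the 90% miscoverage budget on the calibration set;
per-slice coverage on unseen slices scatters around 0.9 or above; the
blurred Pearson correlation between the ground-truth-free uncertainty map
and the true error map is positive on every slice (stronger in the
block-averaged regional variant); and the mean calibrated interval width is
~13–18% of the maximum reconstruction magnitude on these strongly aliased
zero-filled reconstructions (SSIM ≈ 0.5–0.65).

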