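# flimlpd

Fit-free analysis of fluorescence lifetime imaging microscopy (FLIM) data by
Laguerre polynomial deconvolution and simulation-trained random-forest
chemometrics.

## The problem

A TCSPC FLIM measurement yields, at every pixel, a histogram of photon
arrival times — a *decay trace*. The physics is a multi-exponential decay
convolved with the instrument response function (IRF):

```
I(t) = ∫₀ᵗ R(t − T) Σᵢ αᵢ exp(−T/τᵢ) dT  +  Poisson noise
```

The quantities of interest are the lifetimes `τᵢ` (which identify molecular
species, e.g. free vs protein-bound NAD(P)H at roughly 0.2–0.3 ns and
2–3 ns) and their abundances `αᵢ` (relative concentrations, Σαᵢ = 1).
Per-pixel nonlinear curve fitting recovers them but is slow, sensitive to
initialization, and fragile at the low photon counts typical of biological
imaging.

`flimlpd` instead:

1. **Deconvolves without fitting.** Generalized Laguerre polynomials
   `B_n^(α)` (default α = 2, n = 1…15) are convolved with the measured IRF
   to give `L_n^(α)`; each trace is projected onto the convolved basis by
   (constrained) least squares, `I = C·L`, and re-expanded on the
   unconvolved basis, `I_d = C·B`, which removes the IRF in one linear
   step shared by all pixels.
2. **Predicts with simulation-trained models.** Pure multi-exponential
   decays with known `τᵢ, αᵢ` drawn from configurable ranges (peak
   ~150 counts, Poisson noise, *no* IRF) train one PCA (15 components)
   plus 2N random forests (500 trees, 63.2% per-tree sampling without
   replacement, mtry = 12) — one forest per lifetime and per abundance.
   Because training data are IRF-free and prediction operates on
   deconvolved traces, one trained bundle transfers across instruments
   and across image sizes without retraining.
3. **Scores reconstructions.** Predicted parameters are pushed back through
   the forward model and compared with the measured traces by per-pixel
   RMSE; two methods' maps can be compared by per-pixel RMSE ratios, and
   simulated cubes with known truth yield bias/interval recovery reports.

## Worked example

```r
library(flimlpd)

cfg  <- sim_config(n_components = 2)      # peak 150 counts, Poisson noise
irf  <- gaussian_irf(cfg$time)            # synthetic IRF: center 0.5 ns, sigma 0.05 ns

train  <- make_training_set(cfg, m = 3000, seed = 1)
bundle <- train_bundle(train, seed = 2)
bundle
#> <flim_bundle> N = 2 components, 4 models (PCA 15 comps -> RF 500 trees), p = 921

sim  <- make_test_cube(cfg, irf, nx = 32, ny = 32, seed = 3)
maps <- predict_cube(bundle, sim$cube, irf)
maps
#> <flim_maps> 32 x 32 pixels, N = 2 (1024 kept)

al <- align_truth(sim, maps)
print(as.data.frame(recovery_report(al$truth, al$predicted)), digits = 2)
#>   quantity component              unit bias ci_lo ci_hi ci_halfwidth
#> 1      tau         1         % of true 14.9   -32   143           88
#> 2      tau         2         % of true  1.5   -26    41           33
#> 3    alpha         1 percentage points  1.1   -24    27           25
#> 4    alpha         2 percentage points -1.1   -27    24           25

rmse_map(sim$cube, maps, irf)
#> <flim_rmse_report> ML: 1024 traces, median RMSE = 5.362
```

Reading the output: per quantity, `bias` is the mean prediction error
(lifetimes as % of the true value, abundances in percentage points) and
`ci_lo`/`ci_hi` bound the central 95% of the per-pixel error distribution.
The slow lifetime and the abundances recover with modest bias; the sub-ns
lifetime scatters widely because, at a 150-count peak, only a few dozen
photons constrain it — see the vignette for the photon-budget analysis.
The median RMSE of ~5.4 counts against traces with ~150-count peaks and
Poisson noise is essentially the shot-noise floor.

Real data enter through `read_cube_tiff()` (multi-page TIFF, one page per
time channel) and `read_irf()` (two-column CSV); `trim_channels()`,
`subtract_offset()` and `mask_pixels()` handle raw 1024-channel cubes.
Maps import/export as CSV (`read_parameter_maps()` /
`write_parameter_maps()`), so parameter maps exported from other software
can be compared with `rmse_map()` + `rmse_ratio()`.

A thin command-line wrapper with `simulate`, `train`, `predict` and
`evaluate` subcommands is installed as `exec/flimlag`; see
`inst/extdata/example-config.yaml` for its configuration schema.

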