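# liftfrap

Noninvasive estimation of the full 3D anisotropic diffusion tensor from
volumetric fluorescence-recovery-after-photobleaching (FRAP) time
series, by 3D spatial Fourier analysis — plus a virtual light-sheet FRAP
microscope, an independent finite-difference diffusion oracle, the
classical single-plane 2D FRAP analysis for comparison studies, and
auxiliary metrics (Stokes–Einstein predictions, structure-tensor
coherency, tissue water content).

## Who this is for

Researchers quantifying direction-dependent molecular transport in
structured biological media — cornea, tendon, engineered fibrous
scaffolds, hydrogels — where a scalar diffusivity (or an invasive
sectioned-tissue 2D measurement) misrepresents the physiology, and
anyone needing a reproducible in-silico testbed for volumetric FRAP
estimator design.

## The method in one paragraph

Under free anisotropic diffusion every spatial Fourier mode of the
concentration field decays exponentially,

C̃(q, t) = C̃(q, 0) · exp(−4π² qᵀ D q t),  q = (u, v, w) in cycles/µm,

so the decay rate k(q) = 4π²(Dxx u² + Dyy v² + Dzz w² + 2Dxy uv +
2Dxz uw + 2Dyz vw) is linear in the six components of the symmetric
tensor **D**. The pipeline normalizes each postbleach volume by the
averaged prebleach record, Fourier transforms the result, fits an
exponential to each low-frequency mode, and solves for **D** by weighted
linear least squares over ≥ 6 independent mode directions. Eigenvalues
λ₁ ≥ λ₂ ≥ λ₃ (principal diffusivities), the fractional anisotropy
FA = √[(λ₁−λ₂)² + (λ₁−λ₃)² + (λ₂−λ₃)²] / √[2(λ₁²+λ₂²+λ₃²)] ∈ [0, 1],
and the mean diffusivity follow from the eigendecomposition; tensors can
be rotated into a sample (tissue) coordinate frame with
`rotate_tensor()`.

## Worked example

```r
library(liftfrap)

truth <- diffusion_tensor(20, 10, 5, dxy = 2)       # ground truth, µm²/s
cfg <- sim_config(truth, grid = c(64, 64, 32), n_prebleach = 8,
                  n_postbleach = 60, noise = noise_spec(), seed = 42)
series <- simulate_liftfrap(cfg)   # 76 µm FOV, 8 volumes/s, 10 µm bleach cube
fit <- analyze_frap3d(series)

tidy(fit)
#> # A tibble: 6 × 3
#>   component  estimate std.error
#>   <chr>         <dbl>     <dbl>
#> 1 dxx       20.2          0.440
#> 2 dyy        9.89         0.236
#> 3 dzz        5.00         0.105
#> 4 dxy        1.20         0.564
#> 5 dxz        0.225        0.289
#> 6 dyz       -0.000898     0.205

glance(fit)
#> # A tibble: 1 × 8
#>   lambda1 lambda2 lambda3    fa mean_diffusivity n_modes median_r2 is_spd
#>     <dbl>   <dbl>   <dbl> <dbl>            <dbl>   <int>     <dbl> <lgl>
#> 1    20.3    9.75    4.99 0.589             11.7      36     0.942 TRUE
```

The recovered components sit within a standard error or two of the
truth (λ of the true tensor: 20.4, 9.6, 5.0; FA 0.592). `autoplot(fit)` shows
the per-mode recovery curves with their fitted decays, and
`plot_rate_fit(fit)` the fitted rates against the assembled quadratic
form. `write_frap_results(fit, "result")` writes the schema-versioned
JSON tensor serialization, the per-mode CSV table and a log.

Other entry points: `fd_diffuse()` (zero-flux/periodic anisotropic
finite-difference solver with an enforced stability bound),
`analyze_frap2d()` / `fa_from_2d()` (classical single-plane pipeline and
its λ₃ := λ₂ anisotropy proxy), `benchmark_recovery()` (simulate →
analyze sweeps over diffusivity, seed and photon budget),
`stokes_einstein()`, `structure_coherency()`, `water_content()`, and a
thin CLI at `inst/cli/liftfrap` (`simulate`, `analyze`, `analyze2d`,
`benchmark-recovery`, `metrics`).

## Package layout

| Area | Files |
| --- | --- |
| Tensor algebra (eigensystem, FA, rotation) | `R/tensor.R` |
| Virtual microscope + spectral propagator | `R/simulate.R` |
| Finite-difference PDE oracle | `R/pde.R` |
| 3D analysis pipeline | `R/analyze-3d.R` |
| 2D single-plane pipeline | `R/analyze-2d.R` |
| Auxiliary metrics | `R/metrics.R` |
| TIFF/JSON input-output | `R/io.R`, `R/series.R` |
| Benchmark harness, plots | `R/benchmark.R`, `R/plots.R` |

The methods vignette (`vignettes/liftfrap-methods.Rmd`) documents the
model, the estimator's design choices, the noise model, the numerical
tolerances and the known limitations.
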