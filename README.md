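# spectralflow

Multi-b-value spectral diffusion MRI of the kidney, with per-component
flow estimation.

Kidney cortex voxels mix three kinds of water motion: restricted
diffusion in tissue parenchyma, tubular flow, and fast capillary
pseudo-diffusion. From a clinical nine-b-value trace-weighted DWI
acquisition (b = 0–800 s/mm²), `spectralflow` decomposes each voxel's
normalized decay curve S(b)/S₀ into distinct diffusion components and
summarizes each one with the flow proxy **fD** — the product of signal
fraction and diffusion coefficient, proportional to the volume flux out
of a unit cube for an isotropic Gaussian component:

- **Spectral diffusion** (the core method): regularized non-negative
  least squares over M = 300 log-spaced exponentials,
  min‖As − y‖² + λ‖Ls‖² with s ≥ 0, λ = 0.1, L the second-difference
  operator. Peaks of the spectrum are segmented, filtered
  (D < 0.8×10⁻³ mm²/s excluded) and binned into tissue (< 5), tubule
  (5–50) and vascular (≥ 50×10⁻³ mm²/s) regimes. No starting values, no
  fixed component count.
- **Bayesian biexponential** (conventional IVIM):
  f·e^(−bD\*) + (1−f)·e^(−bD) with log-normal priors on D and D\*,
  solved on a deterministic posterior grid with the noise scale
  marginalized analytically.
- **Bounded triexponential least squares** with the standard published
  start and bounds.

The package also ships the simulation framework used to validate the
methods (anisotropic tensors with targeted FA, stretched-exponential
anomalous components exp(−(bD)^γ), Rician noise at SNR 50), agreement
statistics (pooled regression, Bland–Altman, symmetrized percent
difference), a voxel-wise NIfTI mapping pipeline with ROI summaries, and
a command-line interface (`inst/cli/spectralflow` with `simulate`,
`fit`, `map`, `evaluate`, `phantom` subcommands).

## Worked example

```r
library(spectralflow)

## flow constants from the sphere-escape solve
fc <- flow_constants()
round(fc$two_sigma_sq, 4)                      # 0.2113 mm^2
round(fc$sigma, 4)                             # 0.3251 mm
round(half_residence_time(0.0015, fc), 1)      # 35.2 s

## decompose a noiseless three-component cortical curve
curve <- gaussian_signal(f = c(0.6, 0.3, 0.1),
                         D = c(0.0015, 0.010, 0.070),  # mm^2/s
                         bvalues = default_bvalues())
spectral_fit_voxel(curve)
#> <component_fit> method = spectral  flag = ok  R2 = 1
#>                 tissue  tubule vascular
#> f               0.6119  0.2921   0.0959
#> D (1e-3 mm2/s)  1.5846 10.5487  72.5199
#> fD (1e-3 mm2/s) 0.9697  3.0817   6.9573
```

The three regimes are recovered within grid resolution; the vascular
component's flow proxy, fD ≈ 7.0×10⁻³ mm²/s, converts to an absolute
flow of 0.132 ml/(g·s) via `flow_proxy()`.

A simulated cohort exercises a full method comparison:

```r
sim <- simulate_cohort(cohort_config(n_sets = 100, master_seed = 42))
evaluate_cohort(sim, fit_cohort(sim, "biexp"))
#> <agreement_report> method = biexp  mean fit R2 = 0.991
#>   f   y = 0.64x +0.12, R2 = 0.24; BA = 0.00 (-0.5, 0.5)
#>       median delta%: vascular 106.5, tubule 200.0, tissue 10.1
#>   D   y = 0.38x -1.05, R2 = 0.68; BA = -17.63 (-58.0, 22.7) (1e-3 mm2/s)
#>       median delta%: vascular 95.1, tubule 200.0, tissue 17.8
#>   fD  y = 1.15x -0.88, R2 = 0.71; BA = -0.33 (-5.1, 4.5) (1e-3 mm2/s)
#>       median delta%: vascular 26.1, tubule 200.0, tissue 30.2
```

Read: the biexponential tracks the pooled flow proxy well
(fD slope 1.15, R² = 0.71) but, having only two pools, reports the
tubular component as absent — the structural 200% entries — while its
tissue fraction is excellent (10% median difference). Swapping
`"spectral"` or `"triexp"` into `fit_cohort()` produces the same report
for the other methods. See the methods vignette
(`vignettes/spectral-diffusion-kidney.Rmd`) for the models, parameter
choices and known limitations — including why vascular
super-diffusion sits awkwardly on the 50×10⁻³ mm²/s regime boundary for
spectral binning.

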