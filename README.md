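# stgf — single-scan adaptive spatio-temporal graph filtering for dynamic PET

Dynamic PET scans trade photon counts for temporal resolution: each
short frame yields a sinogram corrupted by Poisson noise,
`p_j ~ Poisson(H x_j + r_j)`, and the noise propagates and amplifies
through tomographic reconstruction. `stgf` denoises the *sinogram
sequence* before reconstruction, using only the scan at hand — no
training data, no fixed transform.

The method represents the dynamic sinogram `Y` (bins × frames) on two
similarity graphs and filters it from both sides with their
symmetrically normalized adjacencies:

```
Y(i+1) = F_S(i) · Y(i) · F_T(i)ᵀ ,   F = D^(-1/2) W D^(-1/2)
```

* the **spatial graph** connects each sinogram bin to its k = 80
  nearest neighbours in a feature space of duration-weighted composite
  frames (Gaussian kernel, σ_s = 0.5);
* the **temporal graph** connects time frames within a window of 9 by
  the similarity of their smoothed, high-activity-masked count rates
  (Gaussian kernel, σ_t = 1).

Both graphs are **re-estimated at every iteration** from the current,
cleaner iterate, and a **dual-domain stopping rule** combines the
relative change of the sinogram and of its MLEM reconstruction
(`w1‖ΔY‖/‖Y‖ + w2‖ΔI‖/‖I‖ < ε`, defaults w1 = w2 = 0.5, ε = 0.01), so
the iteration is steered by final image quality. Ablation modes `sgf`
(spatial only) and `tgf` (temporal only) are built in.

The package is self-contained for validation: it ships a seeded dynamic
FDG brain-phantom simulator (two-tissue compartment kinetics, 24-frame
schedule, 20 % randoms/scatter background, 8 M total counts, Poisson
noise), a sparse Siddon-style projector with MLEM, and the evaluation
metrics (relative MSE, bias, variance, region MAE, SSIM).

## Worked example

```r
library(stgf)

ds  <- simulate_dataset(phantom = make_phantom(63), n_realizations = 1, seed = 1)
sys <- build_system_matrix(63)

fit <- stgf(ds$noisy[[1]], sys, r = ds$r,
            durations = ds$schedule$dur, n_iter_mlem = 30)
print(fit)
#> Spatio-temporal graph filter fit (mode STGF)
#>   3969 x 24 sinogram, 4 outer iteration(s), converged (measure 0.009489 < epsilon 0.01)

base <- mlem(ds$noisy[[1]], sys, r = ds$r, n_iter = 30)
print(evaluate_recon(base, ds$truth_images, ds$phantom))
#> Reconstruction metrics over 1 realization(s), 24 frame(s)
#>   mean MSE 0.7762 (77.6%), mean SSIM 0.3920, bias -0.01254, var 0
#>   per-region MAE (frame-averaged):
#> background       gray      white     lesion
#>     0.2216     0.3898     0.2395     0.6941
print(evaluate_recon(fit$images, ds$truth_images, ds$phantom))
#> Reconstruction metrics over 1 realization(s), 24 frame(s)
#>   mean MSE 0.09305 (9.3%), mean SSIM 0.6093, bias -0.00788, var 0
#>   per-region MAE (frame-averaged):
#> background       gray      white     lesion
#>     0.2101     0.1955     0.1115     0.6368
```

Four outer iterations reduce the frame-averaged image-domain relative
MSE from 77.6 % (MLEM on the noisy input) to 9.3 %, raise the mean
SSIM from 0.39 to 0.61, and lower the MAE in every tissue region. `fitted()` returns the denoised sinogram,
`residuals()` the removed component, `plot()` the stopping-measure
trace, and `summary()` the full iteration history.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/stgf.R simulate --side 63 --realizations 5 --seed 1 --out ds.rds
Rscript inst/cli/stgf.R denoise  --input ds.rds --mode stgf --out fit.rds
Rscript inst/cli/stgf.R demo     # reduced end-to-end pipeline with metrics
```

## Package layout

* `R/phantom.R`, `R/kinetics.R`, `R/simulate.R` — phantom, compartment
  model, frame schedule, two-stage noise model, seeded dataset
  generator
* `R/projector.R`, `R/mlem.R` — sparse line-integral system model,
  MLEM, Poisson log-likelihood
* `R/graphs.R` — composite frames, kNN spatial graph, temporal graph,
  mask, symmetric normalization, graph export
* `R/stgf.R` — the iterative engine (`stgf()`) and its S3 methods
* `R/metrics.R`, `R/io.R` — evaluation metrics, dataset container,
  config round-trip, NIfTI export
* `vignettes/stgf-methods.Rmd` — model, conventions, design decisions,
  limitations
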