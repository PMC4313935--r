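# dkiphantom

Digital phantoms and non-local means denoising for diffusion kurtosis
imaging (DKI).

Estimating kurtosis requires diffusion weightings of b = 2000–2500 s/mm²,
where SNR is low and the Rician noise of magnitude MRI systematically
inflates the estimated kurtosis. Judging whether a denoising filter actually
protects the fitted parameter maps needs a ground truth no scanner can
provide. `dkiphantom` addresses this for researchers developing or
evaluating diffusion-MRI denoising:

* it **constructs noise-free, tensor-consistent DKI phantoms** from a real
  or synthetic acquisition — every voxel of the phantom is an exact
  realization of the kurtosis signal model

  S(b) = S₀ · exp(−b·D + b²·D²·K/6),

  with D(n) = nᵀ**D**n from a diffusion tensor and
  K(n) = MD²·W(n)/D(n)² from a rank-4 kurtosis tensor, so the "right
  answer" is known exactly;
* it implements the **NLM denoising family** for diffusion data — 3D
  non-local means, Rician-unbiased NLM, and vector NLM that jointly
  denoises volumes sharing a b-value (VNLM-b) or sharing a gradient
  direction across b-values (VNLM-d) — with the standard parameterization
  (5×5×5 search region, 3×3×3 patch, ρ = 1, h = 1.0σ/0.8σ/1.2σ per
  variant);
* it provides the **Rician noise model** (synthesis and background-based σ
  estimation, σ = √(μ/2)) and an **evaluation harness** computing MSE,
  bias and standard deviation of denoised DW images and MD/MK maps across
  repeated noise realizations;
* a **synthetic tensor phantom generator** (white-matter-like rotating
  fibers, gray-matter-like and CSF-like compartments) makes everything
  runnable and testable without any data download.

I/O uses standard NIfTI volumes plus FSL-style `.bval`/`.bvec` tables. A
thin command-line wrapper (`inst/cli/dkiphantom.R`) exposes the
`simulate` / `add-noise` / `denoise` / `fit` / `construct` / `resample` /
`evaluate` workflow for shell use.

## Worked example

```r
library(dkiphantom)

# ground-truth phantom under a 30-direction, 6-b-value acquisition
ph  <- make_tensor_phantom()                     # 32 x 32 x 12 voxels
sch <- make_gradient_scheme(30, c(0, 500, 1000, 1500, 2000, 2500))
bundle <- phantom_from_tensors(ph$tensors, ph$S0, sch, ph$voxel_size,
                               ph$brain_mask, ph$background_mask)
bundle$noise_free$scheme$n_volumes
#> [1] 151

# corrupt with Rician noise, estimate sigma from the background
noisy <- add_rician(bundle$noise_free$signal, sigma = 15, seed = 11)
nds <- dwi_dataset(noisy, sch, ph$voxel_size, ph$brain_mask, ph$background_mask)
estimate_sigma(nds$signal[, , , 1], nds$background_mask)
#> [1] 14.95733

# denoise with direction-grouped vector NLM and fit MD/MK
den <- denoise_dwi(nds, "vnlm_d", sigma = 15)
maps <- mean_dki_maps(fit_dki_directions(den))

# benchmark the three filters at the highest noise level (sigma = S0/12)
bench <- default_phantom_bundle()                # 12 directions, b <= 2500
res <- evaluate_filters(bench, modes = c("nlm", "vnlm_b", "vnlm_d"),
                        sigmas = 25, n_reps = 25, seed = 1)
res[res$target == "MK", c("filter", "mse", "bias", "std")]
#>   filter        mse       bias        std
#> 3    nlm 0.10281954 0.22381755 0.12877168
#> 6 vnlm_b 0.07419255 0.16230939 0.10387330
#> 9 vnlm_d 0.02281828 0.08437261 0.05679991
```

The benchmark table reads: at noise level σ = 25 (baseline SNR ≈ 12), the
mean-kurtosis map recovered after VNLM-d denoising has roughly 4–5× lower
MSE, and less than half the systematic bias and repetition-to-repetition
spread, of the map recovered after plain voxelwise NLM — volumes along one
gradient direction at different b-values share structure, and denoising
them jointly preserves the shape of the decay curve that the kurtosis fit
depends on. (On the DW images themselves VNLM-d is not uniformly best; its
advantage is specifically in the parameter maps.)

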