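# pmwave

Edge-preserving denoising of grayscale images by solving the Perona–Malik
anisotropic diffusion equation with an interpolating-wavelet multilevel
collocation method on adaptive sparse grids.

## The problem and the method

Smoothing an image with a Gaussian (heat equation) removes noise but blurs
edges. Perona–Malik replaces the constant diffusivity with a decreasing
function of the local gradient modulus,

```
∂u/∂t = div( c(|∇u|) ∇u ),     u(·,0) = f,
c(g) = 1 / (1 + (g/k)²)   or   c(g) = exp(−(g/k)²),
```

so diffusion is suppressed across strong edges (|∇u| ≫ k) and proceeds in
flat, noisy regions (|∇u| ≲ k). This package discretises the equation with
collocation on interpolating scaling functions — Shannon (sinc),
Shannon–Gabor, or the autocorrelation of a Daubechies scaling function (the
Deslauriers–Dubuc fundamental function) — on nested dyadic grids of the unit
square:

- **Interval basis with dynamic extension.** On a finite interval the basis
  is completed by `L` external collocation points per side whose values come
  from Lagrange extrapolation of interior data; equivalently (and cheaper,
  via the inheritance property) from truncated Newton divided-difference
  forms. `L` can be chosen *dynamically* from the decay of boundary divided
  differences, subject to the rule that the 1-norm condition estimate of the
  linearised time-step matrix may not grow by a factor ≥ 10 when `L`
  increases (`select_L_dynamic()`, `estimate_condition()`).
- **Multilevel sparse grid.** Nodal values are converted level by level into
  hierarchical surpluses α¹/α²/α³ (the interpolation residuals at the three
  families of new dyadic nodes, `sg_decompose()`); coefficients below a
  magnitude threshold are dropped from the active set (`sg_compress()`), and
  the field and all derivatives up to second order are evaluated from active
  coefficients only (`sg_reconstruct()`). The recursive transform costs
  O(4^J) coefficient evaluations versus O(4^{2J}) for the explicitly
  assembled operators (kept as a small-grid verification oracle,
  `extension_operators()`).
- **Homotopy predictor–corrector stepping.** Embedding each time step in a
  homotopy parameter ε ∈ [0,1] and truncating the perturbation series at
  first order yields an explicit Euler predictor followed by a trapezoidal
  corrector (second order in Δt), with the wavelet coefficients refreshed
  and re-thresholded between stages (`hpm_step()`).
- **Block partitioning.** Large images are tiled into even blocks solved
  independently (no halo exchange — boundary data is extrapolated from each
  block's own interior), with per-block, per-step condition estimates and a
  seam metric quantifying added block-boundary discontinuities
  (`solve_blocks()`, `seam_metric()`).

A conservative finite-difference solver (`fd_reference_solve()`) serves as
the comparison baseline, and a seeded phantom generator
(`generate_phantom()`) provides disk, step-edge, microgroove and cosine
scenes with calibrated Gaussian noise.

## Worked example

```r
library(pmwave)

ph  <- generate_phantom(129, "disks", noise_sigma = 0.05, seed = 42)
fit <- pm_denoise(ph$noisy, pm_control(), clean = ph$clean)
fit
#> Perona-Malik sparse-grid denoising
#>   image: 129 x 129   c: rational (k = 2)   tau = 1e-05   t_end = 5e-05
#>   basis: daub_autocorr   threshold: 0.001
#>   active collocation points: 16451 -> 16400
#>   PSNR vs clean: 25.96 dB -> 26.38 dB
```

The printout reads: a 129×129 noisy disk phantom was diffused for five steps
of `tau = 1e-5` with the rational diffusivity. Of the 129² = 16641 possible
collocation points, 16451 were active initially (coefficients above the
1e-3 threshold) and 16400 after the last step — the active set shrinks as
the image smooths, which is what makes the sparse-grid representation pay
off. PSNR against the clean reference improves from 25.96 dB to 26.38 dB,
while `range(fitted(fit))` stays inside the input range (edges are not
overshot). `plot(fit)` shows input, output and the removed-noise residual;
`summary(fit)` adds per-block condition estimates when a partition was used.

A shell entry point with the same options is installed at
`inst/cli/pmwave-denoise.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pmwave-denoise.R", package="pmwave"))')" \
    noisy.png denoised.png --k 2 --block 64 --dynamic-L --report report.json
```

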