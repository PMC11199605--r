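# fogbands

Tools for studying fog-driven banded vegetation patterns — the striped,
slowly migrating *Tillandsia* communities of coastal hyper-arid deserts —
and for measuring band orientation statistics in imagery.

Water and nutrients arrive by advected fog, so plant–plant facilitation and
competition are both nonlocal *and* directionally biased. fogbands
implements that theory end to end:

- **Nonlocal model** (`simulate_nonlocal()`): biomass dynamics
  `∂t b = b(1−b)Mf − μ b Mc + D∇²b` with exponential feedbacks
  `Mi = exp[χi ∫ φi(r, r′) b(r′) dr′]` and shifted anisotropic Gaussian
  kernels `φi`. Nonzero kernel offsets make the interaction nonreciprocal
  (`φ(r, r′) ≠ φ(r′, r)`), the fingerprint of fog flow, and set the bands
  in motion. Mixed boundary conditions: biomass pinned to bare ground at
  the upwind/downwind walls, periodic transversally.
- **Reduced model** (`simulate_reduced()`, `map_parameters()`): the
  weak-gradient fourth-order PDE
  `∂t b = −ηb + κb² − b³/2 + d∇²b − b(α∂x + γ∂x² + ∂x⁴)b`, with the
  closed-form mapping from the nonlocal parameters, homogeneous states
  `b± = κ ± √(κ² − 2η)` and the tipping point `(κ/2, κ²/4)`.
- **Linear stability** (`dispersion()`, `critical_point()`,
  `enumerate_modes()`): closed-form growth rate
  `Re λ = b(κ−b) − dk² + b(γkx² − kx⁴)`, `Im λ = −bαkx`; the
  pattern-forming threshold; and the discrete sine/Fourier modes a finite
  mixed-boundary box admits — horizontal (`n = 0`) and oblique (`n = ±1`)
  band families.
- **Amplitude equations** (`amplitude_rhs()`, `equilibrium_branches()`,
  `simulate_envelope()`): the Ginzburg–Landau envelope and its three-mode
  truncation `A = H + O_l e^{iΔky} + O_r e^{−iΔky}`, with equilibrium
  branches, their stability, and the bifurcation diagram showing the
  supercritical horizontal branch, the initially unstable oblique branch,
  its stabilization through the mixed branch, and the H/O coexistence
  window.
- **Orientation analysis** (`preprocess_image()`, `orientation_field()`,
  `angle_difference_hist()`, `alignment_correlation()`): rolling-ball
  background removal, structure-tensor orientation and coherence fields,
  slope-direction fields, angular-difference histograms with mode
  detection, and the band-normal alignment correlation
  `⟨cos(γ⊥ − Γ)⟩`.
- **Synthetic data** (`make_banded_scene()`, `make_dem()`,
  `make_noise_ic()`): seeded striped scenes with known orientation
  domains, dislocation defects, gradients and noise; elevation ramps with
  known slope direction; noisy simulator initial conditions — so the whole
  pipeline is testable without any satellite downloads.

## Worked example

Three discrete unstable modes just above threshold — one horizontal band
family and a symmetric oblique pair:

```r
library(fogbands)

p  <- reduced_params(eta = -0.219, kappa = 0.3, d = 0.3, gamma = 2)
bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]   # 1.026636
ms <- enumerate_modes(p, bp, Lx = 85, Ly = 100)
ms[ms$unstable, ]
#> # A tibble: 3 × 8
#>       m     n    kx      ky re_lambda im_lambda unstable label
#>   <int> <int> <dbl>   <dbl>     <dbl>     <dbl> <lgl>    <chr>
#> 1    25    -1 0.924 -0.0628   0.00138         0 TRUE     O_r
#> 2    25     0 0.924  0        0.00256         0 TRUE     H
#> 3    25     1 0.924  0.0628   0.00138         0 TRUE     O_l

critical_point(kappa = 0.3, d = 0.3, gamma = 2)
#> # A tibble: 1 × 3
#>    eta_c   k_c b_plus
#>    <dbl> <dbl>  <dbl>
#> 1 -0.221 0.924   1.03
```

The horizontal mode `(m, n) = (25, 0)` destabilizes first (growth rate
2.56e-3 at `k ≈ 0.924`), flanked by the oblique pair `(25, ±1)`; the
threshold itself sits at `η_c ≈ −0.2214`. With nonreciprocity `α = 0.27`
the saturated horizontal pattern migrates at phase speed
`b₊·α = 0.661 × 0.27 ≈ 0.178`, which `measure_drift_speed()` recovers from
simulations within a few percent.

On the image side, a synthetic wind-aligned patch with a horizontal family
at 120° and obliques at 113°/127° (wind Γ = 30° CCW from east, noise SD
0.08):

```r
spec <- scene_spec(width = 256, height = 256, wavelength = 16,
  domains = list(
    list(xmin = 0,   xmax = 85,  ymin = 0, ymax = 256, angle = 120),
    list(xmin = 85,  xmax = 170, ymin = 0, ymax = 256, angle = 113),
    list(xmin = 170, xmax = 256, ymin = 0, ymax = 256, angle = 127)),
  contrast = 0.25, noise_sd = 0.08, gradient = c(8e-4, 5e-4), seed = 11)
scene  <- make_banded_scene(spec)
pre    <- preprocess_image(scene, blur_sigma = 1, ball_radius = 20)
orient <- orientation_field(pre, sigma_w = 4)
tidy(angle_difference_hist(orient, 30, binwidth = 1))
#> # A tibble: 3 × 3
#>   location height label
#>      <dbl>  <dbl> <chr>
#> 1     83.3  5897. O_r
#> 2     90.3  5945  H
#> 3     97.2  5636. O_l
alignment_correlation(orient, 30)
#> [1] 0.9942741
```

The wind-difference histogram is trimodal — the horizontal family at 90°
plus the ±7° obliques — and the band-normal alignment correlation is ≈ 0.99
(cos 7° ≈ 0.9925), the synthetic analogue of the tight wind–pattern
alignment seen in real patches.

Most results are tibbles with `autoplot()`, `tidy()` and `glance()`
methods; fields are light raster objects with `as_tibble()`/`autoplot()`
for ggplot2 work. `run_config()`/`run_pipeline()` drive whole stages
reproducibly and write their resolved configuration beside their outputs.

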