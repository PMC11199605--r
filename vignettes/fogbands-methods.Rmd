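---
title: "Models and methods behind fogbands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fogbands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(fogbands)
```

## The system

Rootless *Tillandsia* communities on coastal desert dunes survive entirely on
advected fog. Seen from above they organize into periodic bands, mostly
perpendicular to the prevailing wind, with coexisting domains tilted a few
degrees to either side — horizontal and oblique banded patterns. fogbands
implements the modelling and image-analysis toolchain for this phenomenon:
a nonlocal vegetation model with nonreciprocal feedbacks, its reduced
fourth-order PDE, the linear and weakly nonlinear analysis that predicts
horizontal/oblique coexistence, and a structure-tensor pipeline that measures
band orientation statistics on (synthetic) imagery.

## Nonlocal model

`simulate_nonlocal()` integrates

$$\partial_t b = b(1-b)\,M_f[b] - \mu\, b\, M_c[b] + D\nabla^2 b,
\qquad M_i[b](\mathbf r) = \exp\!\Big[\chi_i \int \phi_i(\mathbf r,\mathbf r')
\, b(\mathbf r')\, d\mathbf r'\Big],$$

with shifted anisotropic Gaussian kernels
$\phi_i \propto \exp[-(x-x'-x_{i0})^2/2l_{ix}^2-(y-y'-y_{i0})^2/2l_{iy}^2]$.
The offsets $x_{i0}$ encode the directional bias of fog flow; they make the
influence functions nonreciprocal, $\phi(\mathbf r,\mathbf r') \ne
\phi(\mathbf r',\mathbf r)$, which breaks reflection symmetry and sets the
bands in motion. The feedback at $\mathbf r$ integrates biomass with weight
centred at $\mathbf r' = \mathbf r - (x_{i0}, y_{i0})$; `build_kernel()`
documents this orientation and the tests pin it down with the mirror
equivariance property (mirroring the initial condition and negating the
offsets mirrors the trajectory).

Numerics. Kernels are sampled on the wrapped lag grid of the box. The
discrete mass must land within $10^{-3}$ of 1 (otherwise the box is too small
for the stated widths and the constructor refuses it, naming the violated
extent); the sampled kernel is then renormalized to exactly unit mass so
uniform biomass is an exact fixed point of the discrete feedback, not one up
to truncation tail. Convolutions run through the FFT — on the box itself for
periodic-x test domains, on a zero-padded array for Dirichlet boxes, which
implements the "bare ground beyond the walls" reading of the boundary
condition. A direct-summation oracle agrees with the FFT path to $10^{-8}$ in
the tests. Time stepping is explicit RK4 with a diffusive + reaction bound on
`dt` (`nonlocal_dt_bound()`); biomass positivity holds along trajectories up
to solver tolerance. An exponent guard rejects parameter regimes where
$|\chi_i \int \phi_i b|$ exceeds 50, long before overflow.

The box size, resolution, step and duration of the banded-pattern runs are
not dictated by the model; the package's standard setting is
$dx = 0.3$ (so $l_{fx} = 0.9 \ge 3\,dx$), a $48 \times 38.4$ box,
$dt = 0.04$ and $T \approx 100$, which is enough for a saturated banded state
from small noise at the standard parameter set
($\mu = 0.98$, $\chi_f = 2.1$, $\chi_c = 1.2$, $D = 0.2$, $x_{0f} = 0.5$,
$x_{0c} = -0.2$, $l_{fx} = l_{fy} = 0.9$, $l_{cx} = 5$, $l_{cy} = 3.5$).

Uniform states reduce to $(1-b)e^{(\chi_f-\chi_c)b} = \mu$;
`uniform_states_nonlocal()` brackets roots on a fine grid and polishes them
with `uniroot()`. At the standard parameters the vegetated state is
$b \approx 0.1216$.

## Reduced model

Near the critical point of nascent bistability ($\mu = 1$,
$\chi_f - \chi_c = 1$, $b = 0$) the model reduces to

$$\partial_t b = -\eta b + \kappa b^2 - \tfrac12 b^3 + d\nabla^2 b
  - b\,(\alpha\,\partial_x + \gamma\,\partial_x^2 + \partial_x^4)\, b,$$

with the mapping implemented by `map_parameters()` ($\kappa=\chi_f-\chi_c-1$,
$\eta=\mu-1$, $\chi_0 = l_{fx}^2/(l_{cx}^2-l_{fx}^2)$, $\chi_1=\chi_c-\chi_0$,
$\sigma = 3l_{fx}^2l_{cx}^2$, $\alpha = (x_{0c}\chi_0 - x_{0f}(1+\chi_0))/
\sigma^{1/4}$, $\gamma = \chi_1(l_{cx}^2-l_{fx}^2)/\sigma^{1/2}$). The
reduction fixes only the combination $d/\sigma^{1/2}$ as "seed dispersion",
so `d` remains an independent input and the mapping deliberately does not
emit it. Homogeneous states are $b_\pm = \kappa \pm \sqrt{\kappa^2-2\eta}$
with the tipping point $(b_l, \eta_l) = (\kappa/2, \kappa^2/4)$.

Spatial discretization is central differences (3-point first/second
derivatives, 5-point fourth derivative and Laplacian); Dirichlet walls use
two layers of zero ghost nodes, consistent with spatially confined, localized
patterns. The explicit RK4 bound is dominated by the nonlinear
hyperdiffusion: `reduced_dt_bound()` evaluates
$2.5/[b\,k_{max}^4 + (d+\gamma b)k_{max}^2]$ at the grid Nyquist wavenumber.
The default grid is $dx = dy = 0.5$ with $dt = 5\times10^{-4}$. For
quantitative growth-rate work the tests use $dx = 0.2$ and wavevectors with
$k_x\,dx \le 0.2$, where the discrete operators track the continuum
dispersion to better than 2%.

## Linear stability

Linearizing about $b_+$ gives the closed form (`dispersion()`)

$$\mathrm{Re}\,\lambda = b_+(\kappa - b_+) - d(k_x^2+k_y^2)
  + b_+(\gamma k_x^2 - k_x^4), \qquad
  \mathrm{Im}\,\lambda = -b_+\,\alpha\, k_x .$$

Only the advective term carries $\alpha$, so the growth surface is
$\alpha$-independent and the phase speed of the critical mode is
$b_+\alpha$ — the drift law that `measure_drift_speed()` verifies against
saturated simulations within 5%. The threshold solves
$\partial_k \mathrm{Re}\lambda = 0$ and $\mathrm{Re}\lambda = 0$
simultaneously; along $b_+(\eta)$ the maximizer is
$k_c^2 = (b_+\gamma - d)/2b_+$, leaving a scalar root-find in $\eta$
(`critical_point()`). At $\kappa = 0.3$, $d = 0.3$, $\gamma = 2$ this gives
$\eta_c = -0.22140$, $k_c = 0.9243$, so $\eta = -0.219$ sits just above
threshold: in an $85 \times 100$ box with Dirichlet-x sine modes
$k_x = \pi m/L_x$ and periodic-y modes $k_y = 2\pi n/L_y$, exactly three
modes are unstable — the horizontal one $(m,n) = (25,0)$ and the symmetric
oblique pair $(25,\pm 1)$ (`enumerate_modes()`). The box sizes are a
choice, not a printed fact; `admissible_box()` reports the window of $L_y$
for which only the $n=\pm1$ rows fit inside the unstable ellipse, and
$L_y = 100$ lies inside it. Labels follow $n$: `H` for $n=0$, `O_l` for
$n>0$, `O_r` for $n<0$ (the sign is a convention; nothing physical pins the
oblique families to a compass side).

## Amplitude equations

Near threshold the band envelope obeys a Ginzburg–Landau equation
$\partial_t A = \hat\mu A - (1+i\beta)|A|^2A + \nabla^2 A - \hat\alpha
\partial_x A$ (`simulate_envelope()`, pseudo-spectral RK4 on a periodic
box). Truncating $A = H + O_l e^{i\Delta k y} + O_r e^{-i\Delta k y}$ gives
three coupled amplitude equations (`amplitude_rhs()`). The model itself does
not fix $\hat\mu, \beta, \hat\alpha, \Delta k$ in terms of the reduced
parameters; `amplitude_from_linear()` wires $\hat\mu = \max_k
\mathrm{Re}\,\lambda$ and $\hat\alpha = -b_+\alpha$ from the linear analysis,
while $\beta$ and $\Delta k$ stay free inputs of the truncation, with
$\Delta k = O(\sqrt{\hat\mu})$ the intended regime.

At $\beta = 0$ the truncation is a gradient flow of the potential coded in
`amplitude_potential()`; the tests check monotonic decay along 100 random
trajectories. The equilibrium branches have closed forms: $|H| =
\sqrt{\hat\mu}$ from $\hat\mu = 0$; the single oblique $|O| =
\sqrt{\hat\mu - \Delta k^2}$ from $\hat\mu = \Delta k^2$, unstable at onset;
the oblique pair $|O|^2 = (\hat\mu-\Delta k^2)/3$ (never stable — stripes
beat rectangles); and the mixed state $|H|^2 = (\hat\mu - 2\Delta k^2)/5$,
$|O|^2 = (2\hat\mu + \Delta k^2)/15$, which branches off at $\hat\mu =
2\Delta k^2$ exactly where the single oblique stabilizes, and acts as the
basin boundary of the resulting H/O bistability.
`equilibrium_branches()` recovers the mixed branch by damped Newton on the
modulus–phase reduced system with natural continuation in $\hat\mu$ (step
halving on failure; a failed solve marks the branch absent at that point,
not an error).

Stability is computed from the Jacobian of the 6-dimensional real system.
With $\beta \ne 0$ equilibria rotate rigidly inside the phase symmetry group
$(H, O_l, O_r) \to (He^{i\theta}, O_le^{i\theta_l}, O_re^{i\theta_r})$,
$2\theta = \theta_l + \theta_r$; the Jacobian is therefore evaluated in a
frame co-rotating at the solution's own phase velocities, which shifts
eigenvalues by purely imaginary amounts and leaves stability intact. Gauge
directions appear as exact zeros and are reported (`n_neutral`), never
counted as instabilities.

## Pattern selection in the PDE, and what finite boxes do

`bifurcation_scan()` reproduces the same sequence by direct simulation:
for each aridity it integrates an H-seeded and an O-seeded state to steady
drift and records the dominant Fourier modulus and label. Three regimes
appear: below $\eta_c$ no bulk pattern; just above it an H-only window
(oblique seeds collapse onto horizontal bands); deeper in, H/O coexistence
where the seeding decides the attractor.

Two finite-box effects deserve explicit mention because the scan's
assertions are written around them. First, Dirichlet walls pin a decaying,
wavelength-$2\pi/k_c$ tail even below threshold, so the below-threshold
modulus is small but not zero; the scan checks it stays under a quarter of
the coexistence amplitude rather than at machine zero. Second, the walls
inject y-independent (H-like) forcing: in narrow transverse boxes
($L_y = 20$ at these parameters) that bias collapses even strong oblique
seeds onto H deep in the nominal coexistence regime, while a periodic
control box keeps the oblique. $L_x = 42.5$, $L_y = 40$ is the smallest box
we found whose interior behaves like the bulk, and it is the scan default;
steady drift is declared when the modulus moves less than `tol` per unit
time across a 50-time-unit window, with `tol` $= 2\times10^{-4}$ in the
scaled-down runs ($10^{-5}$ for production-length ones).

## Orientation analysis

`preprocess_image()` mirrors the standard remote-sensing chain: grayscale by
channel averaging, Gaussian smoothing ($\sigma = 1$ px), and background
removal by a rolling-ball opening (non-flat, ball-shaped structuring
element, radius 20 px) subtracted from the image. The Gaussian filters are
separable convolutions with reflected boundaries — circular (FFT) filtering
would wrap content across image edges and bias orientations there. Bit-exact
agreement with any particular GUI implementation of the rolling ball is not
a goal; recovery of known synthetic ground truth is.

`orientation_field()` builds the structure tensor from central-difference
gradients, averages it with a Gaussian window ($\sigma_w = 4$ px by
default), and reports the band orientation
$\gamma = \tfrac12\,\mathrm{atan2}(2\langle I_xI_y\rangle,
\langle I_x^2\rangle - \langle I_y^2\rangle) + 90^\circ \ (\mathrm{mod}\
180^\circ)$ — the direction along the stripes — plus the coherence
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$. Angles are degrees CCW from
east throughout, folded to $[0^\circ, 180^\circ)$ because orientations are
axial. Noiseless synthetic stripes at any angle in $\{0, 15, \dots, 165\}$
are recovered within $1^\circ$ wherever coherence exceeds 0.9.

`angle_difference_hist()` folds per-pixel differences against a reference
(wind direction, default $\Gamma = 30^\circ$ CCW from east, or a per-pixel
slope field from `slope_field()`) into $[0^\circ, 180^\circ)$, excludes
pixels below a coherence threshold (default 0.3), and detects modes as
circular local maxima above a prominence fraction, refined by parabolic
interpolation. `alignment_correlation()` averages
$\cos(\gamma_\perp - \gamma_{ref})$ over coherent pixels, where
$\gamma_\perp = \gamma_{pattern} - 90^\circ$ is the band-normal (propagation)
direction and deviations are folded to $[-90^\circ, 90^\circ)$: 1 for bands
exactly perpendicular to the reference, about 0 for parallel ones. Spatial
averaging is per coherent pixel; multi-patch aggregation, if wanted, is a
separate summary over per-patch values.

## Synthetic data: what it does and does not emulate

`make_banded_scene()` builds sinusoidal stripe domains (wavelength in
pixels, band angle per domain), a planar illumination gradient, Gaussian
pixel noise, and optional dislocations as $\pi$ phase jumps along a cut —
the ingredients the pipeline must survive. Sinusoids rather than binary
stripes match the near-threshold harmonic patterns and give closed-form
tensor ground truth. The standard validation scene has three vertical
domains at $120^\circ, 113^\circ, 127^\circ$ — a horizontal family
perpendicular to a $30^\circ$ wind plus a $\pm 7^\circ$ oblique pair — with
contrast 0.25 and noise SD 0.08 (SNR $\approx 3$, defined as
contrast/noise SD). On it the $\Delta\phi$ histogram is trimodal with modes
within $1^\circ$ of 83/90/97 and the wind alignment correlation is
$\ge 0.98$ (cos $7^\circ \approx 0.9925$).

What passing these tests does *not* show: real satellite imagery has
non-sinusoidal band profiles, curved and branching bands, spatially varying
illumination beyond a planar ramp, soil heterogeneity, and georeferencing
concerns — none of which are emulated, so quantitative claims about real
Atacama patches (the 0.98/0.1 correlations on real scenes) are out of scope
here. `make_noise_ic()` likewise fixes only what the simulators need: the
initial-condition noise is uniform with amplitude 0.1 around the state under
study (the distribution is a free choice; only "noisy" is prescribed by the
problem), clipped at zero, with Dirichlet columns zeroed.

## Reproducibility and degenerate inputs

All generators are pure functions of (spec, seed); identical seeds give
bit-identical scenes, DEMs and initial conditions, and `run_pipeline()`
writes byte-identical CSVs for identical configs. Degenerate inputs fail
loudly: non-positive grids, wavelengths under 4 px, overlapping scene
domains (ambiguous ground truth), kernels on boxes smaller than their
support, non-steady base states passed to the linearization, time steps
above the explicit bounds, flat rasters in `slope_field()` (angle flagged
`NA`), and histograms with every pixel below the coherence threshold.

## Known limitations

- The linear analysis covers the reduced equation only; the nonlocal model's
  spectrum (transcendental, through the Gaussian kernels) is probed by
  simulation, not closed form.
- The amplitude-equation coefficients are not derived from the reduced
  parameters beyond the linear-order helper; bifurcation diagrams are
  validated structurally, not against printed numerics.
- Defect dynamics (dislocation motion, domain-wall interactions) are out of
  scope; defects appear only as synthetic-scene nuisances for the pipeline.
- The drift law is verified on periodic boxes; with Dirichlet walls the
  x-drift is pinned and migration shows up in the transverse records
  instead.
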