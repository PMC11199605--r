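# Independent oracles used across the test suite.  These deliberately avoid
# the package's own code paths: plain bisection instead of uniroot-based
# routines, literal closed forms typed from scratch, and brute-force direct
# summation instead of FFT convolution.

# bisection root finder
bisect <- function(f, lo, hi, iter = 200) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) {
      lo <- mid; flo <- f(mid)
    } else hi <- mid
  }
  (lo + hi) / 2
}

# literal growth-rate formula for the reduced model (typed independently)
lambda_re_oracle <- function(kx, ky, bs, kappa, d, gamma) {
  bs * (kappa - bs) - d * (kx^2 + ky^2) + bs * (gamma * kx^2 - kx^4)
}

# direct-summation periodic convolution of a lag-grid kernel with a field
direct_conv <- function(K, b, dx, dy) {
  nx <- nrow(b); ny <- ncol(b)
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    s <- 0
    for (jj in seq_len(ny)) {
      di <- ((i - seq_len(nx)) %% nx) + 1
      dj <- ((j - jj) %% ny) + 1
      s <- s + sum(K[cbind(di, dj)] * b[, jj])
    }
    out[i, j] <- s * dx * dy
  }
  out
}

# absolute axial (mod-180) angular error in degrees
ang_err <- function(a, b) abs(((a - b + 90) %% 180) - 90)

# standard printed parameter sets used throughout
fig3_nonlocal <- function() {
  nonlocal_params(mu = 0.98, chi_f = 2.1, chi_c = 1.2, D = 0.2,
                  x0f = 0.5, x0c = -0.2, y0f = 0, y0c = 0,
                  lfx = 0.9, lfy = 0.9, lcx = 5, lcy = 3.5)
}
fig4_reduced <- function(alpha = 0.27, eta = -0.02) {
  reduced_params(eta = eta, kappa = 0.3, d = 0.3, alpha = alpha, gamma = 2)
}

# three-domain striped scene emulating one wind-aligned patch with a
# horizontal family and a +/-7 degree oblique pair (wind at 30 deg CCW from
# east; bands perpendicular to the wind at 120 deg)
three_domain_scene <- function(noise_sd = 0.08, seed = 11, width = 256) {
  w3 <- round(width / 3)
  scene_spec(
    width = width, height = width, wavelength = 16,
    domains = list(
      list(xmin = 0, xmax = w3, ymin = 0, ymax = width, angle = 120),
      list(xmin = w3, xmax = 2 * w3, ymin = 0, ymax = width, angle = 113),
      list(xmin = 2 * w3, xmax = width, ymin = 0, ymax = width, angle = 127)),
    contrast = 0.25, noise_sd = noise_sd, gradient = c(8e-4, 5e-4),
    seed = seed)
}
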