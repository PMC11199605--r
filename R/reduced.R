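#' Parameters of the reduced fourth-order model
#'
#' Near the critical point of nascent bistability the nonlocal model reduces
#' to a nonvariational partial differential equation for the biomass
#' deviation b:
#' \deqn{\partial_t b = -\eta b + \kappa b^2 - b^3/2 + d \nabla^2 b
#'   - b(\alpha \partial_x + \gamma \partial_x^2 + \partial_x^4) b}
#' where \eqn{\eta} is the aridity balance, \eqn{\kappa} the cooperativity,
#' `d` the seed-dispersion coefficient, \eqn{\alpha} the nonreciprocity
#' intensity (sets bands in motion) and \eqn{\gamma} the
#' facilitation/competition range balance.
#'
#' @param eta aridity/mortality balance (positive when mortality dominates).
#' @param kappa cooperativity.
#' @param d seed-dispersion coefficient (> 0).
#' @param alpha nonreciprocity intensity.
#' @param gamma facilitation/competition range balance.
#' @return an object of class `reduced_params`.
#' @export
#' @examples
#' p <- reduced_params(eta = -0.02, kappa = 0.3, d = 0.3,
#'                     alpha = 0.27, gamma = 2)
reduced_params <- function(eta, kappa, d, alpha = 0, gamma) {
  vals <- c(eta = eta, kappa = kappa, d = d, alpha = alpha, gamma = gamma)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  if (d <= 0) stop("d must be > 0")
  structure(as.list(vals), class = "reduced_params")
}

#' Map nonlocal-model parameters to the reduced equation
#'
#' Implements the weak-gradient parameter mapping
#' \deqn{\kappa = \chi_f - \chi_c - 1, \quad \eta = \mu - 1,}
#' \deqn{\chi_0 = l_{fx}^2/(l_{cx}^2 - l_{fx}^2), \quad
#'       \chi_1 = \chi_c - \chi_0, \quad \sigma = 3 l_{fx}^2 l_{cx}^2,}
#' \deqn{\alpha = (x_{0c}\chi_0 - x_{0f}(1+\chi_0))/\sigma^{1/4}, \quad
#'       \gamma = \chi_1 (l_{cx}^2 - l_{fx}^2)/\sigma^{1/2}.}
#' Space in the reduced equation is rescaled by \eqn{\sigma^{1/4}}.  The
#' mapping requires the competition range to exceed the facilitation range
#' (`lcx > lfx`).  The seed-dispersion coefficient `d` is not emitted: the
#' reduction ties it to the ratio \eqn{d/\sigma^{1/2}} only loosely, so `d`
#' stays an independent input of [reduced_params()].
#'
#' @param mu,chi_f,chi_c,x0f,x0c,lfx,lcx nonlocal-model parameters, either
#'   given individually or through `params`.
#' @param params optionally a [nonlocal_params()]; overrides the individual
#'   arguments.
#' @return a one-row tibble with `eta`, `kappa`, `alpha`, `gamma` and the
#'   intermediate quantities `chi0`, `chi1`, `sigma`.
#' @export
#' @examples
#' map_parameters(mu = 0.98, chi_f = 2.1, chi_c = 1.2,
#'                x0f = 0.5, x0c = -0.2, lfx = 0.9, lcx = 5)
map_parameters <- function(mu, chi_f, chi_c, x0f, x0c, lfx, lcx,
                           params = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "nonlocal_params"))
    mu <- params$mu; chi_f <- params$chi_f; chi_c <- params$chi_c
    x0f <- params$x0f; x0c <- params$x0c
    lfx <- params$lfx; lcx <- params$lcx
  }
  if (lcx <= lfx)
    stop("competition range lcx must exceed facilitation range lfx")
  if (lfx <= 0) stop("kernel widths must be > 0")
  chi0 <- lfx^2 / (lcx^2 - lfx^2)
  chi1 <- chi_c - chi0
  sigma <- 3 * lfx^2 * lcx^2
  tibble::tibble(
    eta = mu - 1,
    kappa = chi_f - chi_c - 1,
    alpha = (x0c * chi0 - x0f * (1 + chi0)) / sigma^0.25,
    gamma = chi1 * (lcx^2 - lfx^2) / sqrt(sigma),
    chi0 = chi0, chi1 = chi1, sigma = sigma)
}

#' Homogeneous states of the reduced model and the tipping point
#'
#' The uniform states are the bare state b = 0 and the cover branches
#' \eqn{b_\pm = \kappa \pm \sqrt{\kappa^2 - 2\eta}} (real when
#' \eqn{\kappa^2 \ge 2\eta}).  For \eqn{\kappa > 0} the cover branch folds at
#' the tipping point \eqn{b_l = \kappa/2}, \eqn{\eta_l = \kappa^2/4}, and the
#' system is bistable (bare vs covered) for \eqn{0 < \eta < \eta_l}.
#'
#' @param eta aridity balance.
#' @param kappa cooperativity.
#' @return a tibble with columns `branch` (`"bare"`, `"b_plus"`,
#'   `"b_minus"`), `b`, `exists` and `physical` (real and nonnegative);
#'   attributes `eta_l`, `b_l` and `bistable`.
#' @export
#' @examples
#' uniform_states_reduced(eta = -0.02, kappa = 0.3)
uniform_states_reduced <- function(eta, kappa) {
  disc <- kappa^2 - 2 * eta
  real_pair <- disc >= 0
  bp <- if (real_pair) kappa + sqrt(disc) else NA_real_
  bm <- if (real_pair) kappa - sqrt(disc) else NA_real_
  out <- tibble::tibble(
    branch = c("bare", "b_plus", "b_minus"),
    b = c(0, bp, bm),
    exists = c(TRUE, real_pair, real_pair),
    physical = c(TRUE, real_pair && bp >= 0, real_pair && bm >= 0))
  attr(out, "eta_l") <- kappa^2 / 4
  attr(out, "b_l") <- kappa / 2
  attr(out, "bistable") <- kappa > 0 && eta > 0 && eta < kappa^2 / 4
  out
}

#' Time derivative of the reduced model
#'
#' Central finite differences: 3-point first and second derivatives, 5-point
#' fourth derivative in x, 5-point Laplacian; Dirichlet walls use zero ghost
#' nodes (two layers for the fourth derivative), y is periodic.
#'
#' @param b a [veg_field()].
#' @param params a [reduced_params()].
#' @return a [veg_field()] holding \eqn{\partial_t b}.
#' @export
rhs_reduced <- function(b, params) {
  stopifnot(is_veg_field(b), inherits(params, "reduced_params"))
  if (!all(is.finite(b$values))) stop("non-finite values in input field")
  out <- rhs_reduced_cpp(b$values, params$eta, params$kappa, params$d,
                         params$alpha, params$gamma, b$dx, b$dy,
                         b$bc_x == "dirichlet")
  veg_field(out, dx = b$dx, dy = b$dy, bc_x = b$bc_x, bc_y = b$bc_y)
}

#' Explicit time-step bound for the reduced model
#'
#' The stiffest term is the nonlinear hyperdiffusion `-b dx^4 b`; at the grid
#' Nyquist wavenumber the linearized decay rate is about
#' `b_ref * kmax^4 + (d + b_ref * gamma) * kmax^2`, and RK4 tolerates
#' `dt * rate` up to about 2.8.  A 10% safety margin is kept.
#'
#' @param params a [reduced_params()].
#' @param dx grid spacing in x.
#' @param b_ref reference biomass level (defaults to the upper uniform state,
#'   or 1 if none exists).
#' @return maximal admissible dt.
#' @export
reduced_dt_bound <- function(params, dx, b_ref = NULL) {
  if (is.null(b_ref)) {
    us <- uniform_states_reduced(params$eta, params$kappa)
    b_ref <- if (isTRUE(us$exists[2]) && us$b[2] > 0) us$b[2] else 1
  }
  kmax2 <- (pi / dx)^2
  rate <- b_ref * kmax2^2 + (params$d + abs(params$gamma) * b_ref) * kmax2 + 1
  2.5 / rate
}

#' Simulate the reduced model
#'
#' RK4 integration of [rhs_reduced()].  Besides snapshots, the mid-column
#' profile b(x_mid, y, t) (the space-time record used to visualize upward
#' band migration) and the mid-row profile b(x, y_mid, t) are recorded every
#' `rec_stride` steps.
#'
#' @inheritParams simulate_nonlocal
#' @param params a [reduced_params()].
#' @param dt time step (default 5e-4 for the default dx = 0.5 grids).
#' @return a `veg_traj` (see [simulate_nonlocal()]).
#' @export
simulate_reduced <- function(params, b0, dt = 5e-4, n_steps,
                             snap_stride = 0, rec_stride = 0) {
  stopifnot(is_veg_field(b0), inherits(params, "reduced_params"))
  bound <- reduced_dt_bound(params, b0$dx,
                            b_ref = max(max(b0$values), 0.5))
  if (dt > bound)
    stop(sprintf("dt = %g exceeds the stability bound %.3g", dt, bound))
  res <- simulate_reduced_cpp(b0$values, params$eta, params$kappa, params$d,
                              params$alpha, params$gamma, b0$dx, b0$dy, dt,
                              n_steps, snap_stride, rec_stride,
                              b0$bc_x == "dirichlet")
  make_traj(res, b0, dt, "reduced", params)
}

#' Classify a banded pattern from its dominant Fourier mode
#'
#' The mean-subtracted field is transformed (with a Hann window along x when
#' the x boundary is Dirichlet, to soften the walls) and the dominant mode is
#' sought in the half-plane \eqn{k_x > 0}.  Labels: `H` for a horizontal
#' band pattern (wavevector along x, \eqn{k_y = 0}); `O_l` / `O_r` for
#' oblique patterns with \eqn{k_y > 0} / \eqn{k_y < 0}; `mixed` when a second
#' distinct mode lies within 3 dB of the dominant one; `none` when the
#' spectral peak is less than `peak_factor` times the background (median
#' spectral magnitude).
#'
#' @param field a [veg_field()], typically a saturated pattern.
#' @param peak_factor peak-to-background factor below which the field is
#'   labelled `none`.
#' @return a one-row tibble: `label`, `kx`, `ky`, `m`, `n`, `amplitude`
#'   (peak magnitude, arbitrary units), `second_ratio`.
#' @export
classify_pattern <- function(field, peak_factor = 5) {
  stopifnot(is_veg_field(field))
  v <- field$values - mean(field$values)
  nx <- nrow(v); ny <- ncol(v)
  if (field$bc_x == "dirichlet") {
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(nx) - 1) / (nx - 1)))
    v <- v * w
  }
  F <- stats::fft(v)
  A <- Mod(F)
  kx_idx <- 0:(nx - 1); kx_idx[kx_idx > nx / 2] <- kx_idx[kx_idx > nx / 2] - nx
  ky_idx <- 0:(ny - 1); ky_idx[ky_idx > ny / 2] <- ky_idx[ky_idx > ny / 2] - ny
  KX <- matrix(kx_idx, nx, ny)
  KY <- matrix(ky_idx, nx, ny, byrow = TRUE)
  half <- KX > 0
  Ah <- A[half]
  kxh <- KX[half]; kyh <- KY[half]
  i1 <- which.max(Ah)
  peak <- Ah[i1]
  bg <- stats::median(Ah)
  if (peak < peak_factor * max(bg, .Machine$double.eps)) {
    return(tibble::tibble(label = "none", kx = NA_real_, ky = NA_real_,
                          m = NA_integer_, n = NA_integer_,
                          amplitude = peak, second_ratio = NA_real_))
  }
  # exclude modes adjacent to the dominant one before ranking the runner-up
  near <- abs(kxh - kxh[i1]) <= 1 & abs(kyh - kyh[i1]) <= 1
  second <- if (any(!near)) max(Ah[!near]) else 0
  ratio <- second / peak
  Lx <- field_Lx(field); Ly <- field_Ly(field)
  kx <- 2 * pi * kxh[i1] / (nx * field$dx)
  ky <- 2 * pi * kyh[i1] / (ny * field$dy)
  label <- if (ratio > 1 / sqrt(2)) "mixed"
  else if (kyh[i1] == 0) "H"
  else if (kyh[i1] > 0) "O_l"
  else "O_r"
  tibble::tibble(label = label, kx = kx, ky = ky,
                 m = as.integer(kxh[i1]), n = as.integer(kyh[i1]),
                 amplitude = peak, second_ratio = ratio)
}

#' Phase speed of a drifting pattern from a space-time record
#'
#' Fits the unwrapped phase of the dominant Fourier mode of a recorded
#' profile against time; the phase speed is `-dphi/dt / k`, positive when
#' crests move toward increasing coordinate.
#'
#' @param traj a `veg_traj` recorded with `rec_stride > 0`.
#' @param along `"x"` (mid-row profile; requires periodic x) or `"y"`
#'   (mid-column profile).
#' @param t_min discard records earlier than this (transient).
#' @return a one-row tibble: `speed`, `omega`, `k`, `mode` (integer index),
#'   `r_squared` of the phase fit.
#' @export
measure_drift_speed <- function(traj, along = c("x", "y"), t_min = 0) {
  along <- match.arg(along)
  stopifnot(inherits(traj, "veg_traj"), !is.null(traj$rec_times))
  prof <- if (along == "x") traj$mid_row else traj$mid_col
  d <- if (along == "x") traj$snapshots[[1]]$dx else traj$snapshots[[1]]$dy
  keep <- traj$rec_times >= t_min
  prof <- prof[, keep, drop = FALSE]
  tt <- traj$rec_times[keep]
  n <- nrow(prof)
  F <- stats::mvfft(prof - matrix(colMeans(prof), n, ncol(prof), byrow = TRUE))
  pw <- rowMeans(Mod(F)^2)[2:floor(n / 2)]
  m <- which.max(pw)                      # dominant positive-frequency mode
  ph <- Arg(F[m + 1, ])
  # unwrap
  dph <- diff(ph)
  dph <- dph - 2 * pi * round(dph / (2 * pi))
  phu <- cumsum(c(ph[1], dph))
  fit <- stats::lm(phu ~ tt)
  omega <- -unname(stats::coef(fit)[2])   # mode ~ exp(i(k z - omega t))
  k <- 2 * pi * m / (n * d)
  tibble::tibble(speed = omega / k, omega = omega, k = k, mode = m,
                 r_squared = summary(fit)$r.squared)
}

# seeded initial condition used by the bifurcation scan: uniform cover plus a
# band seed plus a little noise so competing modes are present
seed_pattern_ic <- function(type = c("H", "O"), b_plus, nx, ny, dx, dy,
                            kx, ky, amp = 0.05, noise = 0.01, seed = 1) {
  type <- match.arg(type)
  x <- (seq_len(nx) - 1) * dx
  y <- (seq_len(ny) - 1) * dy
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  pat <- if (type == "H") amp * sin(kx * X) else amp * cos(kx * X + ky * Y)
  vals <- with_seed_(seed,
    b_plus + pat + matrix(stats::runif(nx * ny, -noise, noise), nx, ny))
  vals <- pmax(vals, 0)
  vals[c(1, nx), ] <- 0
  veg_field(vals, dx = dx, dy = dy, bc_x = "dirichlet")
}

#' Bifurcation scan of the reduced model
#'
#' For each aridity value, integrates the reduced model from an H-seeded and
#' an O-seeded initial condition in a Dirichlet-x / periodic-y box until the
#' pattern amplitude drifts by less than `tol` per unit time over a
#' `t_window` window (or `t_max` is reached, in which case the row is flagged
#' unconverged), then records the modulus of the dominant Fourier amplitude
#' and the pattern label.  Near threshold only horizontal bands survive;
#' deeper in the patterned regime both seedings persist with distinct
#' labels — the coexistence region.
#'
#' @param params a [reduced_params()]; its `eta` is ignored in favour of
#'   `eta_values`.
#' @param eta_values aridity grid.
#' @param Lx,Ly box sizes.
#' @param dx,dy grid spacings.
#' @param dt time step.
#' @param seed_amp,noise_amp seed-pattern and noise amplitudes of the initial
#'   conditions.
#' @param t_chunk integration chunk between convergence checks.
#' @param t_window convergence window (amplitude compared across it).
#' @param t_max maximal integration time per run.
#' @param tol amplitude drift tolerance per unit time.
#' @param seed RNG seed for the initial conditions.
#' @return a tibble with one row per (eta, seeding): `eta`, `seeding`,
#'   `label`, `amplitude` (pattern modulus, field units), `m`, `n`,
#'   `converged`, `t_final`.
#' @export
bifurcation_scan <- function(params, eta_values, Lx = 42.5, Ly = 40,
                             dx = 0.5, dy = dx, dt = 1e-3,
                             seed_amp = 0.1, noise_amp = 0.005,
                             t_chunk = 25, t_window = 50, t_max = 500,
                             tol = 1e-5, seed = 1) {
  stopifnot(inherits(params, "reduced_params"))
  nx <- round(Lx / dx) + 1
  ny <- round(Ly / dy)
  purrr::map_dfr(eta_values, function(eta) {
    p <- reduced_params(eta = eta, kappa = params$kappa, d = params$d,
                        alpha = params$alpha, gamma = params$gamma)
    us <- uniform_states_reduced(eta, params$kappa)
    bp <- us$b[us$branch == "b_plus"]
    if (!isTRUE(us$exists[2]) || bp <= 0)
      return(tibble::tibble(eta = eta, seeding = c("H", "O"),
                            label = "none", amplitude = 0,
                            m = NA_integer_, n = NA_integer_,
                            converged = TRUE, t_final = 0))
    disp <- dispersion(p, bp)
    kx_grid <- pi * seq_len(60) / Lx
    mstar <- which.max(disp$re_fun(kx_grid, 0))
    kx <- pi * mstar / Lx
    ky <- 2 * pi / Ly
    # leave headroom for the transient overshoot near the Dirichlet walls
    dt_eta <- min(dt, 0.6 * reduced_dt_bound(p, dx, bp + seed_amp + noise_amp))
    purrr::map_dfr(c("H", "O"), function(sd_type) {
      b <- seed_pattern_ic(sd_type, bp, nx, ny, dx, dy, kx, ky,
                           amp = seed_amp, noise = noise_amp, seed = seed)
      amp_of <- function(f) pattern_modulus(f)
      t_now <- 0
      hist_t <- 0
      hist_a <- amp_of(b)
      converged <- FALSE
      while (t_now < t_max) {
        tr <- simulate_reduced(p, b, dt = dt_eta,
                               n_steps = round(t_chunk / dt_eta))
        b <- final_state(tr)
        t_now <- t_now + t_chunk
        hist_t <- c(hist_t, t_now)
        hist_a <- c(hist_a, amp_of(b))
        iwin <- which(hist_t <= t_now - t_window)
        if (length(iwin) > 0) {
          a_then <- hist_a[max(iwin)]
          drift <- abs(utils::tail(hist_a, 1) - a_then) /
            (t_now - hist_t[max(iwin)])
          if (drift < tol) { converged <- TRUE; break }
        }
      }
      cl <- classify_pattern(b)
      tibble::tibble(eta = eta, seeding = sd_type,
                     label = cl$label,
                     amplitude = pattern_modulus(b),
                     m = cl$m, n = cl$n,
                     converged = converged, t_final = t_now)
    })
  })
}

# modulus of the dominant Fourier amplitude, normalized to field units
pattern_modulus <- function(field) {
  v <- field$values - mean(field$values)
  nx <- nrow(v); ny <- ncol(v)
  if (field$bc_x == "dirichlet") {
    # interior window away from the Dirichlet boundary layers
    i0 <- max(2, round(nx * 0.15)); i1 <- min(nx - 1, round(nx * 0.85))
    v <- v[i0:i1, , drop = FALSE]
    v <- v - mean(v)
    nx <- nrow(v)
  }
  A <- Mod(stats::fft(v)) / (nx * ny)
  kx_idx <- 0:(nx - 1); kx_idx[kx_idx > nx / 2] <- kx_idx[kx_idx > nx / 2] - nx
  2 * max(A[kx_idx > 0, , drop = FALSE])
}
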