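#' Parameters of the nonlocal interaction-redistribution model
#'
#' The model evolves a biomass density b(r, t) under logistic growth enhanced
#' by a facilitative feedback, death enhanced by a competitive feedback, and
#' seed diffusion:
#' \deqn{\partial_t b = b(1-b)M_f - \mu b M_c + D \nabla^2 b}
#' with \eqn{M_i = \exp[\chi_i \int \phi_i(r, r') b(r') dr']} and shifted
#' anisotropic Gaussian influence kernels \eqn{\phi_i}.  Nonzero kernel
#' offsets make the influence nonreciprocal
#' (\eqn{\phi(r, r') \ne \phi(r', r)}), the signature of directional fog
#' flow, and set the patterns in motion.
#'
#' @param mu aridity (mortality/birth balance) parameter, >= 0.
#' @param chi_f,chi_c facilitation and competition intensities, >= 0.
#' @param D seed-dispersion diffusivity, >= 0.
#' @param x0f,x0c,y0f,y0c kernel offsets (lengths); nonzero x offsets break
#'   reciprocity along the fog direction.
#' @param lfx,lfy,lcx,lcy kernel widths (> 0).
#' @return an object of class `nonlocal_params`.
#' @export
#' @examples
#' p <- nonlocal_params(mu = 0.98, chi_f = 2.1, chi_c = 1.2, D = 0.2,
#'                      x0f = 0.5, x0c = -0.2, lfx = 0.9, lfy = 0.9,
#'                      lcx = 5, lcy = 3.5)
nonlocal_params <- function(mu, chi_f, chi_c, D, x0f = 0, x0c = 0,
                            y0f = 0, y0c = 0, lfx, lfy = lfx, lcx, lcy = lcx) {
  if (any(c(lfx, lfy, lcx, lcy) <= 0)) stop("all kernel widths must be > 0")
  if (mu < 0) stop("mu must be >= 0")
  if (D < 0) stop("D must be >= 0")
  if (chi_f < 0 || chi_c < 0) stop("feedback intensities must be >= 0")
  structure(
    list(mu = mu, chi_f = chi_f, chi_c = chi_c, D = D,
         x0f = x0f, x0c = x0c, y0f = y0f, y0c = y0c,
         lfx = lfx, lfy = lfy, lcx = lcx, lcy = lcy),
    class = "nonlocal_params")
}

# offsets/widths of one kernel
kernel_pars <- function(params, which) {
  if (which == "facilitation")
    list(x0 = params$x0f, y0 = params$y0f, lx = params$lfx, ly = params$lfy)
  else
    list(x0 = params$x0c, y0 = params$y0c, lx = params$lcx, ly = params$lcy)
}

# FFT-ordered lag coordinates for an n-point axis of spacing d
lag_coords <- function(n, d) {
  i <- seq_len(n) - 1
  d * ifelse(i <= n / 2, i, i - n)
}

#' Discretize an influence kernel on a grid
#'
#' Samples the shifted anisotropic Gaussian
#' \deqn{\phi(s) = \exp[-(s_x - x_0)^2 / 2 l_x^2 - (s_y - y_0)^2 / 2 l_y^2]
#'   / (2 \pi l_x l_y)}
#' on the wrapped lag grid of a periodic box.  The discrete mass
#' `sum(values) * dx * dy` must land within 1e-3 of 1 (otherwise the grid is
#' too small for the stated widths and an error names the violated extent);
#' the sampled kernel is then renormalized to unit discrete mass so that
#' uniform fields are exact fixed points of the discretized feedback.
#'
#' @param params a [nonlocal_params()].
#' @param which `"facilitation"` or `"competition"`.
#' @param grid list with `nx`, `ny`, `dx`, `dy`.
#' @return an object of class `veg_kernel` with elements `values` (matrix in
#'   FFT lag order), `khat` (its DFT), `grid`, `mass` (pre-normalization
#'   discrete mass) and `which`.
#' @export
build_kernel <- function(params, which = c("facilitation", "competition"),
                         grid) {
  which <- match.arg(which)
  stopifnot(all(c("nx", "ny", "dx", "dy") %in% names(grid)))
  kp <- kernel_pars(params, which)
  ext_x <- grid$nx * grid$dx
  ext_y <- grid$ny * grid$dy
  if (ext_x < 6 * kp$lx)
    stop(sprintf("grid extent in x (%.3g) is smaller than 6 kernel widths (%.3g)",
                 ext_x, 6 * kp$lx))
  if (ext_y < 6 * kp$ly)
    stop(sprintf("grid extent in y (%.3g) is smaller than 6 kernel widths (%.3g)",
                 ext_y, 6 * kp$ly))
  sx <- lag_coords(grid$nx, grid$dx)
  sy <- lag_coords(grid$ny, grid$dy)
  K <- outer(
    exp(-(sx - kp$x0)^2 / (2 * kp$lx^2)),
    exp(-(sy - kp$y0)^2 / (2 * kp$ly^2))) / (2 * pi * kp$lx * kp$ly)
  mass <- sum(K) * grid$dx * grid$dy
  if (abs(mass - 1) > 1e-3)
    stop(sprintf(
      "discrete kernel mass %.6f deviates from 1 by more than 1e-3; grid extent (%.3g x %.3g) too small for widths (%g, %g)",
      mass, ext_x, ext_y, kp$lx, kp$ly))
  K <- K / mass
  structure(
    list(values = K, khat = stats::fft(K), grid = grid, mass = mass,
         which = which, x0 = kp$x0, y0 = kp$y0, lx = kp$lx, ly = kp$ly),
    class = "veg_kernel")
}

#' @export
print.veg_kernel <- function(x, ...) {
  cat(sprintf(
    "<veg_kernel> %s, offsets (%g, %g), widths (%g, %g), %d x %d lag grid, raw mass %.6f\n",
    x$which, x$x0, x$y0, x$lx, x$ly, x$grid$nx, x$grid$ny, x$mass))
  invisible(x)
}

# convolution grid for a field: identical for periodic x, zero-padded in x
# for Dirichlet (bare ground beyond the walls)
conv_grid <- function(b, params) {
  nx <- nrow(b$values); ny <- ncol(b$values)
  if (b$bc_x == "dirichlet") {
    support <- ceiling(6 * max(params$lfx, params$lcx) / b$dx)
    nx <- stats::nextn(nx + support, c(2, 3, 5))
  }
  list(nx = nx, ny = ny, dx = b$dx, dy = b$dy)
}

#' Nonlocal feedback field
#'
#' Evaluates \eqn{M = \exp(\chi \, (\phi * b))} where the kernel-weighted
#' integral uses periodic wrap in y and, for Dirichlet x boundaries, treats
#' everything beyond the walls as bare ground (zero padding in x).  The
#' kernel must have been built (via [build_kernel()]) on a lag grid at least
#' as large as the field in x; [rhs_nonlocal()] and [simulate_nonlocal()]
#' arrange this automatically.
#'
#' @param b a [veg_field()].
#' @param kernel a `veg_kernel` from [build_kernel()].
#' @param chi feedback intensity multiplying the integral.
#' @return a [veg_field()] of feedback values M.
#' @export
nonlocal_feedback <- function(b, kernel, chi) {
  stopifnot(is_veg_field(b), inherits(kernel, "veg_kernel"))
  g <- kernel$grid
  if (g$ny != ncol(b$values) || g$dx != b$dx || g$dy != b$dy)
    stop("kernel grid does not match the field grid")
  if (g$nx < nrow(b$values))
    stop("kernel lag grid is smaller than the field in x")
  if (b$bc_x == "periodic" && g$nx != nrow(b$values))
    stop("periodic-x fields need a kernel on the unpadded grid")
  conv <- conv_fft_cpp(b$values, kernel$khat, b$dx * b$dy)
  if (chi != 0 && max(abs(chi * conv)) > 50)
    stop("feedback exponent magnitude exceeds 50: parameters out of the intended regime")
  veg_field(exp(chi * conv), dx = b$dx, dy = b$dy,
            bc_x = b$bc_x, bc_y = b$bc_y)
}

#' Time derivative of the nonlocal model
#'
#' @param b a [veg_field()] of biomass.
#' @param params a [nonlocal_params()].
#' @return a [veg_field()] holding \eqn{\partial_t b}.  Dirichlet boundary
#'   columns carry zero derivative (they are pinned to bare ground).
#' @export
rhs_nonlocal <- function(b, params) {
  stopifnot(is_veg_field(b), inherits(params, "nonlocal_params"))
  if (!all(is.finite(b$values))) stop("non-finite values in input field")
  g <- conv_grid(b, params)
  Kf <- build_kernel(params, "facilitation", g)
  Kc <- build_kernel(params, "competition", g)
  out <- rhs_nonlocal_cpp(b$values, Kf$khat, Kc$khat,
                          params$chi_f, params$chi_c, params$mu, params$D,
                          b$dx, b$dy, b$bc_x == "dirichlet")
  veg_field(out, dx = b$dx, dy = b$dy, bc_x = b$bc_x, bc_y = b$bc_y)
}

#' Uniform steady states of the nonlocal model
#'
#' With normalized kernels a uniform biomass b reduces the model to
#' \eqn{b[(1-b)e^{\chi_f b} - \mu e^{\chi_c b}] = 0}: the bare state b = 0,
#' plus any root of \eqn{(1-b)e^{(\chi_f-\chi_c) b} = \mu} in (0, 1], found
#' by bracketed root-finding on a fine grid.
#'
#' @param params a [nonlocal_params()] (requires `mu > 0`).
#' @param n_scan number of scan points used to bracket roots.
#' @return a tibble with columns `b` and `branch` (`"bare"` or
#'   `"vegetated"`).  The bare state is always present; the vegetated set may
#'   be empty when aridity is too high.
#' @export
#' @examples
#' p <- nonlocal_params(mu = 0.98, chi_f = 2.1, chi_c = 1.2, D = 0.2,
#'                      lfx = 0.9, lcx = 5)
#' uniform_states_nonlocal(p)
uniform_states_nonlocal <- function(params, n_scan = 2000) {
  stopifnot(inherits(params, "nonlocal_params"))
  if (params$mu <= 0) stop("mu must be > 0")
  dchi <- params$chi_f - params$chi_c
  g <- function(b) (1 - b) * exp(dchi * b) - params$mu
  bs <- seq(0, 1, length.out = n_scan)
  gv <- g(bs)
  roots <- numeric(0)
  for (i in seq_len(n_scan - 1)) {
    if (gv[i] == 0 && bs[i] > 0) roots <- c(roots, bs[i])
    else if (gv[i] * gv[i + 1] < 0)
      roots <- c(roots, stats::uniroot(g, c(bs[i], bs[i + 1]),
                                       tol = 1e-12)$root)
  }
  roots <- roots[roots > 1e-12]
  tibble::tibble(
    b = c(0, roots),
    branch = c("bare", rep("vegetated", length(roots))))
}

#' Simulate the nonlocal model
#'
#' Explicit RK4 time stepping of [rhs_nonlocal()] with the kernel
#' convolutions evaluated by FFT on a zero-padded array (Dirichlet x) or on
#' the box itself (periodic x).  The Dirichlet columns are held at zero.
#'
#' @param params a [nonlocal_params()].
#' @param b0 initial [veg_field()].
#' @param dt time step; must satisfy the explicit stability bound reported by
#'   [nonlocal_dt_bound()].
#' @param n_steps number of steps.
#' @param snap_stride store a snapshot every this many steps (0 = only first
#'   and last).
#' @param rec_stride store the mid-column profile b(x_mid, y, t) and
#'   mid-row profile b(x, y_mid, t) every this many steps (0 = none).
#' @return a `veg_traj` object: list with `snapshots` (list of
#'   [veg_field()]), `snap_times`, `mid_col`, `mid_row`, `rec_times`,
#'   `params`, `dt`.
#' @export
simulate_nonlocal <- function(params, b0, dt = 0.04, n_steps,
                              snap_stride = 0, rec_stride = 0) {
  stopifnot(is_veg_field(b0), inherits(params, "nonlocal_params"))
  bound <- nonlocal_dt_bound(params, b0$dx, b0$dy)
  if (dt > bound)
    stop(sprintf("dt = %g exceeds the stability bound %.3g", dt, bound))
  g <- conv_grid(b0, params)
  Kf <- build_kernel(params, "facilitation", g)
  Kc <- build_kernel(params, "competition", g)
  res <- simulate_nonlocal_cpp(b0$values, Kf$khat, Kc$khat,
                               params$chi_f, params$chi_c, params$mu,
                               params$D, b0$dx, b0$dy, dt, n_steps,
                               snap_stride, rec_stride,
                               b0$bc_x == "dirichlet")
  make_traj(res, b0, dt, "nonlocal", params)
}

#' Explicit time-step bound for the nonlocal model
#'
#' Diffusive CFL limit for the RK4 scheme plus a conservative reaction bound;
#' the default step used by [simulate_nonlocal()] should stay below it.
#'
#' @param params a [nonlocal_params()].
#' @param dx,dy grid spacings.
#' @return maximal admissible dt.
#' @export
nonlocal_dt_bound <- function(params, dx, dy = dx) {
  diff_rate <- 4 * params$D * (1 / dx^2 + 1 / dy^2)
  # crude reaction-rate scale: growth/death factors of order exp(chi)
  react <- 1 + params$mu * exp(min(params$chi_c, 5))
  2.5 / (diff_rate + react)
}

# shared trajectory wrapper for both simulators
make_traj <- function(res, b0, dt, model, params) {
  snaps <- lapply(res$snapshots, function(m)
    veg_field(m, dx = b0$dx, dy = b0$dy, bc_x = b0$bc_x, bc_y = b0$bc_y))
  structure(
    list(snapshots = snaps,
         snap_times = res$snap_steps * dt,
         mid_col = res$mid_col,
         mid_row = res$mid_row,
         rec_times = if (!is.null(res$rec_steps)) res$rec_steps * dt,
         dt = dt, model = model, params = params),
    class = "veg_traj")
}

#' @export
print.veg_traj <- function(x, ...) {
  cat(sprintf("<veg_traj> %s model, %d snapshots, t in [0, %g]\n",
              x$model, length(x$snapshots), max(x$snap_times)))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj a `veg_traj`.
#' @return the last snapshot, a [veg_field()].
#' @export
final_state <- function(traj) {
  traj$snapshots[[length(traj$snapshots)]]
}
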