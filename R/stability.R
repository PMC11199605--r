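#' Linear dispersion relation about a uniform vegetated state
#'
#' Linearizing the reduced model about a uniform steady state \eqn{b_s} with
#' perturbations \eqn{\propto e^{\lambda t + i k \cdot r}} gives the closed
#' form
#' \deqn{\mathrm{Re}\,\lambda = b_s(\kappa - b_s) - d(k_x^2 + k_y^2)
#'   + b_s(\gamma k_x^2 - k_x^4), \qquad
#'   \mathrm{Im}\,\lambda = -b_s \alpha k_x.}
#' The real part is even in both wavenumber components and independent of the
#' nonreciprocity \eqn{\alpha}; the odd imaginary part is what makes the
#' bands travel.
#'
#' @param params a [reduced_params()].
#' @param b_s a uniform steady state of the reduced model; validated by
#'   substitution (residual must be below 1e-8).
#' @return an object of class `veg_dispersion`: list with `re_fun(kx, ky)`,
#'   `im_fun(kx, ky)`, `params`, `b_s`, and the fastest-growing wavenumber
#'   `k_max`, growth `re_max` and frequency `omega_max` at the current
#'   parameters.
#' @export
#' @examples
#' p <- reduced_params(eta = -0.219, kappa = 0.3, d = 0.3, gamma = 2)
#' bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
#' disp <- dispersion(p, bp)
#' glance(disp)
dispersion <- function(params, b_s) {
  stopifnot(inherits(params, "reduced_params"))
  resid <- abs(-params$eta * b_s + params$kappa * b_s^2 - b_s^3 / 2)
  if (resid > 1e-8)
    stop(sprintf("b_s = %g is not a uniform steady state (residual %.2e)",
                 b_s, resid))
  re_fun <- function(kx, ky = 0) {
    b_s * (params$kappa - b_s) - params$d * (kx^2 + ky^2) +
      b_s * (params$gamma * kx^2 - kx^4)
  }
  im_fun <- function(kx, ky = 0) -b_s * params$alpha * kx
  # fastest-growing wavenumber lies on the k_y = 0 axis (the k_y^2 term only
  # damps); closed-form maximizer of Re over k_x^2
  kx2 <- (b_s * params$gamma - params$d) / (2 * b_s)
  k_max <- if (kx2 > 0) sqrt(kx2) else 0
  structure(
    list(params = params, b_s = b_s, re_fun = re_fun, im_fun = im_fun,
         k_max = k_max, re_max = re_fun(k_max, 0),
         omega_max = im_fun(k_max, 0)),
    class = "veg_dispersion")
}

#' @export
print.veg_dispersion <- function(x, ...) {
  cat(sprintf(
    "<veg_dispersion> b_s = %.5g; max Re lambda = %.5g at k = %.5g (omega = %.5g)\n",
    x$b_s, x$re_max, x$k_max, x$omega_max))
  invisible(x)
}

#' @describeIn dispersion evaluate the growth rate on a wavevector grid.
#' @param x a `veg_dispersion`.
#' @param kx,ky wavevector grids (outer product is evaluated).
#' @param ... unused.
#' @method tidy veg_dispersion
#' @export
tidy.veg_dispersion <- function(x, kx = seq(0, 2, by = 0.05), ky = 0, ...) {
  g <- expand.grid(kx = kx, ky = ky)
  tibble::tibble(kx = g$kx, ky = g$ky,
                 re_lambda = x$re_fun(g$kx, g$ky),
                 im_lambda = x$im_fun(g$kx, g$ky))
}

#' @describeIn dispersion one-row summary (base state, critical quantities).
#' @method glance veg_dispersion
#' @export
glance.veg_dispersion <- function(x, ...) {
  tibble::tibble(b_s = x$b_s, k_max = x$k_max, re_max = x$re_max,
                 omega_max = x$omega_max,
                 phase_speed = x$b_s * x$params$alpha)
}

#' Pattern-forming threshold of the reduced model
#'
#' Solves the two marginality conditions
#' \eqn{\partial_k \mathrm{Re}\lambda = 0} and
#' \eqn{\mathrm{Re}\lambda(k_c) = 0} simultaneously, treating the aridity
#' \eqn{\eta} as the control parameter.  Along the cover branch
#' \eqn{b_+(\eta)} the maximizer has the closed form
#' \eqn{k_c^2 = (b_+\gamma - d) / (2 b_+)}, so the threshold reduces to a
#' scalar root-find in \eqn{\eta}.
#'
#' @param kappa,d,gamma,alpha reduced-model parameters (alpha does not enter
#'   the real part and is accepted only for interface symmetry).
#' @param eta_bracket search bracket for the threshold; the default spans
#'   from deep below threshold up to just below the fold
#'   \eqn{\eta = \kappa^2/2} of the cover branch.
#' @param n_scan scan resolution used to bracket the sign change.
#' @return a one-row tibble: `eta_c`, `k_c`, `b_plus` (cover state at
#'   threshold).  Residuals of both defining conditions are below 1e-10.
#' @export
#' @examples
#' critical_point(kappa = 0.3, d = 0.3, gamma = 2)
critical_point <- function(kappa, d, gamma, alpha = 0,
                           eta_bracket = NULL, n_scan = 400) {
  if (is.null(eta_bracket))
    eta_bracket <- c(-10 - kappa^2, kappa^2 / 2 - 1e-9)
  growth_max <- function(eta) {
    disc <- kappa^2 - 2 * eta
    if (disc < 0) return(NA_real_)
    b <- kappa + sqrt(disc)
    kx2 <- (b * gamma - d) / (2 * b)
    if (!is.finite(kx2) || kx2 <= 0) return(-Inf)  # no interior maximum
    b * (kappa - b) - d * kx2 + b * (gamma * kx2 - kx2^2)
  }
  etas <- seq(eta_bracket[1], eta_bracket[2], length.out = n_scan)
  gv <- vapply(etas, growth_max, numeric(1))
  ok <- is.finite(gv)
  idx <- which(ok[-length(ok)] & ok[-1] & gv[-length(gv)] * gv[-1] < 0)
  if (length(idx) == 0)
    stop("no pattern-forming threshold in range")
  i <- idx[1]
  eta_c <- stats::uniroot(growth_max, c(etas[i], etas[i + 1]),
                          tol = 1e-14)$root
  b <- kappa + sqrt(kappa^2 - 2 * eta_c)
  k_c <- sqrt((b * gamma - d) / (2 * b))
  tibble::tibble(eta_c = eta_c, k_c = k_c, b_plus = b)
}

#' Discrete modes of a finite mixed-boundary box
#'
#' Dirichlet walls in x restrict the patterns to sine modes
#' \eqn{k_x = \pi m / L_x} (m >= 1) while the periodic y direction admits
#' \eqn{k_y = 2\pi n / L_y} for integer n.  Each mode is evaluated on the
#' closed-form dispersion relation and labelled `H` (n = 0), `O_l` (n > 0)
#' or `O_r` (n < 0).
#'
#' @param params a [reduced_params()].
#' @param b_s uniform base state.
#' @param Lx,Ly box sizes (> 0).
#' @param m_max,n_max mode ranges; `m_max` defaults to covering twice the
#'   fastest-growing wavenumber, `n_max` to the same physical extent in y.
#' @return a `veg_modeset`: a tibble with `m`, `n`, `kx`, `ky`,
#'   `re_lambda`, `im_lambda`, `unstable`, `label`, carrying the box sizes as
#'   attributes.
#' @export
#' @examples
#' p <- reduced_params(eta = -0.219, kappa = 0.3, d = 0.3, gamma = 2)
#' bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
#' ms <- enumerate_modes(p, bp, Lx = 85, Ly = 100)
#' sum(ms$unstable)
enumerate_modes <- function(params, b_s, Lx, Ly, m_max = NULL, n_max = NULL) {
  if (Lx <= 0 || Ly <= 0) stop("box sizes must be positive")
  disp <- dispersion(params, b_s)
  k_ref <- max(disp$k_max, pi / Lx)
  if (is.null(m_max)) m_max <- max(10, ceiling(2 * k_ref * Lx / pi))
  if (is.null(n_max)) n_max <- max(5, ceiling(2 * k_ref * Ly / (2 * pi)))
  g <- expand.grid(m = seq_len(m_max), n = -n_max:n_max)
  kx <- pi * g$m / Lx
  ky <- 2 * pi * g$n / Ly
  re <- disp$re_fun(kx, ky)
  im <- disp$im_fun(kx, ky)
  out <- tibble::tibble(
    m = g$m, n = g$n, kx = kx, ky = ky,
    re_lambda = re, im_lambda = im,
    unstable = re > 0,
    label = dplyr::case_when(g$n == 0 ~ "H", g$n > 0 ~ "O_l", TRUE ~ "O_r"))
  out <- dplyr::arrange(out, .data$m, .data$n)
  attr(out, "Lx") <- Lx
  attr(out, "Ly") <- Ly
  attr(out, "b_s") <- b_s
  attr(out, "params") <- params
  class(out) <- c("veg_modeset", class(out))
  out
}

#' Band drift speed from the dispersion relation
#'
#' The group-velocity coefficient is \eqn{\partial \mathrm{Im}\lambda /
#' \partial k_x = -b_s \alpha} (independent of k), and the phase speed of the
#' critical mode is \eqn{-\mathrm{Im}\lambda(k_c)/k_c = b_s \alpha}: bands
#' are motionless in the reciprocal case \eqn{\alpha = 0} and reverse
#' direction with the sign of \eqn{\alpha}.
#'
#' @param params a [reduced_params()].
#' @param b_s uniform base state.
#' @return a one-row tibble: `phase_speed`, `dIm_dkx`.
#' @export
drift_speed <- function(params, b_s) {
  stopifnot(inherits(params, "reduced_params"))
  tibble::tibble(phase_speed = b_s * params$alpha,
                 dIm_dkx = -b_s * params$alpha)
}

#' Box-size window admitting a single oblique pair
#'
#' Reports the maximal unstable transverse wavenumber and the window of
#' periodic lengths `Ly` for which exactly the n = +/-1 oblique rows fit
#' inside the unstable ellipse, together with the unstable `k_x` interval on
#' the horizontal axis (useful for choosing `Lx`).
#'
#' @param params a [reduced_params()].
#' @param b_s uniform base state.
#' @return a one-row tibble: `ky_max`, `Ly_min`, `Ly_max`, `kx_lo`, `kx_hi`.
#'   `ky_max = 0` means no unstable modes at all.
#' @export
admissible_box <- function(params, b_s) {
  disp <- dispersion(params, b_s)
  # ky^2 on the neutral ellipse as a function of kx
  ky2 <- function(kx) disp$re_fun(kx, 0) / params$d
  opt <- stats::optimize(function(kx) -ky2(kx), c(0, 3 * max(disp$k_max, 1)))
  ky_max2 <- -opt$objective
  if (ky_max2 <= 0)
    return(tibble::tibble(ky_max = 0, Ly_min = NA_real_, Ly_max = NA_real_,
                          kx_lo = NA_real_, kx_hi = NA_real_))
  ky_max <- sqrt(ky_max2)
  # unstable kx interval at ky = 0
  f <- function(kx) disp$re_fun(kx, 0)
  kpk <- disp$k_max
  kx_lo <- if (f(1e-9) < 0) stats::uniroot(f, c(1e-9, kpk), tol = 1e-12)$root else 0
  up <- kpk
  while (f(up) > 0) up <- up * 1.5
  kx_hi <- stats::uniroot(f, c(kpk, up), tol = 1e-12)$root
  tibble::tibble(ky_max = ky_max,
                 Ly_min = 2 * pi / ky_max,
                 Ly_max = 4 * pi / ky_max,
                 kx_lo = kx_lo, kx_hi = kx_hi)
}
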