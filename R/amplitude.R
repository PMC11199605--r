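#' Parameters of the three-mode amplitude equations
#'
#' Near the pattern-forming threshold the band envelope A obeys a
#' Ginzburg-Landau equation
#' \deqn{\partial_t A = \hat\mu A - (1+i\beta)|A|^2 A + \nabla^2 A
#'   - \hat\alpha \partial_x A,}
#' and truncating A onto a horizontal mode plus a symmetric pair of oblique
#' modes, \eqn{A = H + O_l e^{i\Delta k y} + O_r e^{-i\Delta k y}}, yields
#' three coupled amplitude equations (see [amplitude_rhs()]).
#'
#' @param mu_hat distance to threshold (critical-mode growth rate).
#' @param beta nonlinear dispersion coefficient.
#' @param alpha_hat group-velocity coefficient (drops out of the truncated
#'   equations because the ansatz carries no x dependence).
#' @param delta_k transverse wavenumber offset of the oblique modes (>= 0);
#'   of order \eqn{\sqrt{\hat\mu}} near threshold.
#' @return an object of class `amplitude_params`.
#' @export
amplitude_params <- function(mu_hat, beta = 0, alpha_hat = 0, delta_k) {
  vals <- c(mu_hat, beta, alpha_hat, delta_k)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  if (delta_k < 0) stop("delta_k must be >= 0")
  structure(list(mu_hat = mu_hat, beta = beta, alpha_hat = alpha_hat,
                 delta_k = delta_k),
            class = "amplitude_params")
}

#' Convenience mapping from the linear analysis
#'
#' Sets \eqn{\hat\mu} to the maximal growth rate and \eqn{\hat\alpha} to the
#' group-velocity coefficient \eqn{-b_s\alpha} of a [dispersion()] result;
#' the nonlinear dispersion \eqn{\beta} and the oblique offset
#' \eqn{\Delta k} are free inputs of the truncation.
#'
#' @param disp a `veg_dispersion`.
#' @param beta nonlinear dispersion.
#' @param delta_k transverse offset.
#' @return an [amplitude_params()].
#' @export
amplitude_from_linear <- function(disp, beta = 0, delta_k) {
  stopifnot(inherits(disp, "veg_dispersion"))
  amplitude_params(mu_hat = disp$re_max, beta = beta,
                   alpha_hat = -disp$b_s * disp$params$alpha,
                   delta_k = delta_k)
}

#' Right-hand side of the three-mode amplitude equations
#'
#' \deqn{\dot H = \hat\mu H - (1+i\beta)H(|H|^2 + 2(|O_l|^2+|O_r|^2))
#'   - 2(1+i\beta) O_l O_r \bar H}
#' \deqn{\dot O_l = (\hat\mu - \Delta k^2) O_l
#'   - (1+i\beta)O_l(2|H|^2 + |O_l|^2 + 2|O_r|^2) - (1+i\beta)H^2 \bar O_r}
#' \deqn{\dot O_r = (\hat\mu - \Delta k^2) O_r
#'   - (1+i\beta)O_r(2(|H|^2+|O_l|^2) + |O_r|^2) - (1+i\beta)H^2 \bar O_l}
#'
#' @param state complex vector `c(H, O_l, O_r)`.
#' @param params an [amplitude_params()].
#' @return complex vector of time derivatives.
#' @export
amplitude_rhs <- function(state, params) {
  stopifnot(inherits(params, "amplitude_params"), length(state) == 3)
  H <- state[1]; Ol <- state[2]; Or <- state[3]
  cb <- 1 + 1i * params$beta
  mu <- params$mu_hat
  dk2 <- params$delta_k^2
  aH <- Mod(H)^2; aL <- Mod(Ol)^2; aR <- Mod(Or)^2
  c(
    mu * H - cb * H * (aH + 2 * (aL + aR)) - 2 * cb * Ol * Or * Conj(H),
    (mu - dk2) * Ol - cb * Ol * (2 * aH + aL + 2 * aR) - cb * H^2 * Conj(Or),
    (mu - dk2) * Or - cb * Or * (2 * (aH + aL) + aR) - cb * H^2 * Conj(Ol))
}

#' Potential of the amplitude equations at beta = 0
#'
#' Without nonlinear dispersion the truncated system is a gradient flow of
#' \deqn{V = -\hat\mu|H|^2 - (\hat\mu-\Delta k^2)(|O_l|^2+|O_r|^2)
#'   + \tfrac12(|H|^4+|O_l|^4+|O_r|^4)
#'   + 2(|H|^2|O_l|^2+|H|^2|O_r|^2+|O_l|^2|O_r|^2)
#'   + (H^2\bar O_l\bar O_r + c.c.)}
#' so V is non-increasing along every trajectory.
#'
#' @param state complex vector `c(H, O_l, O_r)`.
#' @param params an [amplitude_params()].
#' @return the potential value (numeric).
#' @export
amplitude_potential <- function(state, params) {
  H <- state[1]; Ol <- state[2]; Or <- state[3]
  aH <- Mod(H)^2; aL <- Mod(Ol)^2; aR <- Mod(Or)^2
  mu <- params$mu_hat; dk2 <- params$delta_k^2
  -mu * aH - (mu - dk2) * (aL + aR) +
    0.5 * (aH^2 + aL^2 + aR^2) +
    2 * (aH * aL + aH * aR + aL * aR) +
    2 * Re(H^2 * Conj(Ol) * Conj(Or))
}

# realify <-> complexify helpers for the 6-dimensional real system
amp_real <- function(z) c(Re(z[1]), Im(z[1]), Re(z[2]), Im(z[2]),
                          Re(z[3]), Im(z[3]))
amp_cplx <- function(v) complex(real = v[c(1, 3, 5)],
                                imaginary = v[c(2, 4, 6)])

# Stability of a (relative) equilibrium of the amplitude equations.
#
# With beta != 0 equilibria rotate rigidly within the phase symmetry group
# (H, O_l, O_r) -> (H e^{i th}, O_l e^{i th_l}, O_r e^{i th_r}),
# 2 th = th_l + th_r.  In a frame co-rotating at the solution's own phase
# velocities the state is a genuine fixed point; the frame change shifts
# eigenvalues by purely imaginary amounts, leaving Re(lambda) — the
# stability — intact.  Gauge (global-phase) directions give exactly neutral
# eigenvalues and are reported, not counted as instabilities.
amp_stability <- function(z, params, tol_neutral = 1e-7) {
  f <- amplitude_rhs(z, params)
  mods <- Mod(z)
  omega <- numeric(3)
  known <- mods > 1e-10
  omega[known] <- Im(Conj(z[known]) * f[known]) / mods[known]^2
  if (!known[1] && known[2] && known[3])
    omega[1] <- (omega[2] + omega[3]) / 2
  if (known[1]) {
    if (!known[2] && !known[3]) omega[2] <- omega[3] <- omega[1]
    else if (known[2] && !known[3]) omega[3] <- 2 * omega[1] - omega[2]
    else if (!known[2] && known[3]) omega[2] <- 2 * omega[1] - omega[3]
  } else if (!known[2] && known[3]) {
    omega[2] <- omega[3]; omega[1] <- omega[3]
  } else if (known[2] && !known[3]) {
    omega[3] <- omega[2]; omega[1] <- omega[2]
  }
  v0 <- amp_real(z)
  F6 <- function(v) amp_real(amplitude_rhs(amp_cplx(v), params))
  J <- matrix(0, 6, 6)
  h <- 1e-6 * max(1, max(abs(v0)))
  for (k in 1:6) {
    e <- numeric(6); e[k] <- h
    J[, k] <- (F6(v0 + e) - F6(v0 - e)) / (2 * h)
  }
  # co-rotating frame correction: d/dt u = F(u) - i omega o u
  for (j in 1:3) {
    idx <- c(2 * j - 1, 2 * j)
    J[idx, idx] <- J[idx, idx] + matrix(c(0, -omega[j], omega[j], 0), 2, 2)
  }
  ev <- eigen(J, only.values = TRUE)$values
  neutral <- abs(Re(ev)) < tol_neutral
  max_re <- if (all(neutral)) 0 else max(Re(ev[!neutral]))
  list(stable = max_re < 0, max_re = max_re, n_neutral = sum(neutral),
       eigenvalues = ev)
}

# relative-equilibrium residual for the symmetric mixed state
# (R_H, R_O, psi): modulus derivatives and the relative-phase drift
mixed_residual <- function(p3, params) {
  RH <- p3[1]; RO <- p3[2]; psi <- p3[3]
  z <- c(RH + 0i, RO * exp(1i * psi / 2), RO * exp(1i * psi / 2))
  f <- amplitude_rhs(z, params)
  mods <- pmax(Mod(z), 1e-12)
  dmod <- Re(Conj(z) * f) / mods
  om <- Im(Conj(z) * f) / mods^2
  c(dmod[1], dmod[2], om[2] + om[3] - 2 * om[1])
}

solve_mixed <- function(params, start, max_iter = 60, tol = 1e-12) {
  p <- start
  for (it in seq_len(max_iter)) {
    r <- mixed_residual(p, params)
    if (max(abs(r)) < tol) return(p)
    J <- matrix(0, 3, 3)
    h <- 1e-7
    for (k in 1:3) {
      e <- numeric(3); e[k] <- h
      J[, k] <- (mixed_residual(p + e, params) -
                   mixed_residual(p - e, params)) / (2 * h)
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    # damped Newton with step halving
    lam <- 1
    repeat {
      pn <- p - lam * step
      if (all(is.finite(pn)) &&
          sum(mixed_residual(pn, params)^2) <= sum(r^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    p <- p - lam * step
  }
  if (max(abs(mixed_residual(p, params))) < 1e-8) p else NULL
}

#' Equilibrium branches of the amplitude equations
#'
#' Assembles, for each value of \eqn{\hat\mu}, the trivial state, the
#' horizontal branch \eqn{|H| = \sqrt{\hat\mu}} (\eqn{\hat\mu > 0}), the
#' single-oblique branch \eqn{|O| = \sqrt{\hat\mu - \Delta k^2}}, the
#' symmetric oblique pair \eqn{|O_{l,r}|^2 = (\hat\mu - \Delta k^2)/3}, and
#' the mixed branch (numerical root-finding on the modulus-phase reduced
#' system, continued naturally in \eqn{\hat\mu}), each with stability from
#' the Jacobian of the 6-dimensional real system (gauge phase directions
#' neutral).  The resulting diagram shows the horizontal pattern arising
#' supercritically at \eqn{\hat\mu = 0}, the oblique branch appearing —
#' initially unstable — at \eqn{\hat\mu = \Delta k^2}, and its
#' stabilization through the collision with the mixed branch, opening the
#' horizontal/oblique coexistence window.
#'
#' @param params an [amplitude_params()]; its `mu_hat` is ignored in favour
#'   of `mu_hat_values`.
#' @param mu_hat_values grid of bifurcation-parameter values.
#' @return a `veg_branches` tibble: `mu_hat`, `branch`, `mod_H`, `mod_Ol`,
#'   `mod_Or`, `psi`, `stable`, `max_re`, `n_neutral`.
#' @export
#' @examples
#' ap <- amplitude_params(mu_hat = 0, beta = 0, delta_k = 0.3)
#' br <- equilibrium_branches(ap, seq(-0.05, 0.4, by = 0.05))
equilibrium_branches <- function(params, mu_hat_values) {
  stopifnot(inherits(params, "amplitude_params"))
  dk2 <- params$delta_k^2
  mixed_prev <- NULL
  rows <- purrr::map_dfr(mu_hat_values, function(mu) {
    p <- amplitude_params(mu, params$beta, params$alpha_hat, params$delta_k)
    add <- function(branch, z, psi = NA_real_) {
      st <- amp_stability(z, p)
      tibble::tibble(mu_hat = mu, branch = branch,
                     mod_H = Mod(z[1]), mod_Ol = Mod(z[2]),
                     mod_Or = Mod(z[3]), psi = psi,
                     stable = st$stable, max_re = st$max_re,
                     n_neutral = st$n_neutral)
    }
    out <- add("trivial", c(0i, 0i, 0i))
    if (mu > 0)
      out <- dplyr::bind_rows(out, add("H", c(sqrt(mu) + 0i, 0i, 0i)))
    if (mu > dk2) {
      R <- sqrt(mu - dk2)
      out <- dplyr::bind_rows(
        out,
        add("O_single", c(0i, R + 0i, 0i)),
        add("O_pair", c(0i, R / sqrt(3) + 0i, R / sqrt(3) + 0i)))
    }
    if (mu > 2 * dk2 + 1e-12) {
      start <- if (!is.null(mixed_prev)) mixed_prev
      else c(sqrt((mu - 2 * dk2) / 5), sqrt((2 * mu + dk2) / 15), 0)
      sol <- solve_mixed(p, start)
      if (is.null(sol))  # retry from the closed-form start
        sol <- solve_mixed(p, c(sqrt((mu - 2 * dk2) / 5),
                                sqrt((2 * mu + dk2) / 15), 0))
      if (!is.null(sol) && all(sol[1:2] > 1e-8)) {
        mixed_prev <<- sol
        z <- c(sol[1] + 0i, sol[2] * exp(1i * sol[3] / 2),
               sol[2] * exp(1i * sol[3] / 2))
        out <- dplyr::bind_rows(out, add("mixed", z, psi = sol[3]))
      }
    }
    out
  })
  attr(rows, "params") <- params
  class(rows) <- c("veg_branches", class(rows))
  rows
}

#' Integrate the amplitude equations
#'
#' RK4 integration of [amplitude_rhs()], recording moduli over time and
#' labelling the final attractor by the nearest equilibrium branch.
#'
#' @param state0 complex vector `c(H, O_l, O_r)`.
#' @param params an [amplitude_params()].
#' @param dt time step; defaults to `0.1 / max(|mu_hat|, 1)`.
#' @param t_end integration time.
#' @param record_stride store every this many steps.
#' @return a `veg_amp_traj` tibble: `t`, `H`, `O_l`, `O_r` (complex),
#'   `mod_H`, `mod_Ol`, `mod_Or`; attributes `params` and `final_label`.
#' @export
integrate_amplitudes <- function(state0, params, dt = NULL, t_end = 100,
                                 record_stride = 10) {
  stopifnot(inherits(params, "amplitude_params"))
  if (is.null(dt)) dt <- 0.1 / max(abs(params$mu_hat), 1)
  n <- max(1, round(t_end / dt))
  z <- as.complex(state0)
  out_t <- numeric(0); out_z <- NULL
  store <- function(step, z) {
    out_t <<- c(out_t, step * dt)
    out_z <<- rbind(out_z, z)
  }
  store(0, z)
  for (s in seq_len(n)) {
    k1 <- amplitude_rhs(z, params)
    k2 <- amplitude_rhs(z + dt / 2 * k1, params)
    k3 <- amplitude_rhs(z + dt / 2 * k2, params)
    k4 <- amplitude_rhs(z + dt * k3, params)
    z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(Mod(z))) || max(Mod(z)) > 1e6)
      stop(sprintf("amplitude integration diverged at step %d", s))
    if (s %% record_stride == 0 || s == n) store(s, z)
  }
  tr <- tibble::tibble(
    t = out_t, H = out_z[, 1], O_l = out_z[, 2], O_r = out_z[, 3],
    mod_H = Mod(out_z[, 1]), mod_Ol = Mod(out_z[, 2]),
    mod_Or = Mod(out_z[, 3]))
  attr(tr, "params") <- params
  attr(tr, "final_label") <- classify_amplitude_state(z, params)
  class(tr) <- c("veg_amp_traj", class(tr))
  tr
}

# nearest equilibrium branch in modulus space
classify_amplitude_state <- function(z, params) {
  br <- equilibrium_branches(params, params$mu_hat)
  m <- Mod(z)
  dists <- vapply(seq_len(nrow(br)), function(i) {
    target <- c(br$mod_H[i], br$mod_Ol[i], br$mod_Or[i])
    # oblique branches are symmetric under O_l <-> O_r
    min(sqrt(sum((m - target)^2)),
        sqrt(sum((m - target[c(1, 3, 2)])^2)))
  }, numeric(1))
  br$branch[which.min(dists)]
}

#' @describeIn integrate_amplitudes final attractor label of a trajectory.
#' @param x a `veg_amp_traj`.
#' @param ... unused.
#' @method glance veg_amp_traj
#' @export
glance.veg_amp_traj <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(final_label = attr(x, "final_label"),
                 mod_H = x$mod_H[n], mod_Ol = x$mod_Ol[n],
                 mod_Or = x$mod_Or[n], t_end = x$t[n])
}

#' Simulate the Ginzburg-Landau envelope equation
#'
#' Pseudo-spectral RK4 integration of
#' \eqn{\partial_t A = \hat\mu A - (1+i\beta)|A|^2A + \nabla^2 A -
#' \hat\alpha \partial_x A} on a periodic box, with projections of the field
#' onto the three-mode basis \eqn{\{1, e^{\pm i \Delta k y}\}} recorded over
#' time for comparison with [integrate_amplitudes()].
#'
#' @param params an [amplitude_params()].
#' @param A0 complex matrix (nx x ny) initial envelope; `nx = 1` gives the
#'   y-only dynamics of the truncation ansatz.
#' @param Lx,Ly box sizes; `Ly` must hold an integer number of oblique
#'   wavelengths \eqn{2\pi/\Delta k}.
#' @param dt time step.
#' @param t_end integration time.
#' @param record_stride record projections every this many steps.
#' @return a tibble `t`, `H`, `O_l`, `O_r` (complex projections),
#'   `higher_frac` (power fraction outside the three modes), with the final
#'   field as attribute `A_final`.
#' @export
simulate_envelope <- function(params, A0, Lx, Ly, dt = 0.02, t_end = 50,
                              record_stride = 10) {
  stopifnot(inherits(params, "amplitude_params"))
  A <- as.matrix(A0)
  nx <- nrow(A); ny <- ncol(A)
  dk <- params$delta_k
  if (dk > 0) {
    ratio <- Ly * dk / (2 * pi)
    if (abs(ratio - round(ratio)) > 1e-8)
      stop("Ly must be an integer multiple of 2*pi/delta_k")
  }
  kxi <- 0:(nx - 1); kxi[kxi > nx / 2] <- kxi[kxi > nx / 2] - nx
  kyi <- 0:(ny - 1); kyi[kyi > ny / 2] <- kyi[kyi > ny / 2] - ny
  KX <- matrix(2 * pi * kxi / Lx, nx, ny)
  KY <- matrix(2 * pi * kyi / Ly, nx, ny, byrow = TRUE)
  K2 <- KX^2 + KY^2
  cb <- 1 + 1i * params$beta
  y <- (seq_len(ny) - 1) * (Ly / ny)
  e_l <- matrix(exp(-1i * dk * y), nx, ny, byrow = TRUE)
  rhs <- function(A) {
    Ah <- stats::fft(A)
    lap <- stats::fft(-K2 * Ah, inverse = TRUE) / (nx * ny)
    adv <- stats::fft(1i * KX * Ah, inverse = TRUE) / (nx * ny)
    params$mu_hat * A - cb * Mod(A)^2 * A + lap - params$alpha_hat * adv
  }
  n <- max(1, round(t_end / dt))
  out <- NULL
  project <- function(step, A) {
    H <- mean(A)
    Ol <- mean(A * e_l)
    Or <- mean(A * Conj(e_l))
    ptot <- mean(Mod(A)^2)
    p3 <- Mod(H)^2 + Mod(Ol)^2 + Mod(Or)^2
    tibble::tibble(t = step * dt, H = H, O_l = Ol, O_r = Or,
                   higher_frac = max(0, 1 - p3 / max(ptot, 1e-300)))
  }
  out <- project(0, A)
  for (s in seq_len(n)) {
    k1 <- rhs(A); k2 <- rhs(A + dt / 2 * k1)
    k3 <- rhs(A + dt / 2 * k2); k4 <- rhs(A + dt * k3)
    A <- A + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (max(Mod(A)) > 1e6 || any(!is.finite(Mod(A))))
      stop(sprintf("envelope integration diverged at step %d", s))
    if (s %% record_stride == 0 || s == n)
      out <- dplyr::bind_rows(out, project(s, A))
  }
  attr(out, "A_final") <- A
  out
}
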