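test_that("the closed-form growth rate matches an independently typed oracle", {
  p <- reduced_params(eta = -0.219, kappa = 0.3, d = 0.3, alpha = 0.27,
                      gamma = 2)
  bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
  disp <- dispersion(p, bp)
  ks <- expand.grid(kx = seq(0, 1.6, by = 0.2), ky = seq(-0.4, 0.4, by = 0.2))
  expect_equal(disp$re_fun(ks$kx, ks$ky),
               lambda_re_oracle(ks$kx, ks$ky, bp, 0.3, 0.3, 2),
               tolerance = 1e-14)
  expect_equal(disp$im_fun(ks$kx, ks$ky), -bp * 0.27 * ks$kx,
               tolerance = 1e-14)
  # maximal growth just above threshold, located by an independent maximizer
  opt <- stats::optimize(function(k) -lambda_re_oracle(k, 0, bp, 0.3, 0.3, 2),
                         c(0.1, 2))
  expect_equal(disp$k_max, opt$minimum, tolerance = 1e-5)
  expect_equal(disp$re_max, -opt$objective, tolerance = 1e-7)
  expect_equal(disp$re_max, 0.00256, tolerance = 2e-3)
  expect_equal(disp$k_max, 0.924, tolerance = 1e-3)
})

test_that("uniform states are validated before linearization", {
  p <- fig4_reduced()
  expect_error(dispersion(p, 0.5), "not a uniform steady state")
  # homogeneous perturbations of the cover state decay (k = 0)
  bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
  expect_lt(dispersion(p, bp)$re_fun(0, 0), 0)
  expect_equal(dispersion(p, bp)$re_fun(0, 0), bp * (p$kappa - bp))
})

test_that("nonreciprocity moves only the imaginary part of the spectrum", {
  bp <- uniform_states_reduced(-0.02, 0.3)$b[2]
  k <- c(0.3, 0.9, 1.4)
  res <- sapply(c(0, 0.1, 0.27, -0.4), function(a) {
    disp <- dispersion(fig4_reduced(alpha = a), bp)
    c(disp$re_fun(k, 0.1), disp$im_fun(k, 0))
  })
  for (j in 2:4) expect_identical(res[1:3, j], res[1:3, 1])
  expect_equal(res[4:6, 2] / res[4:6, 3], rep(0.1 / 0.27, 3),
               tolerance = 1e-12)
})

test_that("the pattern-forming threshold satisfies both marginality conditions", {
  cp <- critical_point(kappa = 0.3, d = 0.3, gamma = 2)
  bp <- 0.3 + sqrt(0.09 - 2 * cp$eta_c)
  expect_equal(bp, cp$b_plus, tolerance = 1e-10)
  # Re lambda = 0 at (eta_c, k_c) and d(Re lambda)/dk = 0
  expect_lt(abs(lambda_re_oracle(cp$k_c, 0, bp, 0.3, 0.3, 2)), 1e-10)
  h <- 1e-6
  deriv <- (lambda_re_oracle(cp$k_c + h, 0, bp, 0.3, 0.3, 2) -
              lambda_re_oracle(cp$k_c - h, 0, bp, 0.3, 0.3, 2)) / (2 * h)
  expect_lt(abs(deriv), 1e-8)
  second <- (lambda_re_oracle(cp$k_c + h, 0, bp, 0.3, 0.3, 2) -
               2 * lambda_re_oracle(cp$k_c, 0, bp, 0.3, 0.3, 2) +
               lambda_re_oracle(cp$k_c - h, 0, bp, 0.3, 0.3, 2)) / h^2
  expect_lt(second, 0)
  # eta = -0.219 sits just above the threshold
  expect_lt(cp$eta_c, -0.219)
  expect_gt(cp$eta_c, -0.225)
  # independent bisection on the same marginality function
  gm <- function(eta) {
    b <- 0.3 + sqrt(0.09 - 2 * eta)
    k2 <- (2 * b - 0.3) / (2 * b)
    lambda_re_oracle(sqrt(k2), 0, b, 0.3, 0.3, 2)
  }
  expect_equal(cp$eta_c, bisect(gm, -0.3, -0.2), tolerance = 1e-10)
})

test_that("a vanishing range balance leaves no pattern-forming threshold", {
  expect_error(critical_point(kappa = 0.3, d = 0.3, gamma = 0),
               "no pattern-forming threshold")
})

test_that("the finite box at eta = -0.219 admits exactly one horizontal and one oblique pair", {
  p <- reduced_params(eta = -0.219, kappa = 0.3, d = 0.3, gamma = 2)
  bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
  ms <- enumerate_modes(p, bp, Lx = 85, Ly = 100)
  un <- ms[ms$unstable, ]
  expect_equal(nrow(un), 3)
  expect_setequal(un$n, c(-1, 0, 1))
  expect_true(all(un$m == 25))
  expect_setequal(un$label, c("H", "O_l", "O_r"))
  expect_equal(un$label[un$n == 0], "H")
  expect_equal(un$label[un$n == 1], "O_l")

  # doubling the transverse box halves the k_y spacing: n = +/-2 modes enter
  ms2 <- enumerate_modes(p, bp, Lx = 85, Ly = 200)
  un2 <- ms2[ms2$unstable, ]
  expect_gt(nrow(un2), 3)
  expect_true(all(c(-2, 2) %in% un2$n))

  # far below threshold nothing is unstable
  plow <- reduced_params(eta = -0.4, kappa = 0.3, d = 0.3, gamma = 2)
  blow <- uniform_states_reduced(-0.4, 0.3)$b[2]
  expect_equal(sum(enumerate_modes(plow, blow, 85, 100)$unstable), 0)
})

test_that("the unstable mode set is symmetric under reflection of the oblique index", {
  p <- reduced_params(eta = -0.19, kappa = 0.3, d = 0.3, alpha = 0.27,
                      gamma = 2)
  bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
  ms <- enumerate_modes(p, bp, Lx = 60, Ly = 70)
  for (nn in unique(abs(ms$n))) {
    up <- ms$unstable[ms$n == nn]
    dn <- ms$unstable[ms$n == -nn]
    expect_identical(up, dn)
  }
})

test_that("the first mode to destabilize with rising aridity is horizontal", {
  p0 <- reduced_params(eta = 0, kappa = 0.3, d = 0.3, gamma = 2)
  cp <- critical_point(0.3, 0.3, 2)
  eta <- cp$eta_c + 1e-4
  p <- reduced_params(eta = eta, kappa = 0.3, d = 0.3, gamma = 2)
  bp <- uniform_states_reduced(eta, 0.3)$b[2]
  disp <- dispersion(p, bp)
  g <- expand.grid(kx = seq(0.01, 2, length.out = 300),
                   ky = seq(-1, 1, length.out = 101))
  re <- disp$re_fun(g$kx, g$ky)
  expect_equal(g$ky[which.max(re)], 0)
})

test_that("phase speed and group-velocity coefficient follow b_s alpha", {
  bp <- uniform_states_reduced(-0.02, 0.3)$b[2]
  expect_equal(drift_speed(fig4_reduced(alpha = 0), bp)$phase_speed, 0)
  s1 <- drift_speed(fig4_reduced(alpha = 0.27), bp)
  s2 <- drift_speed(fig4_reduced(alpha = -0.27), bp)
  expect_equal(s1$phase_speed, -s2$phase_speed)
  expect_equal(s1$phase_speed, 0.17835, tolerance = 1e-4)
  expect_equal(s1$dIm_dkx, -s1$phase_speed)
})

test_that("the admissible transverse window brackets the standard box", {
  p <- reduced_params(eta = -0.219, kappa = 0.3, d = 0.3, gamma = 2)
  bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
  win <- admissible_box(p, bp)
  expect_gt(win$ky_max, 0)
  expect_true(win$Ly_min < 100 && 100 <= win$Ly_max)
  expect_true(win$kx_lo < pi * 25 / 85 && pi * 25 / 85 < win$kx_hi)
  # below threshold there is no window at all
  plow <- reduced_params(eta = -0.4, kappa = 0.3, d = 0.3, gamma = 2)
  blow <- uniform_states_reduced(-0.4, 0.3)$b[2]
  expect_equal(admissible_box(plow, blow)$ky_max, 0)
})
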