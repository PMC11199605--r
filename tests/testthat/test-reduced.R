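test_that("the weak-gradient parameter mapping reproduces hand-computed values", {
  m <- map_parameters(mu = 0.98, chi_f = 2.1, chi_c = 1.2,
                      x0f = 0.5, x0c = -0.2, lfx = 0.9, lcx = 5)
  # independent arithmetic from the printed formulas
  chi0 <- 0.9^2 / (5^2 - 0.9^2)
  sigma <- 3 * 0.9^2 * 5^2
  expect_equal(m$kappa, -0.1)
  expect_equal(m$eta, -0.02)
  expect_equal(m$chi0, chi0, tolerance = 1e-12)
  expect_equal(m$sigma, 60.75)
  expect_equal(m$alpha, (-0.2 * chi0 - 0.5 * (1 + chi0)) / sigma^0.25,
               tolerance = 1e-12)
  expect_equal(m$alpha, -0.18749, tolerance = 1e-4)
  expect_equal(m$gamma, (1.2 - chi0) * (25 - 0.81) / sqrt(sigma),
               tolerance = 1e-12)
  expect_equal(m$gamma, 3.6204, tolerance = 1e-4)
})

test_that("mapping limits behave: reciprocal offsets and nascent bistability", {
  m0 <- map_parameters(mu = 1, chi_f = 2, chi_c = 0.9, x0f = 0, x0c = 0,
                       lfx = 1, lcx = 3)
  expect_equal(m0$alpha, 0)
  mc <- map_parameters(mu = 1, chi_f = 1.9, chi_c = 0.9, x0f = 0.1,
                       x0c = 0, lfx = 1, lcx = 3)
  expect_equal(mc$kappa, 0)
  expect_error(map_parameters(mu = 1, chi_f = 2, chi_c = 1, x0f = 0,
                              x0c = 0, lfx = 3, lcx = 1), "competition range")
  # mapping accepts a nonlocal parameter object too
  mm <- map_parameters(params = fig3_nonlocal())
  expect_equal(mm$alpha, -0.18749, tolerance = 1e-4)
})

test_that("homogeneous cover branches and the tipping point follow the closed forms", {
  us <- uniform_states_reduced(eta = -0.02, kappa = 0.3)
  expect_equal(us$b[us$branch == "b_plus"], 0.3 + sqrt(0.09 + 0.04),
               tolerance = 1e-12)
  expect_equal(us$b[us$branch == "b_plus"], 0.66056, tolerance = 1e-4)
  expect_false(us$physical[us$branch == "b_minus"])  # negative, nonphysical
  expect_equal(attr(us, "eta_l"), 0.0225)
  expect_equal(attr(us, "b_l"), 0.15)

  u0 <- uniform_states_reduced(eta = 0, kappa = 0.3)
  expect_equal(u0$b[2:3], c(0.6, 0))
  expect_true(attr(uniform_states_reduced(0.01, 0.3), "bistable"))
  expect_false(uniform_states_reduced(0.3, 0.3)$exists[2])  # beyond the fold
})

test_that("bare soil and uniform cover are fixed points of the reduced dynamics", {
  p <- fig4_reduced()
  z <- veg_field(matrix(0, 32, 16), dx = 0.5, bc_x = "periodic")
  expect_equal(max(abs(rhs_reduced(z, p)$values)), 0)
  bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
  bu <- veg_field(matrix(bp, 32, 16), dx = 0.5, bc_x = "periodic")
  expect_lt(max(abs(rhs_reduced(bu, p)$values)), 1e-10)
  bad <- veg_field(matrix(c(NA, rep(0, 31 * 16 + 15)), 32, 16), dx = 0.5)
  expect_error(rhs_reduced(bad, p), "finite")
})

test_that("single Fourier modes classify as horizontal or oblique with the sign convention", {
  nx <- 64; ny <- 32; dx <- 0.5
  x <- (0:(nx - 1)) * dx; y <- (0:(ny - 1)) * dx
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  kx <- 2 * pi * 6 / (nx * dx); ky <- 2 * pi * 2 / (ny * dx)
  h <- veg_field(0.5 + 0.2 * cos(kx * X), dx = dx, bc_x = "periodic")
  expect_equal(classify_pattern(h)$label, "H")
  ol <- veg_field(0.5 + 0.2 * cos(kx * X + ky * Y), dx = dx, bc_x = "periodic")
  cl <- classify_pattern(ol)
  expect_equal(cl$label, "O_l")
  expect_gt(cl$ky, 0)
  or <- veg_field(0.5 + 0.2 * cos(kx * X - ky * Y), dx = dx, bc_x = "periodic")
  expect_equal(classify_pattern(or)$label, "O_r")
  set.seed(1)
  wn <- veg_field(matrix(stats::rnorm(nx * ny), nx, ny), dx = dx,
                  bc_x = "periodic")
  expect_equal(classify_pattern(wn)$label, "none")
  # superposed oblique pair within 3 dB reads as mixed
  mx <- veg_field(0.5 + 0.2 * cos(kx * X + ky * Y) + 0.18 * cos(kx * X - ky * Y),
                  dx = dx, bc_x = "periodic")
  expect_equal(classify_pattern(mx)$label, "mixed")
})

test_that("reflecting the box and negating the nonreciprocity mirrors trajectories", {
  p <- fig4_reduced(alpha = 0.27)
  pm <- fig4_reduced(alpha = -0.27)
  b0 <- make_noise_ic(43, 24, dx = 0.5, mean = 0.66, amplitude = 0.1,
                      seed = 5)
  mirror <- function(v) v[rev(seq_len(nrow(v))), , drop = FALSE]
  b0m <- veg_field(mirror(b0$values), dx = 0.5, bc_x = "dirichlet")
  f1 <- final_state(simulate_reduced(p, b0, dt = 1e-3, n_steps = 2000))
  f2 <- final_state(simulate_reduced(pm, b0m, dt = 1e-3, n_steps = 2000))
  expect_equal(mirror(f2$values), f1$values, tolerance = 1e-10)
})

test_that("small nonreciprocity advects the pattern without changing its amplitude", {
  # alpha only enters Im(lambda): the saturated modulus is alpha-independent
  run_amp <- function(alpha) {
    p <- fig4_reduced(alpha = alpha)
    bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
    nx <- 100; dx <- 0.5
    x <- (0:(nx - 1)) * dx
    k <- 2 * pi * 7 / (nx * dx)
    b0 <- veg_field(matrix(bp + 0.01 * cos(k * x), nx, 2), dx = dx,
                    bc_x = "periodic")
    tr <- simulate_reduced(p, b0, dt = 1e-3, n_steps = 80000)
    fogbands:::pattern_modulus(final_state(tr))
  }
  a0 <- run_amp(0)
  a1 <- run_amp(0.05)
  expect_lt(abs(a1 - a0) / a0, 0.02)
})

test_that("time steps beyond the explicit stability bound are refused", {
  p <- fig4_reduced()
  b0 <- make_noise_ic(20, 10, dx = 0.5, seed = 1)
  expect_error(simulate_reduced(p, b0, dt = 0.05, n_steps = 10),
               "stability bound")
})
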