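test_that("discretized kernels peak at their offset and carry unit mass", {
  p <- fig3_nonlocal()
  g <- list(nx = 64, ny = 64, dx = 0.3, dy = 0.3)
  Kf <- build_kernel(p, "facilitation", g)
  expect_lt(abs(Kf$mass - 1), 1e-3)
  expect_equal(sum(Kf$values) * g$dx * g$dy, 1, tolerance = 1e-12)
  # facilitation offset x0f = 0.5: peak on the lag grid nearest (0.5, 0)
  pk <- arrayInd(which.max(Kf$values), dim(Kf$values))
  lag_x <- fogbands:::lag_coords(g$nx, g$dx)
  lag_y <- fogbands:::lag_coords(g$ny, g$dy)
  expect_lt(abs(lag_x[pk[1]] - 0.5), g$dx / 2 + 1e-12)
  expect_lt(abs(lag_y[pk[2]] - 0), g$dy / 2 + 1e-12)

  p0 <- nonlocal_params(mu = 0.98, chi_f = 2.1, chi_c = 1.2, D = 0.2,
                        lfx = 0.9, lfy = 0.9, lcx = 5, lcy = 3.5)
  K0 <- build_kernel(p0, "facilitation", g)
  expect_equal(as.integer(arrayInd(which.max(K0$values), dim(K0$values))),
               c(1L, 1L))
})

test_that("nonzero x offsets break reciprocity; negating them mirrors the kernel", {
  p <- fig3_nonlocal()
  g <- list(nx = 64, ny = 64, dx = 0.3, dy = 0.3)
  K <- build_kernel(p, "facilitation", g)$values
  pm <- nonlocal_params(mu = p$mu, chi_f = p$chi_f, chi_c = p$chi_c, D = p$D,
                        x0f = -p$x0f, x0c = -p$x0c,
                        lfx = p$lfx, lfy = p$lfy, lcx = p$lcx, lcy = p$lcy)
  Km <- build_kernel(pm, "facilitation", g)$values
  # mirror in x on the wrapped lag grid: lag s -> -s
  mirror <- K[c(1, 64:2), ]
  expect_equal(Km, mirror, tolerance = 1e-12)
  # phi(r, r') != phi(r', r): the kernel is not even in the lag
  expect_gt(max(abs(K - K[c(1, 64:2), ])), 1e-3)
})

test_that("too-small grids for the stated kernel widths are refused with the extent named", {
  p <- fig3_nonlocal()
  expect_error(build_kernel(p, "competition",
                            list(nx = 32, ny = 64, dx = 0.3, dy = 0.3)),
               "extent in x")
  expect_error(build_kernel(p, "competition",
                            list(nx = 200, ny = 32, dx = 0.3, dy = 0.3)),
               "extent in y")
})

test_that("feedback is unity for bare ground or zero intensity and exp(chi b) for uniform cover", {
  p <- fig3_nonlocal()
  g <- list(nx = 160, ny = 96, dx = 0.3, dy = 0.3)
  K <- build_kernel(p, "competition", g)
  b0 <- veg_field(matrix(0, 160, 96), dx = 0.3, bc_x = "periodic")
  expect_equal(nonlocal_feedback(b0, K, p$chi_c)$values,
               matrix(1, 160, 96), tolerance = 1e-14)
  bu <- veg_field(matrix(0.3, 160, 96), dx = 0.3, bc_x = "periodic")
  expect_equal(nonlocal_feedback(bu, K, 0)$values,
               matrix(1, 160, 96), tolerance = 1e-14)
  M <- nonlocal_feedback(bu, K, p$chi_c)$values
  expect_lt(max(abs(M - exp(p$chi_c * 0.3))), 1e-6)
})

test_that("the overflow guard rejects runaway feedback exponents", {
  p <- nonlocal_params(mu = 0.9, chi_f = 3, chi_c = 1, D = 0.1,
                      lfx = 0.5, lfy = 0.5, lcx = 1, lcy = 1)
  g <- list(nx = 32, ny = 32, dx = 0.25, dy = 0.25)
  K <- build_kernel(p, "facilitation", g)
  b <- veg_field(matrix(1, 32, 32), dx = 0.25, bc_x = "periodic")
  expect_error(nonlocal_feedback(b, K, 100), "exponent")
})

test_that("FFT convolution agrees with direct summation", {
  p <- nonlocal_params(mu = 0.9, chi_f = 1.5, chi_c = 0.8, D = 0.1,
                       x0f = 0.3, x0c = -0.1, lfx = 0.5, lfy = 0.5,
                       lcx = 1.2, lcy = 1.0)
  g <- list(nx = 30, ny = 26, dx = 0.4, dy = 0.4)
  K <- build_kernel(p, "facilitation", g)
  set.seed(2)
  bv <- matrix(stats::runif(30 * 26), 30, 26)
  b <- veg_field(bv, dx = 0.4, bc_x = "periodic")
  M <- nonlocal_feedback(b, K, 1)
  expect_lt(max(abs(log(M$values) - direct_conv(K$values, bv, 0.4, 0.4))),
            1e-8)
})

test_that("uniform steady states solve (1-b) exp((chi_f-chi_c) b) = mu", {
  p <- fig3_nonlocal()
  us <- uniform_states_nonlocal(p)
  expect_equal(us$b[us$branch == "bare"], 0)
  # independent bisection oracle on the printed parameter set
  root <- bisect(function(b) (1 - b) * exp(0.9 * b) - 0.98, 1e-9, 1)
  expect_equal(us$b[us$branch == "vegetated"], root, tolerance = 1e-8)
  expect_equal(root, 0.1216, tolerance = 1e-3)

  # balanced feedbacks reduce to the logistic root 1 - mu
  pb <- nonlocal_params(mu = 0.7, chi_f = 1.3, chi_c = 1.3, D = 0.1,
                        lfx = 1, lfy = 1, lcx = 2, lcy = 2)
  expect_equal(uniform_states_nonlocal(pb)$b[2], 0.3, tolerance = 1e-8)

  # aridity beyond the maximum of the scalar function leaves only bare soil
  g_max <- -stats::optimize(function(b) -(1 - b) * exp(0.9 * b),
                            c(0, 1))$objective
  ph <- nonlocal_params(mu = g_max + 0.1, chi_f = 2.1, chi_c = 1.2, D = 0.2,
                        lfx = 0.9, lfy = 0.9, lcx = 5, lcy = 3.5)
  expect_equal(nrow(uniform_states_nonlocal(ph)), 1)
})

test_that("bare ground and the uniform vegetated state are fixed points of the dynamics", {
  p <- fig3_nonlocal()
  b0 <- veg_field(matrix(0, 136, 96), dx = 0.3, bc_x = "periodic")
  expect_equal(max(abs(rhs_nonlocal(b0, p)$values)), 0)
  root <- uniform_states_nonlocal(p)$b[2]
  bu <- veg_field(matrix(root, 136, 96), dx = 0.3, bc_x = "periodic")
  expect_lt(max(abs(rhs_nonlocal(bu, p)$values)), 1e-8)
})

test_that("without nonlocal feedback the dynamics is logistic growth minus mortality", {
  p <- nonlocal_params(mu = 0.4, chi_f = 0, chi_c = 0, D = 0.1,
                       lfx = 0.5, lfy = 0.5, lcx = 1, lcy = 1)
  bu <- veg_field(matrix(0.6, 32, 32), dx = 0.25, bc_x = "periodic")
  r <- rhs_nonlocal(bu, p)$values
  expect_equal(r, matrix(0.6 * 0.4 - 0.4 * 0.6, 32, 32), tolerance = 1e-12)
  # fixed point at b = 1 - mu
  bf <- veg_field(matrix(1 - p$mu, 32, 32), dx = 0.25, bc_x = "periodic")
  expect_lt(max(abs(rhs_nonlocal(bf, p)$values)), 1e-12)
})

test_that("mirroring the initial condition and negating offsets mirrors the trajectory", {
  p <- nonlocal_params(mu = 0.9, chi_f = 1.6, chi_c = 0.9, D = 0.1,
                       x0f = 0.3, x0c = -0.15, lfx = 0.5, lfy = 0.5,
                       lcx = 1.2, lcy = 1.0)
  pm <- nonlocal_params(mu = 0.9, chi_f = 1.6, chi_c = 0.9, D = 0.1,
                        x0f = -0.3, x0c = 0.15, lfx = 0.5, lfy = 0.5,
                        lcx = 1.2, lcy = 1.0)
  b0 <- make_noise_ic(33, 24, dx = 0.4, mean = 0.3, amplitude = 0.1, seed = 9)
  mirror <- function(v) v[rev(seq_len(nrow(v))), , drop = FALSE]
  b0m <- veg_field(mirror(b0$values), dx = 0.4, bc_x = "dirichlet")
  f1 <- final_state(simulate_nonlocal(p, b0, dt = 0.02, n_steps = 100))
  f2 <- final_state(simulate_nonlocal(pm, b0m, dt = 0.02, n_steps = 100))
  expect_equal(mirror(f2$values), f1$values, tolerance = 1e-10)
})

test_that("excess aridity drives the biomass toward bare ground", {
  p <- nonlocal_params(mu = 2, chi_f = 2.1, chi_c = 1.2, D = 0.2,
                       x0f = 0.5, x0c = -0.2, lfx = 0.9, lfy = 0.9,
                       lcx = 5, lcy = 3.5)
  expect_equal(nrow(uniform_states_nonlocal(p)), 1)  # only bare soil
  b0 <- make_noise_ic(136, 96, dx = 0.3, mean = 0.2, amplitude = 0.05,
                      seed = 3, bc_x = "periodic")
  tr <- simulate_nonlocal(p, b0, dt = 0.04, n_steps = 500)
  expect_lt(max(final_state(tr)$values), 0.01 * max(b0$values))
})

test_that("trajectories preserve nonnegative biomass and report their records", {
  p <- fig3_nonlocal()
  b0 <- make_noise_ic(68, 96, dx = 0.3, mean = 0.12, amplitude = 0.05,
                      seed = 2)
  tr <- simulate_nonlocal(p, b0, dt = 0.04, n_steps = 50, snap_stride = 25,
                          rec_stride = 10)
  expect_gte(min(final_state(tr)$values), -1e-10)
  expect_equal(length(tr$snapshots), 3)  # t = 0, 25 and the final state
  expect_equal(dim(tr$mid_col), c(96, 6))
  expect_equal(dim(tr$mid_row), c(68, 6))
})
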