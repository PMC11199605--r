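test_that("single-mode equilibria satisfy the amplitude equations exactly", {
  p <- amplitude_params(mu_hat = 0.25, beta = 0, delta_k = 0.3)
  expect_equal(amplitude_rhs(c(0i, 0i, 0i), p), c(0i, 0i, 0i))
  expect_lt(max(Mod(amplitude_rhs(c(sqrt(0.25) + 0i, 0i, 0i), p))), 1e-10)
  expect_lt(max(Mod(amplitude_rhs(c(0i, sqrt(0.25 - 0.09) + 0i, 0i), p))),
            1e-10)
  expect_lt(max(Mod(amplitude_rhs(c(0i, 0i, sqrt(0.25 - 0.09) + 0i), p))),
            1e-10)
})

test_that("equilibrium branches reproduce the horizontal-first bifurcation sequence", {
  ap <- amplitude_params(mu_hat = 0, beta = 0, delta_k = 0.3)
  dk2 <- 0.09
  br <- equilibrium_branches(ap, c(-0.05, 0.04, 0.12, 0.15, 0.25, 0.35))
  at <- function(mu, name) br[br$mu_hat == mu & br$branch == name, ]

  # below threshold only the stable trivial state
  expect_equal(br$branch[br$mu_hat == -0.05], "trivial")
  expect_true(at(-0.05, "trivial")$stable)

  # horizontal branch: supercritical, |H| = sqrt(mu), stable throughout
  for (mu in c(0.04, 0.12, 0.25)) {
    h <- at(mu, "H")
    expect_equal(h$mod_H, sqrt(mu), tolerance = 1e-12)
    expect_true(h$stable)
    expect_false(at(mu, "trivial")$stable)
  }

  # obliques exist only above mu = dk^2, initially unstable, then stabilized
  expect_equal(nrow(at(0.04, "O_single")), 0)
  o1 <- at(0.12, "O_single")
  expect_equal(o1$mod_Ol, sqrt(0.12 - dk2), tolerance = 1e-12)
  expect_false(o1$stable)
  expect_equal(o1$max_re, 2 * dk2 - 0.12, tolerance = 1e-6)  # collision rate
  expect_true(at(0.25, "O_single")$stable)
  expect_true(at(0.35, "O_single")$stable)

  # mixed branch appears at mu = 2 dk^2 as the (unstable) basin boundary
  expect_equal(nrow(at(0.15, "mixed")), 0)
  mx <- at(0.25, "mixed")
  expect_equal(mx$mod_H, sqrt((0.25 - 2 * dk2) / 5), tolerance = 1e-8)
  expect_equal(mx$mod_Ol, sqrt((2 * 0.25 + dk2) / 15), tolerance = 1e-8)
  expect_false(mx$stable)

  # the symmetric oblique pair (rectangles) never wins against stripes
  expect_equal(at(0.25, "O_pair")$mod_Ol, sqrt((0.25 - dk2) / 3),
               tolerance = 1e-12)
  expect_false(at(0.25, "O_pair")$stable)
})

test_that("the beta = 0 potential is non-increasing along random trajectories", {
  set.seed(7)
  for (i in 1:20) {
    mu <- stats::runif(1, -0.1, 0.4)
    p <- amplitude_params(mu, 0, 0, 0.3)
    z0 <- complex(real = stats::rnorm(3, 0, 0.3),
                  imaginary = stats::rnorm(3, 0, 0.3))
    tr <- integrate_amplitudes(z0, p, dt = 0.02, t_end = 30,
                               record_stride = 5)
    V <- apply(cbind(tr$H, tr$O_l, tr$O_r), 1, amplitude_potential,
               params = p)
    expect_true(all(diff(V) <= 1e-8))
  }
})

test_that("gauge phase rotations leave the modulus dynamics invariant", {
  p <- amplitude_params(0.3, 0.4, 0, 0.3)
  z0 <- c(0.2 + 0.1i, 0.15 - 0.05i, 0.1 + 0.02i)
  th <- 0.7; thl <- 1.1; thr <- 2 * th - thl
  zr <- z0 * exp(1i * c(th, thl, thr))
  t1 <- integrate_amplitudes(z0, p, dt = 0.02, t_end = 20, record_stride = 20)
  t2 <- integrate_amplitudes(zr, p, dt = 0.02, t_end = 20, record_stride = 20)
  expect_equal(t1$mod_H, t2$mod_H, tolerance = 1e-10)
  expect_equal(t1$mod_Ol, t2$mod_Ol, tolerance = 1e-10)
  expect_equal(t1$mod_Or, t2$mod_Or, tolerance = 1e-10)
})

test_that("swapping the oblique amplitudes maps solutions onto solutions", {
  p <- amplitude_params(0.3, 0.2, 0, 0.3)
  z0 <- c(0.1 + 0i, 0.25 + 0.05i, 0.05 - 0.1i)
  swap <- function(z) z[c(1, 3, 2)]
  t1 <- integrate_amplitudes(z0, p, dt = 0.02, t_end = 15, record_stride = 30)
  t2 <- integrate_amplitudes(swap(z0), p, dt = 0.02, t_end = 15,
                             record_stride = 30)
  expect_equal(t1$mod_Ol, t2$mod_Or, tolerance = 1e-12)
  expect_equal(t1$mod_Or, t2$mod_Ol, tolerance = 1e-12)
})

test_that("trajectories decay below threshold and split into basins in the bistable window", {
  pneg <- amplitude_params(-0.1, 0, 0, 0.3)
  tr <- integrate_amplitudes(c(0.1 + 0.05i, 0.08i, 0.05 + 0i), pneg,
                             t_end = 200)
  expect_equal(glance(tr)$final_label, "trivial")
  expect_lt(glance(tr)$mod_H, 1e-4)

  # H-only window: oblique-dominated states still fall onto the H branch
  ph <- amplitude_params(0.12, 0, 0, 0.3)
  th <- integrate_amplitudes(c(0.02 + 0i, 0.17 + 0i, 0.01 + 0i), ph,
                             t_end = 600)
  expect_equal(glance(th)$final_label, "H")

  # coexistence window: seeding decides the attractor
  pc <- amplitude_params(0.3, 0, 0, 0.3)
  hseed <- integrate_amplitudes(c(0.2 + 0i, 0.01 + 0i, 0.01 + 0i), pc,
                                t_end = 300)
  oseed <- integrate_amplitudes(c(0.01 + 0i, 0.4 + 0i, 0i), pc, t_end = 300)
  expect_equal(glance(hseed)$final_label, "H")
  expect_equal(glance(oseed)$final_label, "O_single")
})

test_that("the envelope equation preserves its invariant subspaces", {
  dk <- 0.3; Ly <- 2 * pi / dk
  p <- amplitude_params(0.1, 0, 0, dk)
  y <- (0:31) * (Ly / 32)
  A0 <- matrix(0.05 + 0.02 * cos(dk * y), 1, 32)  # real initial envelope
  env <- simulate_envelope(p, A0, Lx = 1, Ly = Ly, dt = 0.02, t_end = 5,
                           record_stride = 50)
  expect_lt(max(abs(Im(env$H))), 1e-12)
  expect_lt(max(abs(Im(env$O_l + env$O_r))), 1e-12)

  # x-independent envelopes never feel the advection term
  p2 <- amplitude_params(0.1, 0, 3, dk)
  env2 <- simulate_envelope(p2, A0, Lx = 1, Ly = Ly, dt = 0.02, t_end = 5,
                            record_stride = 50)
  expect_equal(env2$H, env$H, tolerance = 1e-13)
  expect_equal(env2$O_l, env$O_l, tolerance = 1e-13)

  expect_error(simulate_envelope(p, A0, Lx = 1, Ly = Ly * 1.1, dt = 0.02,
                                 t_end = 1), "integer multiple")
})

test_that("the truncated ansatz tracks the full envelope dynamics near onset", {
  mu <- 0.04; dk <- 0.15
  p <- amplitude_params(mu, beta = 0.1, alpha_hat = 0, delta_k = dk)
  Ly <- 2 * pi / dk; ny <- 64
  y <- (0:(ny - 1)) * (Ly / ny)
  H0 <- 0.1 + 0i; Ol0 <- 0.04 + 0.01i; Or0 <- 0.03 - 0.005i
  A0 <- matrix(H0 + Ol0 * exp(1i * dk * y) + Or0 * exp(-1i * dk * y), 1, ny)
  env <- simulate_envelope(p, A0, Lx = 1, Ly = Ly, dt = 0.02, t_end = 120,
                           record_stride = 50)
  amp <- integrate_amplitudes(c(H0, Ol0, Or0), p, dt = 0.02, t_end = 120,
                              record_stride = 50)
  scale <- max(amp$mod_H, amp$mod_Ol)
  expect_lt(max(abs(Mod(env$H) - amp$mod_H)) / scale, 0.05)
  expect_lt(max(abs(Mod(env$O_l) - amp$mod_Ol)) / scale, 0.05)
  expect_lt(max(abs(Mod(env$O_r) - amp$mod_Or)) / scale, 0.05)
  expect_lt(max(env$higher_frac), 0.05)
})

test_that("the linear-analysis helper wires growth and drift into the envelope scale", {
  p <- fig4_reduced()
  bp <- uniform_states_reduced(p$eta, p$kappa)$b[2]
  disp <- dispersion(p, bp)
  ap <- amplitude_from_linear(disp, beta = 0.2, delta_k = 0.1)
  expect_equal(ap$mu_hat, disp$re_max)
  expect_equal(ap$alpha_hat, -bp * 0.27)
  expect_equal(ap$beta, 0.2)
})
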