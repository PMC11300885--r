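test_that("natural frequencies are normal draws converted to rad/s", {
  # zero-variance case: all draws collapse onto the mean
  w <- sample_natural_frequencies(250, 0, n = 3, seed = 42)
  expect_equal(w, rep(2 * pi * 250, 3))

  # law-of-large-numbers bound on the sample mean (in Hz)
  w <- sample_natural_frequencies(20, 2, n = 1e4, seed = 7)
  expect_lt(abs(mean(w) / (2 * pi) - 20), 3 * 2 / sqrt(1e4))
  expect_lt(abs(sd(w) / (2 * pi) - 2), 0.1)

  # deterministic given seed, different across seeds
  expect_identical(w, sample_natural_frequencies(20, 2, n = 1e4, seed = 7))
  expect_false(identical(w, sample_natural_frequencies(20, 2, n = 1e4, seed = 8)))

  expect_error(sample_natural_frequencies(20, 2, n = 1, seed = 1),
               class = "ernasim_invalid_argument")
})

test_that("pulse train fires one timestep per period", {
  dt <- 1e-4
  expect_identical(pulse_train_value(0, 130, dt), 1L)
  expect_identical(pulse_train_value(0.5 / 130, 130, dt), 0L)

  # exhaustive count over one second of grid times
  tt <- seq(0, 1 - dt, by = dt)
  expect_equal(sum(pulse_train_value(tt, 130, dt)), 130)

  expect_error(pulse_train_value(0, 130, dt = 1 / 100),
               class = "ernasim_invalid_argument")
})

test_that("coupling function evaluates its Fourier series and is 2*pi periodic", {
  expect_equal(coupling_function(0, c(1, 0, 0, 0, 0)), 1)
  expect_equal(coupling_function(pi / 2, c(0, 1, 0, 1, 0)), cos(pi / 2) + cos(pi))

  set.seed(11)
  x <- runif(100, -10, 10)
  co <- rnorm(5)
  expect_equal(coupling_function(x, co), coupling_function(x + 2 * pi, co),
               tolerance = 1e-12)
})

test_that("PRC kinds evaluate their periodic forms", {
  expect_equal(prc(c(0, pi / 2, 3 * pi / 2), "sine"), c(0, 1, -1))

  co <- c(0.1, 0.3, -0.2, 0.05, 0.4)
  x <- seq(-5, 5, length.out = 21)
  expect_equal(prc(x, "second_order_fourier", coefs = co),
               coupling_function(x, co))

  # tabulated sine recovered by interpolation
  grid <- seq(0, 2 * pi, length.out = 257)[-257]
  tab <- sin(grid)
  expect_equal(prc(x, "hodgkin_huxley_tabulated", table = tab), sin(x),
               tolerance = 1e-3)

  expect_error(prc(0, "nope"), class = "ernasim_configuration_error")
})

test_that("mean-field drive matches the brute-force pairwise sum", {
  # all phases equal: every entry is f(0)
  co <- c(0.3, -1.2, 0.4, 0.8, -0.5)
  ph <- rep(1.3, 6)
  expect_equal(mean_field_coupling_drive(ph, co),
               rep(co[1] + co[2] + co[4], 6))

  # two oscillators at 0 and pi with pure cos coupling: drives are zero
  expect_equal(mean_field_coupling_drive(c(0, pi), c(0, 1, 0, 0, 0)),
               c(0, 0), tolerance = 1e-15)

  # random instances vs the O(N^2) oracle
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    ph <- runif(n, 0, 2 * pi)
    co <- rnorm(5)
    got <- mean_field_coupling_drive(ph, co)
    want <- brute_force_drive(ph, co)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("order parameter is the complex mean of unit phasors", {
  z <- order_parameter(rep(0.7, 9))
  expect_equal(z, complex(modulus = 1, argument = 0.7))

  # uniformly spaced phases cancel
  expect_lt(Mod(order_parameter(2 * pi * (0:9) / 10)), 1e-12)

  expect_equal(order_parameter(c(0, pi / 2)), complex(real = .5, imaginary = .5))
  expect_equal(Mod(order_parameter(c(0, pi / 2))), sqrt(2) / 2)
})

test_that("noise-free uncoupled phases advance exactly linearly", {
  p <- quick_params(zeta = 0, sigma_hz = 0)
  omega <- sample_natural_frequencies(10, 3, 5, seed = 2)
  th <- runif(5, 0, 2 * pi)
  cur <- th
  for (i in 1:1000) {
    cur <- euler_maruyama_step(cur, omega, p, k_t = 0, I_t = 0)
  }
  expect_equal(cur, th + omega * 1000 * p$dt_s, tolerance = 1e-12)
})

test_that("symmetric coupled oscillators stay identical without noise", {
  p <- quick_params(zeta = 0)
  omega <- rep(2 * pi * 20, 4)
  cur <- rep(0.5, 4)
  for (i in 1:200) {
    cur <- euler_maruyama_step(cur, omega, p, k_t = 50, I_t = 0)
  }
  expect_equal(max(cur) - min(cur), 0)
  expect_true(all(is.finite(cur)))
})

test_that("single forced oscillator matches a high-accuracy ODE reference", {
  skip_if_not_installed("deSolve")
  # dtheta/dt = omega + I sin(theta), k = 0, zeta = 0
  omega <- 2 * pi * 5
  I <- 20
  p <- model_parameters(zeta = 0, dt_s = 1e-4)
  th <- 0.3
  for (i in seq_len(10000)) {
    th <- euler_maruyama_step(th, omega, p, k_t = 0, I_t = I)
  }
  ref <- deSolve::ode(y = c(theta = 0.3), times = c(0, 1), parms = NULL,
                      func = function(t, y, parms) list(omega + I * sin(y)),
                      method = "ode45", rtol = 1e-10, atol = 1e-10)
  expect_lt(abs(th - ref[2, "theta"]), 1e-3)
})

test_that("simulation traces respect their invariants", {
  sim <- simulate_erna(quick_params(), quick_protocol(), pools = quick_pools())
  expect_true(all(sim$abs_z <= 1 + 1e-12))
  expect_true(all(sim$n_rrp >= 0 & sim$n_rrp <= 1))
  expect_true(all(sim$n_rp >= 0 & sim$n_rp <= 1))
  expect_true(all(sim$n_rtp >= 0 & sim$n_rtp <= 1))
  expect_equal(nrow(sim), 3 / (2e-4))
  # pulses spaced by the stimulation period
  pt <- attr(sim, "pulse_times_s")
  expect_true(all(abs(diff(pt) - 1 / 130) < 1e-4)) # spacing up to grid rounding
})

test_that("all-off protocols keep coupling at its baseline", {
  sim <- simulate_erna(quick_params(), stim_protocol(seg_off(1)),
                       pools = quick_pools())
  p <- quick_params()
  expect_true(all(sim$k == p$kmu))
  expect_true(all(sim$dominant_pool == "RRP"))
})

test_that("identical seeds give bit-identical traces", {
  a <- simulate_erna(quick_params(seed = 5), quick_protocol())
  b <- simulate_erna(quick_params(seed = 5), quick_protocol())
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_erna(quick_params(seed = 6), quick_protocol())
  expect_false(identical(a$re_z, c$re_z))
})

test_that("doubling the network size leaves the mean-field scale unchanged", {
  # population-mean coupling: the drive magnitude must not grow with N
  set.seed(9)
  co <- c(-0.5, 1.5, 0, 0.3, 1.6)
  ph50 <- runif(50, 0, 2 * pi)
  ph200 <- runif(200, 0, 2 * pi)
  d50 <- mean_field_coupling_drive(ph50, co)
  d200 <- mean_field_coupling_drive(ph200, co)
  # both concentrate around f0 for uniform phases, independently of N
  expect_lt(abs(mean(d50) - co[1]), 0.5)
  expect_lt(abs(mean(d200) - co[1]), 0.25)
})
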