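test_that("welch spectrogram localizes pure tones", {
  fs <- 5000
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 300 * t)
  sg <- welch_spectrogram(x, fs, window_s = 1, overlap = 0.25)
  bin <- fs / 4096 # half-window segments zero-padded to NFFT
  peaks <- sg$frequency_hz[apply(sg$psd, 1, which.max)]
  expect_true(all(abs(peaks - 300) <= 2 * bin))
  expect_true(all(sg$psd >= 0))
})

test_that("constant signals put all power in the DC bin", {
  sg <- welch_spectrogram(rep(2, 1000), 1000, window_s = 1)
  p <- sg$psd[1, ]
  # all power concentrated at DC (within the taper's main lobe; the bin just
  # above DC can exceed the DC bin itself under one-sided doubling)
  expect_lt(sg$frequency_hz[which.max(p)], 5)
  # beyond the taper's main-lobe leakage everything is at the numerical floor
  far <- sg$frequency_hz > 10
  expect_lt(sum(p[far]) / sum(p), 1e-4)
})

test_that("welch PSD integrates to the signal power (Parseval)", {
  set.seed(5)
  fs <- 2000
  x <- sin(2 * pi * 130 * seq(0, 2, by = 1 / fs)) + rnorm(2 * fs + 1, sd = 0.3)
  sg <- welch_spectrogram(x, fs, window_s = 2)
  df <- sg$frequency_hz[2] - sg$frequency_hz[1]
  expect_equal(sum(sg$psd[1, ]) * df, mean(x^2), tolerance = 0.05)
})

test_that("spectrogram rejects degenerate inputs", {
  expect_error(welch_spectrogram(1:10, 1000, window_s = 1),
               class = "ernasim_invalid_argument")
  expect_error(welch_spectrogram(rnorm(100), 1000, window_s = 0.001),
               class = "ernasim_invalid_argument")
  expect_error(welch_spectrogram(rnorm(2000), 1000, window_s = 1, overlap = 1),
               class = "ernasim_invalid_argument")
})

test_that("peak frequency restricts to the requested band with inclusive edges", {
  fs <- 2000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 260 * t) + 0.3 * sin(2 * pi * 350 * t)
  sg <- welch_spectrogram(x, fs, window_s = 1)
  expect_true(all(abs(peak_frequency(sg, c(240, 400))$value - 260) < 2))
  expect_true(all(abs(peak_frequency(sg, c(300, 400))$value - 350) < 2))

  # single tone exactly at an inclusive band edge
  nfft <- 2048
  f_edge <- 240 * fs / fs # use a bin-aligned tone at 240.234... Hz
  f_bin <- sg$frequency_hz[which.min(abs(sg$frequency_hz - 240))]
  x2 <- sin(2 * pi * f_bin * t)
  sg2 <- welch_spectrogram(x2, fs, window_s = 1)
  expect_true(all(abs(peak_frequency(sg2, c(f_bin, 400))$value - f_bin) < 1e-9))

  expect_error(peak_frequency(sg, c(1500, 1600)),
               class = "ernasim_invalid_argument")
})

test_that("peak-frequency extraction tracks a chirp following the target curve", {
  fs <- 5000
  dt <- 1 / fs
  t <- seq(0, 60, by = dt)
  f_inst <- target_decay(t)
  phase <- 2 * pi * cumsum(f_inst) * dt
  x <- sin(phase)
  sg <- welch_spectrogram(x, fs, window_s = 1, overlap = 0)
  pk <- peak_frequency(sg, c(240, 400))
  want <- target_decay(pk$time_s)
  bin <- fs / 8192
  # within a bin plus the curve's drift across each window
  expect_true(all(abs(pk$value - want) < 6))
  expect_lt(mean(abs(pk$value - want)), 2.5)
})

test_that("erna amplitude is a moving mean of |Z| bounded in [0, 1]", {
  sim <- tibble::tibble(time_s = seq(0, 10, by = 1e-3),
                        abs_z = rep(0.7, 10001))
  amp <- erna_amplitude(sim, window_s = 1)
  expect_feature_series(amp)
  expect_true(all(abs(amp$value - 0.7) < 1e-12))

  sim$abs_z <- rep(1, 10001)
  expect_true(all(erna_amplitude(sim)$value == 1))

  # step from 0.2 to 0.8 produces a linear ramp across one window
  sim$abs_z <- ifelse(sim$time_s < 5, 0.2, 0.8)
  amp <- erna_amplitude(sim, window_s = 1, hop_s = 0.05)
  ramp <- amp[amp$time_s > 4.6 & amp$time_s < 5.4, ]
  expect_true(all(diff(ramp$value) > 0))
  expect_equal(amp$value[amp$time_s < 4.4], rep(0.2, sum(amp$time_s < 4.4)),
               tolerance = 1e-6)
  expect_equal(amp$value[which.min(abs(amp$time_s - 5))], 0.5, tolerance = 0.01)
})

test_that("measurement noise realizes the requested SNR", {
  set.seed(8)
  x <- sin(2 * pi * 40 * seq(0, 200, by = 1e-3))
  y <- add_measurement_noise(x, snr_db = 20, seed = 4)
  noise <- y - x
  expect_equal(mean(noise^2), 0.01 * mean(x^2), tolerance = 0.02)
  snr_est <- 10 * log10(mean(x^2) / mean(noise^2))
  expect_lt(abs(snr_est - 20), 0.2)

  # enormous SNR leaves the signal essentially untouched
  y2 <- add_measurement_noise(x, snr_db = 300, seed = 4)
  expect_equal(y2, x, tolerance = 1e-10)

  expect_error(add_measurement_noise(rep(0, 10), 20, 1),
               class = "ernasim_invalid_argument")
  expect_identical(add_measurement_noise(x, 20, seed = 4),
                   add_measurement_noise(x, 20, seed = 4))
})

test_that("aggregation computes pointwise mean and SEM", {
  fs1 <- tibble::tibble(time_s = 1:5, value = rep(0, 5), sem = NA_real_, n = 1L)
  fs2 <- tibble::tibble(time_s = 1:5, value = rep(2, 5), sem = NA_real_, n = 1L)
  agg <- aggregate_realizations(list(fs1, fs2))
  expect_equal(agg$value, rep(1, 5))
  expect_equal(agg$sem, rep(1, 5)) # sd = sqrt(2), sem = sqrt(2)/sqrt(2)
  expect_equal(agg$n[1], 2L)

  same <- aggregate_realizations(list(fs1, fs1, fs1))
  expect_equal(same$value, fs1$value)
  expect_equal(same$sem, rep(0, 5))

  bad <- tibble::tibble(time_s = 2:6, value = rep(1, 5), sem = NA_real_, n = 1L)
  expect_error(aggregate_realizations(list(fs1, bad)),
               class = "ernasim_invalid_argument")
})

test_that("aggregation SEM shrinks as 1/sqrt(n)", {
  make <- function(seed) {
    set.seed(seed)
    tibble::tibble(time_s = 1:100, value = rnorm(100), sem = NA_real_, n = 1L)
  }
  sem5 <- mean(aggregate_realizations(lapply(1:5, make))$sem)
  sem45 <- mean(aggregate_realizations(lapply(1:45, make))$sem)
  expect_equal(sem5 / sem45, 3, tolerance = 0.35)
})

test_that("phase clusters are counted by circular gap grouping", {
  expect_equal(phase_cluster_count(rep(1.2, 10), 0.3), 1L)
  two <- c(rnorm(10, 0, 0.02), rnorm(10, pi, 0.02))
  expect_equal(phase_cluster_count(two, pi / 4), 2L)
  n <- 8
  grid <- 2 * pi * (0:(n - 1)) / n
  expect_equal(phase_cluster_count(grid, 2 * pi / n - 0.01), 8L)
  expect_error(phase_cluster_count(grid, 4), class = "ernasim_invalid_argument")
})
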