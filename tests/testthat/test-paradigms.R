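# Paradigm tests run scaled-down protocols (short durations, few
# realizations) so the suite stays fast; the full published-length runs are
# exercised by the acceptance script.

test_that("fit-protocol paradigm aggregates frequency and amplitude with SEM", {
  run <- run_fit_protocol(quick_params(), quick_pools(), n_realizations = 3,
                          settle_s = 1, on_s = 5)
  expect_s3_class(run, "erna_paradigm")
  freq <- run$features[run$features$measure == "frequency_hz", ]
  amp <- run$features[run$features$measure == "amplitude", ]
  expect_gt(nrow(freq), 0)
  expect_true(all(freq$n == 3))
  expect_true(all(!is.na(freq$sem)))
  expect_true(all(freq$value >= 240 & freq$value <= 400))
  expect_true(all(amp$value >= 0 & amp$value <= 1))
  # output grid covers the stimulation window
  expect_gt(max(freq$time_s), 0.8 * 5)
  expect_error(run_fit_protocol(quick_params(), n_realizations = 0),
               class = "ernasim_invalid_argument")
})

test_that("long-term schedule alternates to 1200 s and the run returns to baseline", {
  sched <- default_longterm_schedule()
  expect_equal(sum(sched$duration_s), 1200)
  expect_true(all(sched$mode %in% c("off", "continuous")))
  expect_true(all(sched$f_stim_hz[sched$mode == "continuous"] == 130))

  # scaled-down on/off alternation: |Z| must return below the synchrony
  # threshold within each off-period (baseline return). Off-periods are kept
  # at a realistic length: dissolution of the stimulation-synchronized
  # cluster happens in the low-coupling window after termination.
  short <- stim_protocol(seg_off(4), seg_on(25, 130), seg_off(20),
                         seg_on(25, 130), seg_off(20))
  run <- run_longterm_onoff(quick_params(), quick_pools(), schedule = short,
                            snr_db = 20)
  sim <- run$sim
  for (t0 in c(29, 74)) { # start of each post-stimulation off-period
    win <- sim$abs_z[sim$time_s > t0 & sim$time_s < t0 + 20]
    expect_lt(min(win), 0.2)
  }
  expect_equal(unname(sim$n_rrp[1]), 1) # pools start fully occupied
  expect_s3_class(run$spectrogram, "erna_spectrogram")
})

test_that("frequency sweep validates its range and keeps seeds aligned", {
  expect_error(run_frequency_sweep(quick_params(), f_list = c(50, 130)),
               class = "ernasim_invalid_argument")
  run <- run_frequency_sweep(quick_params(), quick_pools(),
                             f_list = c(90, 130), n_realizations = 2,
                             settle_s = 1, on_s = 4)
  expect_equal(length(unique(run$features$condition)), 2)
  expect_true(all(table(run$features$condition) > 0))
})

test_that("amplitude sweep applies Ifact to both stimulation and release", {
  expect_error(run_amplitude_sweep(quick_params(), ifact_list = c(0.5)),
               class = "ernasim_invalid_argument")

  # Ifact = 1 reproduces the plain fit-protocol run bit-for-bit at equal seeds
  p <- quick_params(seed = 4)
  pools <- quick_pools()
  a <- simulate_erna(p, fit_protocol(1, 2, 130, ifact = 1), pools = pools)
  b <- simulate_erna(p, fit_protocol(1, 2, 130), pools = pools)
  expect_identical(a$re_z, b$re_z)

  # higher Ifact depletes pools faster at equal seeds
  hi <- simulate_erna(p, fit_protocol(1, 2, 130, ifact = 1.1), pools = pools)
  lo <- simulate_erna(p, fit_protocol(1, 2, 130, ifact = 0.8), pools = pools)
  expect_lt(min(hi$n_rtp), min(lo$n_rtp))
  expect_lt(mean(hi$k[hi$stim_on]), mean(lo$k[lo$stim_on]))
})

test_that("burst paradigm alternates RtP dominance in bursts with RRP recovery", {
  run <- run_burst_paradigm(quick_params(), quick_pools(), cdbs_s = 30,
                            burst_s = 6, n_realizations = 2)
  k <- run$coupling
  expect_true(all(c("time_s", "k_norm", "dominant_pool") %in% names(k)))
  # during cDBS the coupling decays to reserve-pool dominance
  expect_equal(k$dominant_pool[which.min(abs(k$time_s + 1))], "RtP")
  post <- k[k$time_s > 0, ]
  # bursts drop coupling to RtP dominance ...
  expect_true(any(post$dominant_pool == "RtP"))
  # ... and it recovers to RRP dominance between bursts
  late_in_period <- post[post$time_s %% 1 > 0.8, ]
  expect_gt(mean(late_in_period$dominant_pool == "RRP"), 0.5)
  # burst pulses per second = 10
  sched <- pulse_schedule(stim_protocol(seg_burst(6)), 1e-4)
  expect_equal(length(sched$pulse_steps), 60)
})

test_that("paradigm outputs are reproducible from the master seed", {
  r1 <- run_fit_protocol(quick_params(seed = 2), quick_pools(),
                         n_realizations = 2, settle_s = 1, on_s = 3)
  r2 <- run_fit_protocol(quick_params(seed = 2), quick_pools(),
                         n_realizations = 2, settle_s = 1, on_s = 3)
  expect_identical(r1$features, r2$features)
})

test_that("network size does not change the on-stimulation frequency course", {
  # population-mean coupling makes predictions N-robust: compare the late
  # on-stimulation peak frequency at N = 50 vs N = 200 over a few seeds
  late_peak <- function(n_osc, seed) {
    p <- quick_params(seed = seed, n_oscillators = n_osc)
    sim <- simulate_erna(p, fit_protocol(2, 10), pools = quick_pools())
    pk <- on_peak_series(sim, window_s = 1, overlap = 0)
    mean(tail(pk$value, 3))
  }
  f50 <- vapply(1:3, function(s) late_peak(50, s), numeric(1))
  f200 <- vapply(1:3, function(s) late_peak(200, s), numeric(1))
  sem <- function(x) sd(x) / sqrt(length(x))
  gap <- abs(mean(f50) - mean(f200))
  expect_lt(gap, 2 * (sem(f50) + sem(f200)) + 10)
})
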