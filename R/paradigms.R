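run_realizations <- function(params, protocol, pools, n_realizations,
                             initial_occupancy = c(1, 1, 1),
                             extract = function(sim, r) NULL) {
  if (n_realizations < 1) {
    abort("need at least one realization.", class = "ernasim_invalid_argument")
  }
  purrr::map(seq_len(n_realizations), function(r) {
    sim <- simulate_erna(params, protocol, pools = pools,
                         initial_occupancy = initial_occupancy,
                         realization = r)
    extract(sim, r)
  })
}

new_paradigm <- function(name, features, conditions, params, pools,
                         n_realizations, extra = list()) {
  structure(c(list(paradigm = name, features = features,
                   conditions = conditions, params = params, pools = pools,
                   n_realizations = n_realizations), extra),
            class = "erna_paradigm")
}

#' @export
print.erna_paradigm <- function(x, ...) {
  cat(sprintf("<erna_paradigm: %s> %d condition(s) x %d realization(s)\n",
              x$paradigm, length(x$conditions), x$n_realizations))
  print(x$features, n = 6)
  invisible(x)
}

#' Fitting-protocol paradigm: 130 Hz frequency decay with SEM band
#'
#' Simulates the fitting protocol (off-stimulation settling followed by
#' continuous 130 Hz stimulation) over several realizations of noise, natural
#' frequencies and initial conditions, and aggregates the on-stimulation
#' peak-frequency and amplitude time courses (mean and SEM) for comparison
#' with the empirical decay curve.
#'
#' @param params An `erna_parameters` (default: the reference fit).
#' @param pools An `erna_pools`.
#' @param n_realizations Number of realizations (published figures use 15).
#' @param settle_s,on_s Settling and stimulation durations (s).
#' @param f_stim_hz Stimulation frequency.
#' @param window_s Peak-frequency analysis window (default 1 s; the cost
#'   function uses 100 ms windows, figure-style output uses 1 s).
#' @param overlap Window overlap (default 0.5).
#' @return An `erna_paradigm` whose `features` tibble has one aggregated
#'   (mean, SEM, n) series per `measure` (`"frequency_hz"`, `"amplitude"`).
#' @export
run_fit_protocol <- function(params = reference_parameters(),
                             pools = vesicle_pool_parameters(),
                             n_realizations = 15,
                             settle_s = 20, on_s = 100, f_stim_hz = 130,
                             window_s = 1, overlap = 0.5) {
  protocol <- fit_protocol(settle_s, on_s, f_stim_hz)
  per <- run_realizations(params, protocol, pools, n_realizations,
                          extract = function(sim, r) {
    freq <- on_peak_series(sim, window_s = window_s, overlap = overlap)
    on <- sim[sim$stim_on, ]
    amp <- erna_amplitude(on, window_s = 1, hop_s = window_s * (1 - overlap))
    amp$time_s <- amp$time_s - min(on$time_s)
    list(freq = freq, amp = amp)
  })
  freq <- aggregate_realizations(purrr::map(per, "freq"))
  amp <- aggregate_realizations(purrr::map(per, "amp"))
  features <- dplyr::bind_rows(
    dplyr::mutate(freq, measure = "frequency_hz", condition = "130 Hz"),
    dplyr::mutate(amp, measure = "amplitude", condition = "130 Hz"))
  new_paradigm("fit_protocol", features, "130 Hz", params, pools,
               n_realizations)
}

#' Default long-term on/off stimulation schedule
#'
#' Alternating off and 130 Hz on periods of varying lengths summing to
#' 1200 s of continuous observation.
#'
#' @param f_stim_hz Stimulation frequency for the on-periods.
#' @return An `erna_protocol`.
#' @export
default_longterm_schedule <- function(f_stim_hz = 130) {
  stim_protocol(
    seg_off(50), seg_on(100, f_stim_hz), seg_off(50),
    seg_on(150, f_stim_hz), seg_off(100), seg_on(250, f_stim_hz),
    seg_off(50), seg_on(300, f_stim_hz), seg_off(100),
    seg_on(50, f_stim_hz))
}

#' Long-term on/off spectrogram paradigm
#'
#' One long trace under an alternating on/off schedule (1200 s by default),
#' started with all vesicle pools at 100% occupancy, with white measurement
#' noise added to `Re(Z)` at 20 dB SNR, analysed with a 1 s / 25% overlap
#' Welch spectrogram.
#'
#' @param params,pools Model and vesicle parameters.
#' @param schedule An `erna_protocol` alternating off/on segments.
#' @param snr_db Measurement-noise SNR in dB.
#' @param record_stride Recording stride for the (long) trace; the default 4
#'   records at 2.5 kHz, ample for the 0-400 Hz analysis band.
#' @return An `erna_paradigm` with the spectrogram, the noisy signal's
#'   feature series and the underlying trace summary.
#' @export
run_longterm_onoff <- function(params = reference_parameters(),
                               pools = vesicle_pool_parameters(),
                               schedule = default_longterm_schedule(),
                               snr_db = 20, record_stride = 4L) {
  sim <- simulate_erna(params, schedule, pools = pools,
                       record_stride = record_stride,
                       initial_occupancy = c(1, 1, 1))
  seeds <- attr(sim, "seeds")
  noisy <- add_measurement_noise(sim$re_z, snr_db = snr_db,
                                 seed = seeds[["measurement_noise"]])
  fs <- attr(sim, "sample_rate_hz")
  sg <- welch_spectrogram(noisy, fs, window_s = 1, overlap = 0.25,
                          t0 = sim$time_s[1])
  sched <- pulse_schedule(schedule, params$dt_s)
  win_on <- sched$stim_on_at(sg$window_center_s)
  peaks_on <- peak_frequency(sg, band = c(240, 400))
  peaks_off <- peak_frequency(sg, band = c(1, 100))
  features <- dplyr::bind_rows(
    dplyr::mutate(peaks_on[win_on, ], measure = "frequency_hz",
                  condition = "on"),
    dplyr::mutate(peaks_off[!win_on, ], measure = "frequency_hz",
                  condition = "off"))
  new_paradigm("longterm_onoff", features, c("on", "off"), params, pools, 1L,
               extra = list(spectrogram = sg, sim = sim, snr_db = snr_db,
                            stim_on_at = sched$stim_on_at))
}

#' Stimulation-frequency sweep paradigm
#'
#' Re-runs the fitting protocol at several stimulation frequencies within the
#' clinically used 70-180 Hz range, with identical seeds across conditions so
#' differences are condition-driven. No parameter other than the pulse-train
#' frequency changes.
#'
#' @param params,pools Model and vesicle parameters.
#' @param f_list Stimulation frequencies (Hz), all within `[70, 180]`.
#' @param n_realizations Realizations per condition.
#' @param settle_s,on_s Protocol durations.
#' @param window_s,overlap Analysis windows for the feature series.
#' @return An `erna_paradigm` with aggregated frequency and amplitude series
#'   per condition.
#' @export
run_frequency_sweep <- function(params = reference_parameters(),
                                pools = vesicle_pool_parameters(),
                                f_list = c(90, 130, 150, 180),
                                n_realizations = 15,
                                settle_s = 20, on_s = 100,
                                window_s = 1, overlap = 0.5) {
  if (any(f_list < 70 | f_list > 180)) {
    abort("stimulation frequencies must lie within the 70-180 Hz clinical range.",
          class = "ernasim_invalid_argument")
  }
  feats <- purrr::map(f_list, function(f) {
    run <- run_fit_protocol(params, pools, n_realizations, settle_s, on_s,
                            f_stim_hz = f, window_s = window_s,
                            overlap = overlap)
    dplyr::mutate(run$features, condition = sprintf("%g Hz", f))
  })
  new_paradigm("frequency_sweep", dplyr::bind_rows(feats),
               sprintf("%g Hz", f_list), params, pools, n_realizations)
}

#' Stimulation-amplitude sweep paradigm
#'
#' Re-runs the fitting protocol at several amplitude factors `Ifact` in
#' `[0.8, 1.1]`. `Ifact` scales the stimulation intensity and every pool's
#' per-pulse release probability jointly; `Ifact = 1` is the fitted operating
#' point and reproduces the fit-protocol run bit-for-bit at equal seeds.
#'
#' @param params,pools Model and vesicle parameters.
#' @param ifact_list Amplitude factors, all in `[0.8, 1.1]`.
#' @inheritParams run_frequency_sweep
#' @return An `erna_paradigm` with aggregated series per condition.
#' @export
run_amplitude_sweep <- function(params = reference_parameters(),
                                pools = vesicle_pool_parameters(),
                                ifact_list = c(0.8, 0.9, 1.0, 1.1),
                                n_realizations = 15,
                                settle_s = 20, on_s = 100,
                                window_s = 1, overlap = 0.5) {
  if (any(ifact_list < 0.8 | ifact_list > 1.1)) {
    abort("Ifact must lie within [0.8, 1.1].",
          class = "ernasim_invalid_argument")
  }
  feats <- purrr::map(ifact_list, function(ifa) {
    protocol <- fit_protocol(settle_s, on_s, 130, ifact = ifa)
    per <- run_realizations(params, protocol, pools, n_realizations,
                            extract = function(sim, r) {
      freq <- on_peak_series(sim, window_s = window_s, overlap = overlap)
      on <- sim[sim$stim_on, ]
      amp <- erna_amplitude(on, window_s = 1,
                            hop_s = window_s * (1 - overlap))
      amp$time_s <- amp$time_s - min(on$time_s)
      list(freq = freq, amp = amp)
    })
    freq <- aggregate_realizations(purrr::map(per, "freq"))
    amp <- aggregate_realizations(purrr::map(per, "amp"))
    dplyr::bind_rows(
      dplyr::mutate(freq, measure = "frequency_hz",
                    condition = sprintf("Ifact %.2g", ifa)),
      dplyr::mutate(amp, measure = "amplitude",
                    condition = sprintf("Ifact %.2g", ifa)))
  })
  new_paradigm("amplitude_sweep", dplyr::bind_rows(feats),
               sprintf("Ifact %.2g", ifact_list), params, pools,
               n_realizations)
}

#' Post-stimulation bursting paradigm
#'
#' Continuous 130 Hz stimulation long enough to reach reserve-pool (RtP)
#' dominance, terminated at time zero, followed by one 10-pulse 130 Hz burst
#' per second for 20 s. Outputs the frequency and amplitude time courses and
#' the coupling-strength trace normalized by `kmu`, with the dominant pool
#' annotated per sample.
#'
#' @param params,pools Model and vesicle parameters.
#' @param cdbs_s Duration of the preceding continuous stimulation (s).
#' @param burst_s Duration of the bursting period (s, default 20).
#' @param n_realizations Realizations for the feature series.
#' @param window_s,overlap Feature analysis windows.
#' @return An `erna_paradigm`; `coupling` holds the normalized k-trace of the
#'   first realization with times relative to cDBS termination.
#' @export
run_burst_paradigm <- function(params = reference_parameters(),
                               pools = vesicle_pool_parameters(),
                               cdbs_s = 90, burst_s = 20,
                               n_realizations = 15,
                               window_s = 1, overlap = 0.5) {
  protocol <- stim_protocol(
    seg_on(cdbs_s, 130),
    seg_burst(burst_s, pulses_per_burst = 10, intra_burst_rate_hz = 130,
              burst_period_s = 1))
  per <- run_realizations(params, protocol, pools, n_realizations,
                          extract = function(sim, r) {
    burst <- sim[sim$time_s >= cdbs_s, ]
    fs <- attr(sim, "sample_rate_hz")
    sg <- welch_spectrogram(burst$re_z, fs, window_s = window_s,
                            overlap = overlap, t0 = 0)
    freq <- peak_frequency(sg, band = c(240, 400))
    amp <- erna_amplitude(burst, window_s = 1,
                          hop_s = window_s * (1 - overlap))
    amp$time_s <- amp$time_s - cdbs_s
    coupling <- if (r == 1) {
      tibble(time_s = sim$time_s - cdbs_s, k_norm = sim$k / params$kmu,
             dominant_pool = sim$dominant_pool)
    } else NULL
    list(freq = freq, amp = amp, coupling = coupling)
  })
  freq <- aggregate_realizations(purrr::map(per, "freq"))
  amp <- aggregate_realizations(purrr::map(per, "amp"))
  features <- dplyr::bind_rows(
    dplyr::mutate(freq, measure = "frequency_hz", condition = "burst"),
    dplyr::mutate(amp, measure = "amplitude", condition = "burst"))
  new_paradigm("burst", features, "burst", params, pools, n_realizations,
               extra = list(coupling = per[[1]]$coupling, cdbs_s = cdbs_s,
                            burst_s = burst_s))
}
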