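next_pow2 <- function(n) {
  2^ceiling(log2(n))
}

# Welch PSD of one signal chunk: Hann-tapered segments of half the chunk
# length with 50% overlap, zero-padded to NFFT = next power of two >= chunk
# length, one-sided density normalization (power / Hz).
welch_psd_chunk <- function(x, fs, nfft = next_pow2(length(x))) {
  n <- length(x)
  seg_len <- max(8L, n %/% 2L)
  hop <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))  # Hann
  norm <- fs * sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    X <- fft(c(seg, numeric(nfft - seg_len)))
    p <- Mod(X[seq_len(nfft %/% 2 + 1)])^2 / norm
    # one-sided: double everything except DC and Nyquist
    p[2:(nfft %/% 2)] <- 2 * p[2:(nfft %/% 2)]
    acc <- acc + p
  }
  acc / length(starts)
}

#' Welch spectrogram
#'
#' Splits a real signal into (possibly overlapping) analysis windows and
#' computes a Welch power spectral density in each: Hann-tapered segments of
#' half the window length with 50% overlap, zero-padded to the next power of
#' two at or above the window length. The published analyses use 1 s windows
#' with 25% overlap for long recordings and 100 ms windows with 50% overlap
#' for short ones; both are parameters here. No notch filters are applied.
#'
#' @param signal Real numeric series (normally `Re(Z)` of a simulation).
#' @param sample_rate Sampling rate in Hz.
#' @param window_s Analysis-window length in seconds.
#' @param overlap Fraction of window overlap between consecutive windows,
#'   in `[0, 1)`.
#' @param t0 Time of the first sample (s), used for window-center times.
#' @return An object of class `erna_spectrogram`: a list with
#'   `window_center_s`, `frequency_hz`, and `psd` (windows x frequencies
#'   matrix, power/Hz).
#' @export
#' @examples
#' x <- sin(2 * pi * 300 * seq(0, 2, by = 1 / 5000))
#' sg <- welch_spectrogram(x, 5000, window_s = 1)
#' f <- sg$frequency_hz[apply(sg$psd, 1, which.max)]
#' all(abs(f - 300) < 5000 / 4096)
welch_spectrogram <- function(signal, sample_rate, window_s,
                              overlap = 0.25, t0 = 0) {
  win_n <- as.integer(round(window_s * sample_rate))
  if (win_n < 8) {
    abort("analysis window must cover at least 8 samples.",
          class = "ernasim_invalid_argument")
  }
  if (overlap < 0 || overlap >= 1) {
    abort("`overlap` must lie in [0, 1).", class = "ernasim_invalid_argument")
  }
  if (length(signal) < win_n) {
    abort("signal is shorter than one analysis window.",
          class = "ernasim_invalid_argument")
  }
  hop <- max(1L, as.integer(round(win_n * (1 - overlap))))
  starts <- seq(1L, length(signal) - win_n + 1L, by = hop)
  nfft <- next_pow2(win_n)
  freq <- (0:(nfft %/% 2)) * sample_rate / nfft
  psd <- matrix(0, nrow = length(starts), ncol = length(freq))
  for (i in seq_along(starts)) {
    chunk <- signal[starts[i]:(starts[i] + win_n - 1L)]
    psd[i, ] <- welch_psd_chunk(chunk, sample_rate, nfft)
  }
  centers <- t0 + (starts - 1L + (win_n - 1) / 2) / sample_rate
  structure(list(window_center_s = centers, frequency_hz = freq, psd = psd,
                 window_s = window_s, overlap = overlap,
                 sample_rate_hz = sample_rate),
            class = "erna_spectrogram")
}

#' @export
print.erna_spectrogram <- function(x, ...) {
  cat(sprintf("<erna_spectrogram> %d windows (%.3g s, %.0f%% overlap), %d frequencies up to %.4g Hz\n",
              nrow(x$psd), x$window_s, 100 * x$overlap,
              length(x$frequency_hz), max(x$frequency_hz)))
  invisible(x)
}

#' @export
tidy.erna_spectrogram <- function(x, ...) {
  tibble(
    time_s = rep(x$window_center_s, times = length(x$frequency_hz)),
    frequency_hz = rep(x$frequency_hz, each = length(x$window_center_s)),
    psd = as.vector(x$psd)
  )
}

#' Peak-frequency time course
#'
#' For each spectrogram window, the frequency of maximum power spectral
#' density restricted to a band (inclusive edges). Ties break toward the
#' lower frequency. The on-stimulation ERNA band is 240-400 Hz; the
#' off-stimulation low-frequency band is 1-100 Hz.
#'
#' @param spectrogram An `erna_spectrogram`.
#' @param band Length-2 numeric, frequency band in Hz.
#' @return A feature-series tibble with columns `time_s`, `value` (Hz),
#'   `sem` (NA for single series) and `n` (1).
#' @export
peak_frequency <- function(spectrogram, band = c(240, 400)) {
  sel <- which(spectrogram$frequency_hz >= band[1] &
                 spectrogram$frequency_hz <= band[2])
  if (length(sel) == 0) {
    abort("no spectrogram frequencies inside the requested band.",
          class = "ernasim_invalid_argument")
  }
  f_band <- spectrogram$frequency_hz[sel]
  peak <- apply(spectrogram$psd[, sel, drop = FALSE], 1,
                function(p) f_band[which.max(p)])
  tibble(time_s = spectrogram$window_center_s, value = peak,
         sem = NA_real_, n = 1L)
}

#' ERNA amplitude time course
#'
#' Moving-window mean of the order-parameter modulus `|Z|`, the model's ERNA
#' amplitude surrogate (bounded in `[0, 1]` by construction).
#'
#' @param sim An `erna_sim` (or any tibble with `time_s` and `abs_z`).
#' @param window_s Averaging window in seconds (default 1).
#' @param hop_s Spacing of output samples (default `window_s / 2`).
#' @return A feature-series tibble (`time_s`, `value`, `sem`, `n`).
#' @export
erna_amplitude <- function(sim, window_s = 1, hop_s = window_s / 2) {
  dt <- sim$time_s[2] - sim$time_s[1]
  win_n <- as.integer(round(window_s / dt))
  if (win_n > nrow(sim)) {
    abort("averaging window exceeds the trace duration.",
          class = "ernasim_invalid_argument")
  }
  hop_n <- max(1L, as.integer(round(hop_s / dt)))
  cs <- cumsum(c(0, sim$abs_z))
  starts <- seq(1L, nrow(sim) - win_n + 1L, by = hop_n)
  means <- (cs[starts + win_n] - cs[starts]) / win_n
  centers <- sim$time_s[1] + (starts - 1L + (win_n - 1) / 2) * dt
  tibble(time_s = centers, value = means, sem = NA_real_, n = 1L)
}

#' Add white Gaussian measurement noise at a given SNR
#'
#' Adds zero-mean white Gaussian noise whose power is
#' `signal power / 10^(snr_db / 10)` (signal power measured from the input,
#' as MATLAB's `awgn(x, snr, 'measured')` does). Deterministic given `seed`.
#'
#' @param signal Real numeric series with nonzero power.
#' @param snr_db Signal-to-noise ratio in dB (default 20).
#' @param seed Integer seed for the noise draw.
#' @return The noisy series.
#' @export
add_measurement_noise <- function(signal, snr_db = 20, seed = 1) {
  pw <- mean(signal^2)
  if (!is.finite(pw) || pw <= 0) {
    abort("signal must have nonzero power.", class = "ernasim_invalid_argument")
  }
  noise_sd <- sqrt(pw / 10^(snr_db / 10))
  signal + noise_sd * cpp_rnorm_seeded(length(signal), seed)
}

#' Aggregate feature series across realizations
#'
#' Pointwise mean and standard error of the mean across realizations sharing
#' one time grid (the published figures average 15 realizations of noise,
#' natural frequencies and initial conditions).
#'
#' @param series_list List of feature-series tibbles with identical `time_s`.
#' @return A feature-series tibble with `sem = sd / sqrt(n)`.
#' @export
aggregate_realizations <- function(series_list) {
  if (length(series_list) == 0) {
    abort("need at least one series.", class = "ernasim_invalid_argument")
  }
  times <- series_list[[1]]$time_s
  for (s in series_list[-1]) {
    if (length(s$time_s) != length(times) ||
        any(abs(s$time_s - times) > 1e-9)) {
      abort("all series must share the same time grid.",
            class = "ernasim_invalid_argument")
    }
  }
  vals <- vapply(series_list, function(s) s$value, numeric(length(times)))
  vals <- matrix(vals, nrow = length(times))
  n <- length(series_list)
  m <- rowMeans(vals)
  sem <- if (n > 1) apply(vals, 1, sd) / sqrt(n) else rep(NA_real_, length(times))
  tibble(time_s = times, value = m, sem = sem, n = n)
}

#' Count phase clusters
#'
#' Single-linkage clustering of phases on the circle: sorted wrapped phases
#' are split wherever the circular gap between neighbours exceeds
#' `threshold`; the number of groups is the cluster count. A diagnostic for
#' the clustering behaviour that underlies the model's off-stimulation
#' low-frequency rhythm.
#'
#' @param phases Phase vector (rad).
#' @param threshold Gap threshold in rad, in `(0, pi)`.
#' @return Integer cluster count (at least 1).
#' @export
phase_cluster_count <- function(phases, threshold) {
  if (threshold <= 0 || threshold >= pi) {
    abort("`threshold` must lie in (0, pi).", class = "ernasim_invalid_argument")
  }
  x <- sort(phases %% (2 * pi))
  if (length(x) == 1) return(1L)
  gaps <- c(diff(x), x[1] + 2 * pi - x[length(x)])
  max(1L, sum(gaps > threshold))
}
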