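#' Model parameters for the oscillator network
#'
#' Bundles every scalar of the stochastic phase-oscillator network: the
#' population size, the normal distribution the natural frequencies are drawn
#' from, the baseline coupling strength, the intrinsic noise level, the
#' stimulation intensity, the second-order Fourier coupling function, the
#' phase-response curve (PRC) and the integration timestep.
#'
#' Default values are the package's reference fitted parameter set, produced
#' by the package's own pattern search against the empirical on-stimulation
#' peak-frequency decay curve (see [reference_parameters()] and the methods
#' vignette).
#'
#' @param n_oscillators Number of phase oscillators (default 50).
#' @param omega_hz Mean of the natural-frequency distribution, in Hz.
#' @param sigma_hz Standard deviation of the natural-frequency distribution,
#'   in Hz (must be non-negative).
#' @param kmu Baseline (off-stimulation, fully replenished) coupling strength,
#'   in rad/s per unit coupling-function output.
#' @param zeta Intrinsic noise standard deviation, in rad/sqrt(s).
#' @param stim_amplitude Stimulation intensity `I`, in rad/s per unit PRC
#'   output; the effective intensity of a pulse is `I * Ifact`.
#' @param coupling Numeric vector of the five Fourier coefficients
#'   `c(f0, f1, f2, f3, f4)` of the coupling function
#'   `f(x) = f0 + f1 cos(x) + f2 sin(x) + f3 cos(2x) + f4 sin(2x)`.
#' @param prc_kind One of `"sine"` (default, `g(x) = sin(x)`),
#'   `"second_order_fourier"` (coefficients in `prc_coefs`), or
#'   `"hodgkin_huxley_tabulated"` (tabulated periodic curve in `prc_table`).
#' @param prc_coefs Fourier coefficients `c(g0..g4)` of the PRC when
#'   `prc_kind = "second_order_fourier"`.
#' @param prc_table Numeric vector of PRC values on a uniform phase grid over
#'   `[0, 2*pi)` when `prc_kind = "hodgkin_huxley_tabulated"`; evaluated with
#'   periodic linear interpolation.
#' @param dt_s Integration timestep in seconds (default `1e-4`).
#' @param seed Master seed (integer) from which all per-realization child
#'   seeds are derived; see [seed_tree()].
#'
#' @return An object of class `erna_parameters` (a validated list).
#' @export
#' @examples
#' p <- model_parameters(omega_hz = 250, sigma_hz = 5)
#' p$n_oscillators
model_parameters <- function(n_oscillators = 50,
                             omega_hz = 158,
                             sigma_hz = 8,
                             kmu = 3582.41118430775,
                             zeta = 17,
                             stim_amplitude = 300,
                             coupling = c(-0.5012, 1.334, -0.45, 0.3, 1.45),
                             prc_kind = c("sine", "second_order_fourier",
                                          "hodgkin_huxley_tabulated"),
                             prc_coefs = c(0, 0, 1, 0, 0),
                             prc_table = NULL,
                             dt_s = 1e-4,
                             seed = 1L) {
  prc_kind <- match.arg(prc_kind)
  if (!is.numeric(n_oscillators) || n_oscillators < 2) {
    abort("`n_oscillators` must be at least 2.", class = "ernasim_invalid_argument")
  }
  if (sigma_hz < 0) {
    abort("`sigma_hz` must be non-negative.", class = "ernasim_invalid_argument")
  }
  if (dt_s <= 0) {
    abort("`dt_s` must be positive.", class = "ernasim_invalid_argument")
  }
  if (zeta < 0) {
    abort("`zeta` must be non-negative.", class = "ernasim_invalid_argument")
  }
  if (length(coupling) != 5 || !is.numeric(coupling)) {
    abort("`coupling` must be the five Fourier coefficients f0..f4.",
          class = "ernasim_invalid_argument")
  }
  if (prc_kind == "second_order_fourier" &&
      (length(prc_coefs) != 5 || !is.numeric(prc_coefs))) {
    abort("`prc_coefs` must be the five Fourier coefficients g0..g4.",
          class = "ernasim_invalid_argument")
  }
  if (prc_kind == "hodgkin_huxley_tabulated" &&
      (is.null(prc_table) || length(prc_table) < 8)) {
    abort("`prc_table` must tabulate the PRC on at least 8 grid points.",
          class = "ernasim_configuration_error")
  }
  structure(
    list(
      n_oscillators = as.integer(n_oscillators),
      omega_hz = omega_hz,
      sigma_hz = sigma_hz,
      kmu = kmu,
      zeta = zeta,
      stim_amplitude = stim_amplitude,
      coupling = as.numeric(coupling),
      prc_kind = prc_kind,
      prc_coefs = as.numeric(prc_coefs),
      prc_table = if (is.null(prc_table)) numeric(0) else as.numeric(prc_table),
      dt_s = dt_s,
      seed = as.integer(seed)
    ),
    class = "erna_parameters"
  )
}

#' @export
print.erna_parameters <- function(x, ...) {
  cat("<erna_parameters>\n")
  cat(sprintf("  N = %d oscillators, omega = %.4g Hz (sd %.4g Hz)\n",
              x$n_oscillators, x$omega_hz, x$sigma_hz))
  cat(sprintf("  kmu = %.6g rad/s, zeta = %.4g rad/sqrt(s), I = %.6g rad/s\n",
              x$kmu, x$zeta, x$stim_amplitude))
  cat(sprintf("  coupling f0..f4 = (%s)\n",
              paste(signif(x$coupling, 5), collapse = ", ")))
  cat(sprintf("  PRC: %s, dt = %g s, seed = %d\n",
              x$prc_kind, x$dt_s, x$seed))
  invisible(x)
}

#' Vesicle pool parameters
#'
#' Per-pool replenishment time constant, per-pulse release probability, and
#' pool-coupling factor for the readily-releasable (RRP), recycling (RP) and
#' reserve (RtP) vesicle pools. The dominant-pool rule maps occupancies to
#' coupling strength as `k(t) = kmu * max(M_pool * n_pool)`; `M_RRP` is fixed
#' at 1 so that the fully replenished, off-stimulation coupling strength is
#' exactly `kmu`.
#'
#' @param tau_s Length-3 numeric: replenishment time constants (s) for
#'   RRP, RP, RtP. Must be strictly increasing.
#' @param p_release Length-3 numeric in (0,1): per-pulse release
#'   probabilities. Must be strictly decreasing.
#' @param M Length-3 numeric: pool-coupling factors; `M[1]` must be 1.
#'
#' @return An object of class `erna_pools`.
#' @seealso [calibrate_pool_parameters()] which produces the shipped defaults
#'   from the pools' depletion/replenishment timescales.
#' @export
vesicle_pool_parameters <- function(tau_s = c(0.667616401390668,
                                              2.67046560556267,
                                              40.0569840834401),
                                    p_release = c(0.237759893796735,
                                                  0.0114469053430611,
                                                  1.91863682891813e-4),
                                    M = c(1, 0.6, 0.3)) {
  stopifnot(length(tau_s) == 3, length(p_release) == 3, length(M) == 3)
  if (any(tau_s <= 0)) {
    abort("replenishment time constants must be positive.",
          class = "ernasim_invalid_argument")
  }
  if (!(tau_s[1] < tau_s[2] && tau_s[2] < tau_s[3])) {
    abort("pools must replenish on increasing timescales (tau_RRP < tau_RP < tau_RtP).",
          class = "ernasim_invalid_argument")
  }
  if (any(p_release <= 0) || any(p_release >= 1)) {
    abort("release probabilities must lie in (0, 1).",
          class = "ernasim_invalid_argument")
  }
  if (!(p_release[1] > p_release[2] && p_release[2] > p_release[3])) {
    abort("release probabilities must decrease (p_RRP > p_RP > p_RtP).",
          class = "ernasim_invalid_argument")
  }
  if (any(M < 0)) {
    abort("pool-coupling factors must be non-negative.",
          class = "ernasim_invalid_argument")
  }
  if (M[1] != 1) {
    abort("M_RRP must be 1 (normalization: off-stimulation k equals kmu).",
          class = "ernasim_invalid_argument")
  }
  structure(
    list(
      pool = c("RRP", "RP", "RtP"),
      tau_s = as.numeric(tau_s),
      p_release = as.numeric(p_release),
      M = as.numeric(M)
    ),
    class = "erna_pools"
  )
}

#' @export
print.erna_pools <- function(x, ...) {
  cat("<erna_pools>\n")
  df <- data.frame(pool = x$pool, tau_s = x$tau_s,
                   p_release = x$p_release, M = x$M)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Reference fitted parameter set
#'
#' The package's reference fit of the oscillator-network parameters to the
#' empirical on-stimulation ERNA peak-frequency decay curve
#' (`260 + 80 exp(-0.07 t)` Hz), produced by the package's own generalized
#' pattern search under the fitting protocol (20 s off, then 100 s of 130 Hz
#' stimulation), with the off-stimulation hypersynchrony penalty. The fit and
#' its provenance are described in the methods vignette.
#'
#' @param seed Master seed stored in the returned parameter object.
#' @return An `erna_parameters` object.
#' @export
reference_parameters <- function(seed = 1L) {
  model_parameters(seed = seed)
}
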