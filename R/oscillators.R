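#' Sample oscillator natural frequencies
#'
#' Natural frequencies are drawn from a normal distribution with mean
#' `omega_hz` and standard deviation `sigma_hz` (both in Hz) and converted to
#' angular frequency (rad/s). Sampling is deterministic given `seed` and uses
#' the package's own generator, so it is independent of R's global RNG state.
#'
#' @param omega_hz Mean natural frequency in Hz.
#' @param sigma_hz Standard deviation in Hz (non-negative).
#' @param n Number of oscillators (at least 2).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, natural frequencies in rad/s.
#' @export
#' @examples
#' w <- sample_natural_frequencies(250, 0, n = 3, seed = 1)
#' all(w == 2 * pi * 250)
sample_natural_frequencies <- function(omega_hz, sigma_hz, n, seed) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    abort("`n` must be a count of at least 2.", class = "ernasim_invalid_argument")
  }
  if (sigma_hz < 0) {
    abort("`sigma_hz` must be non-negative.", class = "ernasim_invalid_argument")
  }
  hz <- omega_hz + sigma_hz * cpp_rnorm_seeded(as.integer(n), seed)
  2 * pi * hz
}

#' Simplified DBS pulse-train indicator
#'
#' The stimulation pulse train takes value 1 at grid time `t` when
#' `t mod (1/f_stim) < dt` and 0 otherwise, i.e. each pulse lasts exactly one
#' integration timestep.
#'
#' @param t Time (s), scalar or vector.
#' @param f_stim Stimulation frequency in Hz (positive).
#' @param dt Integration timestep in seconds; must satisfy `dt < 1/f_stim` or
#'   consecutive pulses would merge.
#' @return Integer vector of 0/1 indicators.
#' @export
pulse_train_value <- function(t, f_stim, dt) {
  if (f_stim <= 0 || dt <= 0) {
    abort("`f_stim` and `dt` must be positive.", class = "ernasim_invalid_argument")
  }
  if (dt >= 1 / f_stim) {
    abort("`dt` must be smaller than the stimulation period 1/f_stim.",
          class = "ernasim_invalid_argument")
  }
  period <- 1 / f_stim
  r <- t %% period
  # resolve floating-point ties at exact period boundaries to a single pulse
  eps <- period * 1e-9
  as.integer(r < dt - eps | r > period - eps)
}

#' Second-order Fourier series coupling function
#'
#' `f(x) = f0 + f1 cos(x) + f2 sin(x) + f3 cos(2x) + f4 sin(2x)`, a
#' 2*pi-periodic function of pairwise phase differences.
#'
#' @param x Phase difference(s) in rad.
#' @param coefs Numeric vector `c(f0, f1, f2, f3, f4)`.
#' @return Numeric vector of coupling-function values.
#' @export
coupling_function <- function(x, coefs) {
  stopifnot(length(coefs) == 5)
  coefs[1] + coefs[2] * cos(x) + coefs[3] * sin(x) +
    coefs[4] * cos(2 * x) + coefs[5] * sin(2 * x)
}

#' Phase response curve
#'
#' Evaluates the 2*pi-periodic phase response curve. The default sinusoidal
#' PRC is `g(x) = sin(x)`; a second-order Fourier PRC uses the coefficients
#' `g0..g4`; a tabulated PRC (e.g. derived from a Hodgkin-Huxley neuron) is
#' evaluated by periodic linear interpolation of values given on a uniform
#' phase grid over `[0, 2*pi)`.
#'
#' @param theta Phase(s) in rad.
#' @param kind One of `"sine"`, `"second_order_fourier"`,
#'   `"hodgkin_huxley_tabulated"`.
#' @param coefs Fourier coefficients (length 5) for the Fourier PRC.
#' @param table Tabulated values for the tabulated PRC.
#' @return Numeric vector of phase responses.
#' @export
prc <- function(theta, kind = "sine", coefs = NULL, table = NULL) {
  if (kind == "sine") {
    return(sin(theta))
  }
  if (kind == "second_order_fourier") {
    if (is.null(coefs) || length(coefs) != 5) {
      abort("a second-order Fourier PRC needs coefficients g0..g4.",
            class = "ernasim_configuration_error")
    }
    return(coupling_function(theta, coefs))
  }
  if (kind == "hodgkin_huxley_tabulated") {
    if (is.null(table) || length(table) < 8) {
      abort("a tabulated PRC needs at least 8 grid values.",
            class = "ernasim_configuration_error")
    }
    n <- length(table)
    x <- theta %% (2 * pi)
    u <- x * n / (2 * pi)
    i0 <- pmin(floor(u), n - 1)
    w <- u - i0
    i1 <- (i0 + 1) %% n
    return(table[i0 + 1] * (1 - w) + table[i1 + 1] * w)
  }
  abort(sprintf("unknown PRC kind '%s'.", kind),
        class = "ernasim_configuration_error")
}

#' Mean-field coupling drive
#'
#' For each oscillator i, the population average of `f(theta_j - theta_i)`
#' over all j, computed in O(N) from the first and second circular moments of
#' the phase distribution. This is the coupling drive entering the phase
#' equation (before multiplication by the coupling strength `k(t)`).
#'
#' @param phases Phase vector (rad), length at least 2.
#' @param coefs Coupling-function coefficients `c(f0..f4)`.
#' @return Numeric vector of per-oscillator drives.
#' @export
mean_field_coupling_drive <- function(phases, coefs) {
  if (length(phases) < 2) {
    abort("need at least 2 oscillators.", class = "ernasim_invalid_argument")
  }
  stopifnot(length(coefs) == 5)
  c1 <- mean(cos(phases)); s1 <- mean(sin(phases))
  c2 <- mean(cos(2 * phases)); s2 <- mean(sin(2 * phases))
  cs <- cos(phases); sn <- sin(phases)
  cs2 <- cos(2 * phases); sn2 <- sin(2 * phases)
  coefs[1] +
    coefs[2] * (c1 * cs + s1 * sn) +
    coefs[3] * (s1 * cs - c1 * sn) +
    coefs[4] * (c2 * cs2 + s2 * sn2) +
    coefs[5] * (s2 * cs2 - c2 * sn2)
}

#' Kuramoto order parameter
#'
#' The complex mean of unit phasors, `Z = mean(exp(1i * theta))`. Its modulus
#' measures network synchrony (`|Z| = 1` at full synchrony, ~0 for an
#' incoherent population) and its real part serves as the recorded-signal
#' surrogate.
#'
#' @param phases Phase vector in rad.
#' @return A complex scalar.
#' @export
#' @examples
#' Mod(order_parameter(c(0, pi))) < 1e-15
order_parameter <- function(phases) {
  if (length(phases) < 1) {
    abort("need at least one phase.", class = "ernasim_invalid_argument")
  }
  mean(complex(real = cos(phases), imaginary = sin(phases)))
}

#' Single Euler-Maruyama step (reference implementation)
#'
#' Advances the phase vector by one timestep:
#' `theta_i <- theta_i + (omega_i + k * drive_i + I * g(theta_i)) * dt
#'  + zeta * sqrt(dt) * xi_i`.
#' This R implementation mirrors the compiled integrator one step at a time
#' and is used for small-scale verification; production simulations run
#' through [simulate_erna()].
#'
#' @param phases Phase vector (rad).
#' @param omega Natural frequencies (rad/s), same length.
#' @param params An `erna_parameters` object (supplies coupling coefficients,
#'   PRC, `zeta` and `dt_s`).
#' @param k_t Coupling strength at this step (rad/s per unit drive).
#' @param I_t Stimulation intensity at this step (rad/s per unit PRC output).
#' @param noise_draw Standard-normal vector, same length as `phases` (the
#'   Wiener increments divided by `sqrt(dt)`); defaults to zeros.
#' @return Updated phase vector.
#' @export
euler_maruyama_step <- function(phases, omega, params, k_t, I_t,
                                noise_draw = rep(0, length(phases))) {
  stopifnot(length(omega) == length(phases),
            length(noise_draw) == length(phases))
  dt <- params$dt_s
  # population average of f(theta_j - theta_i) over all j (self included, as
  # in the compiled core); for a single oscillator this is f(0)
  co <- params$coupling
  c1 <- mean(cos(phases)); s1 <- mean(sin(phases))
  c2 <- mean(cos(2 * phases)); s2 <- mean(sin(2 * phases))
  drive <- co[1] +
    co[2] * (c1 * cos(phases) + s1 * sin(phases)) +
    co[3] * (s1 * cos(phases) - c1 * sin(phases)) +
    co[4] * (c2 * cos(2 * phases) + s2 * sin(2 * phases)) +
    co[5] * (s2 * cos(2 * phases) - c2 * sin(2 * phases))
  g <- prc(phases, params$prc_kind,
           coefs = params$prc_coefs,
           table = if (length(params$prc_table)) params$prc_table else NULL)
  out <- phases + (omega + k_t * drive + I_t * g) * dt +
    params$zeta * sqrt(dt) * noise_draw
  if (any(!is.finite(out))) {
    abort(sprintf(
      "numerical instability: non-finite phases (kmu-scale k = %g, I = %g, zeta = %g, dt = %g).",
      k_t, I_t, params$zeta, dt), class = "ernasim_numerical_instability")
  }
  out
}
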