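#' Empirical ERNA frequency-decay target curve
#'
#' The on-stimulation peak-frequency decay extracted from patient recordings
#' under 130 Hz stimulation: `f(t) = a + b * exp(-r * t)` Hz with defaults
#' a = 260 Hz, b = 80 Hz, r = 0.07 1/s, where t is the time elapsed since
#' stimulation onset.
#'
#' @param asymptote `a`, Hz (positive).
#' @param amplitude `b`, Hz (non-negative).
#' @param rate `r`, 1/s (positive).
#' @return An object of class `erna_target_curve`.
#' @export
target_curve <- function(asymptote = 260, amplitude = 80, rate = 0.07) {
  if (asymptote <= 0 || amplitude < 0 || rate <= 0) {
    abort("need asymptote > 0, amplitude >= 0, rate > 0.",
          class = "ernasim_invalid_argument")
  }
  structure(list(asymptote = asymptote, amplitude = amplitude, rate = rate),
            class = "erna_target_curve")
}

#' @rdname target_curve
#' @param t Time since stimulation onset (s, non-negative; vectorized).
#' @param curve An `erna_target_curve`.
#' @return `target_decay()`: target frequency in Hz.
#' @export
#' @examples
#' target_decay(0)    # 340 Hz
#' target_decay(1e9)  # -> 260 Hz asymptote
target_decay <- function(t, curve = target_curve()) {
  if (any(t < 0)) {
    abort("`t` must be non-negative.", class = "ernasim_invalid_argument")
  }
  curve$asymptote + curve$amplitude * exp(-curve$rate * t)
}

#' On-stimulation cost
#'
#' Sum of absolute deviations between the model peak-frequency series and the
#' target decay curve, sampled every 100 ms over the stimulation window:
#' `CostOn = sum_i |f_model(t_i) - f_target(t_i)|`.
#'
#' @param model_peaks Feature-series tibble (`time_s` measured from
#'   stimulation onset, `value` in Hz).
#' @param curve An `erna_target_curve`.
#' @return The on-stimulation cost (Hz x samples).
#' @export
cost_on <- function(model_peaks, curve = target_curve()) {
  if (nrow(model_peaks) == 0) {
    abort("empty peak-frequency series.", class = "ernasim_invalid_argument")
  }
  sum(abs(model_peaks$value - target_decay(model_peaks$time_s, curve)))
}

#' Off-stimulation cost
#'
#' Penalizes off-stimulation hypersynchrony. With `z_max` the maximum of
#' `|Z|` over the off-stimulation period: the cost is 0 below the synchrony
#' threshold 0.2 and `z_max / 0.2 - 1` above it (continuous and piecewise
#' linear).
#'
#' @param z_max Maximum off-stimulation order-parameter modulus, in `[0, 1]`.
#' @param threshold Synchrony threshold (default 0.2).
#' @return The off-stimulation cost (dimensionless, non-negative).
#' @export
#' @examples
#' cost_off(0.1) # 0
#' cost_off(0.4) # 1
cost_off <- function(z_max, threshold = 0.2) {
  if (any(z_max < 0 | z_max > 1)) {
    abort("`z_max` must lie in [0, 1].", class = "ernasim_invalid_argument")
  }
  ifelse(z_max < threshold, 0, z_max / threshold - 1)
}

#' Weighted total cost
#'
#' `Cost = 0.9 * CostOn + 0.1 * CostOff`; the on-stimulation frequency decay
#' is the dominant feature.
#'
#' @param cost_on_value On-stimulation cost.
#' @param cost_off_value Off-stimulation cost.
#' @param weights Length-2 weights (default `c(0.9, 0.1)`).
#' @return The weighted total cost.
#' @export
total_cost <- function(cost_on_value, cost_off_value,
                       weights = cost_weights()) {
  unname(weights[1] * cost_on_value + weights[2] * cost_off_value)
}

#' @rdname total_cost
#' @export
cost_weights <- function() {
  c(on = 0.9, off = 0.1)
}

#' Names of the free parameters in the fitting problem
#' @return Character vector of the 11 free-parameter names.
#' @export
free_parameter_names <- function() {
  c("omega_hz", "sigma_hz", "kmu", "zeta", "stim_amplitude",
    "f0", "f1", "f2", "f3", "f4")
}

#' Assemble model parameters from a free-parameter vector
#'
#' @param x Named (or ordered) numeric vector over [free_parameter_names()].
#' @param base An `erna_parameters` supplying everything not being fitted.
#' @return An `erna_parameters` object.
#' @export
params_from_vector <- function(x, base = model_parameters()) {
  nm <- free_parameter_names()
  if (!is.null(names(x))) x <- x[nm]
  stopifnot(length(x) == length(nm))
  model_parameters(
    n_oscillators = base$n_oscillators,
    omega_hz = x[[1]], sigma_hz = max(0, x[[2]]), kmu = x[[3]],
    zeta = max(0, x[[4]]), stim_amplitude = x[[5]],
    coupling = as.numeric(x[6:10]),
    prc_kind = base$prc_kind, prc_coefs = base$prc_coefs,
    prc_table = if (length(base$prc_table)) base$prc_table else NULL,
    dt_s = base$dt_s, seed = base$seed
  )
}

#' @rdname params_from_vector
#' @param params An `erna_parameters`.
#' @return `vector_from_params()`: named numeric vector of free parameters.
#' @export
vector_from_params <- function(params) {
  c(omega_hz = params$omega_hz, sigma_hz = params$sigma_hz,
    kmu = params$kmu, zeta = params$zeta,
    stim_amplitude = params$stim_amplitude,
    f0 = params$coupling[1], f1 = params$coupling[2],
    f2 = params$coupling[3], f3 = params$coupling[4],
    f4 = params$coupling[5])
}

#' Extract the on-stimulation peak-frequency series of a fitting run
#'
#' Welch spectrograms of `Re(Z)` over the stimulation window in `window_s`
#' windows (non-overlapping by default, per the 100 ms cost sampling;
#' overlapping windows are available for figure-style output), peak frequency
#' restricted to `band`. Times are reported relative to stimulation onset.
#'
#' @param sim An `erna_sim` from a protocol with one off and one on period.
#' @param window_s Analysis-window length (default 0.1 s).
#' @param overlap Window overlap fraction (default 0: non-overlapping).
#' @param band Peak-search band in Hz (default `c(240, 400)`).
#' @return A feature-series tibble, `time_s` relative to stimulation onset.
#' @export
on_peak_series <- function(sim, window_s = 0.1, overlap = 0,
                           band = c(240, 400)) {
  on <- sim[sim$stim_on, ]
  if (nrow(on) == 0) {
    abort("no on-stimulation samples in the trace.",
          class = "ernasim_invalid_argument")
  }
  fs <- attr(sim, "sample_rate_hz")
  t_on <- min(on$time_s)
  sg <- welch_spectrogram(on$re_z, fs, window_s = window_s,
                          overlap = overlap, t0 = 0)
  peak_frequency(sg, band)
}

#' Evaluate one candidate parameter set under the fitting protocol
#'
#' Simulates the fitting protocol (by default 20 s off-stimulation settling
#' followed by 100 s of continuous 130 Hz stimulation at `Ifact = 1`),
#' computes `Zmax` (the maximum off-stimulation `|Z|`), the on-stimulation
#' peak-frequency series in the 240-400 Hz band sampled every 100 ms, and the
#' resulting cost breakdown. Deterministic given the candidate and seed. A
#' simulation that goes numerically unstable is reported as infinite cost
#' with `unstable = TRUE` so a surrounding search can continue.
#'
#' @param x Free-parameter vector (see [free_parameter_names()]).
#' @param base Base `erna_parameters` for the non-fitted fields.
#' @param pools An `erna_pools`.
#' @param protocol Fitting protocol (default [fit_protocol()]).
#' @param curve Target curve (default [target_curve()]).
#' @param seed Seed used for the evaluation's realization.
#' @param window_s Cost sampling window (default 0.1 s).
#' @return A list of class `erna_cost`: `cost_on`, `cost_off`, `total`,
#'   `z_max_off`, `n_samples`, `unstable`.
#' @export
evaluate_candidate <- function(x, base = model_parameters(),
                               pools = vesicle_pool_parameters(),
                               protocol = fit_protocol(),
                               curve = target_curve(),
                               seed = 1L, window_s = 0.1) {
  params <- params_from_vector(x, base)
  params$seed <- as.integer(seed)
  sim <- tryCatch(
    simulate_erna(params, protocol, pools = pools),
    ernasim_numerical_instability = function(e) NULL,
    error = function(e) {
      if (grepl("numerical instability", conditionMessage(e))) NULL
      else stop(e)
    })
  if (is.null(sim)) {
    return(structure(list(cost_on = Inf, cost_off = Inf, total = Inf,
                          z_max_off = NA_real_, n_samples = 0L,
                          unstable = TRUE), class = "erna_cost"))
  }
  z_max <- max(sim$abs_z[!sim$stim_on])
  z_max <- min(z_max, 1)  # |Z| <= 1 up to floating point
  peaks <- on_peak_series(sim, window_s = window_s)
  con <- cost_on(peaks, curve)
  coff <- cost_off(z_max)
  structure(list(cost_on = con, cost_off = coff,
                 total = total_cost(con, coff),
                 z_max_off = z_max, n_samples = nrow(peaks),
                 unstable = FALSE),
            class = "erna_cost")
}

#' @export
print.erna_cost <- function(x, ...) {
  cat(sprintf("<erna_cost> total = %.4g (on = %.4g over %d samples, off = %.4g, Zmax = %.3f)\n",
              x$total, x$cost_on, x$n_samples, x$cost_off, x$z_max_off))
  invisible(x)
}

#' Generalized pattern search
#'
#' Derivative-free minimization by coordinate polling: from the incumbent,
#' the `2 d` points `x +/- mesh * scale * e_i` are evaluated; on improvement
#' the incumbent moves and the mesh expands, otherwise the mesh contracts.
#' Terminates when the mesh falls below `tol` or the evaluation budget is
#' exhausted. The incumbent cost is non-increasing by construction and the
#' full evaluation log is returned.
#'
#' @param objective Function taking a parameter vector, returning a scalar
#'   cost (may return `Inf`).
#' @param initial Initial parameter vector (within bounds).
#' @param lower,upper Bound vectors (same length as `initial`).
#' @param mesh0 Initial mesh size as a fraction of the bound range
#'   (default 0.25).
#' @param expansion Mesh expansion factor on success (default 2).
#' @param contraction Mesh contraction factor on failure (default 0.5).
#' @param tol Mesh-size tolerance (default 1e-3).
#' @param max_evals Evaluation budget (default 500).
#' @return A list of class `erna_search`: `par`, `value`, `converged`,
#'   `n_evals`, `log` (tibble of every evaluation), `mesh_history`.
#' @export
#' @examples
#' sphere <- function(x) sum((x - c(1, -2, 3))^2)
#' fit <- pattern_search(sphere, c(0, 0, 0), rep(-5, 3), rep(5, 3))
#' fit$value < 1e-3
pattern_search <- function(objective, initial, lower, upper,
                           mesh0 = 0.25, expansion = 2, contraction = 0.5,
                           tol = 1e-3, max_evals = 500L) {
  d <- length(initial)
  stopifnot(length(lower) == d, length(upper) == d)
  if (any(initial < lower | initial > upper)) {
    abort("`initial` must lie within the bounds.",
          class = "ernasim_invalid_argument")
  }
  scale <- upper - lower
  if (any(scale <= 0)) {
    abort("bounds must satisfy lower < upper.",
          class = "ernasim_invalid_argument")
  }
  x <- as.numeric(initial)
  nm <- names(initial)
  mesh <- mesh0
  log_par <- list()
  log_cost <- numeric(0)
  n_evals <- 0L
  eval_log <- function(p) {
    n_evals <<- n_evals + 1L
    v <- objective(p)
    log_par[[n_evals]] <<- p
    log_cost[n_evals] <<- v
    v
  }
  best <- eval_log(x)
  mesh_history <- mesh
  while (mesh >= tol && n_evals < max_evals) {
    improved <- FALSE
    for (i in seq_len(d)) {
      for (sgn in c(1, -1)) {
        if (n_evals >= max_evals) break
        cand <- x
        cand[i] <- min(upper[i], max(lower[i], x[i] + sgn * mesh * scale[i]))
        if (cand[i] == x[i]) next
        v <- eval_log(cand)
        if (v < best) {
          best <- v
          x <- cand
          improved <- TRUE
          break
        }
      }
      if (improved || n_evals >= max_evals) break
    }
    mesh <- if (improved) min(mesh * expansion, 1) else mesh * contraction
    mesh_history <- c(mesh_history, mesh)
  }
  if (!is.null(nm)) names(x) <- nm
  log_mat <- do.call(rbind, log_par)
  colnames(log_mat) <- nm %||% paste0("x", seq_len(d))
  structure(list(
    par = x, value = best, converged = mesh < tol, n_evals = n_evals,
    log = dplyr::bind_cols(as_tibble(log_mat),
                           tibble(cost = log_cost, eval = seq_len(n_evals))),
    mesh_history = mesh_history
  ), class = "erna_search")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the oscillator-network parameters to the ERNA decay curve
#'
#' Wraps [pattern_search()] around [evaluate_candidate()]: minimizes the
#' weighted cost `0.9 CostOn + 0.1 CostOff` over the 10 free parameters
#' (mean/sd of natural frequencies, baseline coupling, noise, stimulation
#' intensity, and the five coupling-function coefficients). One seeded
#' realization per cost evaluation.
#'
#' @param initial Named free-parameter vector (default: the reference fit).
#' @param lower,upper Named bound vectors; defaults in
#'   [default_fit_bounds()].
#' @param base,pools,protocol,curve,seed,window_s Passed to
#'   [evaluate_candidate()].
#' @param constrain_omega If TRUE, pins the mean natural frequency to 20 Hz
#'   (the constrained low-frequency variant).
#' @param ... Passed to [pattern_search()] (`mesh0`, `tol`, `max_evals`, ...).
#' @return An object of class `erna_fit`: the `erna_search` result plus
#'   `best_parameters` (an `erna_parameters`), `best_cost` (an `erna_cost`)
#'   and the evaluation seed.
#' @export
fit_erna <- function(initial = vector_from_params(reference_parameters()),
                     lower = default_fit_bounds()$lower,
                     upper = default_fit_bounds()$upper,
                     base = model_parameters(),
                     pools = vesicle_pool_parameters(),
                     protocol = fit_protocol(),
                     curve = target_curve(),
                     seed = 1L, window_s = 0.1,
                     constrain_omega = FALSE, ...) {
  if (constrain_omega) {
    initial[["omega_hz"]] <- 20
    lower[["omega_hz"]] <- 20
    upper[["omega_hz"]] <- 20 + 1e-9
  }
  objective <- function(x) {
    evaluate_candidate(x, base = base, pools = pools, protocol = protocol,
                       curve = curve, seed = seed, window_s = window_s)$total
  }
  res <- pattern_search(objective, initial, lower, upper, ...)
  best_params <- params_from_vector(res$par, base)
  best_cost <- evaluate_candidate(res$par, base = base, pools = pools,
                                  protocol = protocol, curve = curve,
                                  seed = seed, window_s = window_s)
  out <- res
  out$best_parameters <- best_params
  out$best_cost <- best_cost
  out$seed <- seed
  class(out) <- c("erna_fit", class(res))
  out
}

#' Default fitting bounds
#'
#' Wide, documented bounds for the 10 free parameters. The mean natural
#' frequency spans 10-400 Hz in the unconstrained variant.
#'
#' @return A list with named `lower` and `upper` vectors.
#' @export
default_fit_bounds <- function() {
  nm <- free_parameter_names()
  lower <- c(10, 0, 10, 0, 0, -5, -5, -5, -5, -5)
  upper <- c(400, 50, 5000, 50, 20000, 5, 5, 5, 5, 5)
  names(lower) <- nm
  names(upper) <- nm
  list(lower = lower, upper = upper)
}

#' @export
print.erna_fit <- function(x, ...) {
  cat(sprintf("<erna_fit> cost %.4g after %d evaluations (converged: %s)\n",
              x$value, x$n_evals, x$converged))
  print(x$best_parameters)
  invisible(x)
}

#' @export
tidy.erna_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = as.numeric(x$par))
}

#' @export
glance.erna_fit <- function(x, ...) {
  tibble(cost = x$value, cost_on = x$best_cost$cost_on,
         cost_off = x$best_cost$cost_off, z_max_off = x$best_cost$z_max_off,
         n_evals = x$n_evals, converged = x$converged)
}
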