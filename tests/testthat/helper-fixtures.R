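# Small, fast parameter sets and protocols shared across tests. Everything is
# generated in code; no stored fixtures.

quick_params <- function(seed = 1L, ...) {
  model_parameters(seed = seed, ...)
}

quick_pools <- function() {
  vesicle_pool_parameters()
}

# a short settle + stimulation protocol that keeps unit tests fast
quick_protocol <- function(settle_s = 1, on_s = 2, f_stim_hz = 130) {
  fit_protocol(settle_s, on_s, f_stim_hz)
}

# brute-force O(N^2) oracle for the mean-field coupling drive
brute_force_drive <- function(phases, coefs) {
  vapply(seq_along(phases), function(i) {
    mean(coupling_function(phases - phases[i], coefs))
  }, numeric(1))
}

expect_feature_series <- function(fs) {
  expect_true(all(c("time_s", "value", "sem", "n") %in% names(fs)))
  expect_true(all(diff(fs$time_s) > 0))
}
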