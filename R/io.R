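default_config <- function() {
  p <- model_parameters()
  v <- vesicle_pool_parameters()
  list(
    model = list(
      n_oscillators = p$n_oscillators,
      omega_hz = p$omega_hz,
      sigma_hz = p$sigma_hz,
      kmu = p$kmu,
      zeta = p$zeta,
      stim_amplitude = p$stim_amplitude,
      f0 = p$coupling[1], f1 = p$coupling[2], f2 = p$coupling[3],
      f3 = p$coupling[4], f4 = p$coupling[5],
      prc_kind = p$prc_kind,
      dt_s = p$dt_s,
      seed = p$seed
    ),
    vesicle = list(
      tau_rrp_s = v$tau_s[1], tau_rp_s = v$tau_s[2], tau_rtp_s = v$tau_s[3],
      p_rrp = v$p_release[1], p_rp = v$p_release[2], p_rtp = v$p_release[3],
      m_rrp = v$M[1], m_rp = v$M[2], m_rtp = v$M[3]
    ),
    protocol = list(
      settle_s = 20, on_s = 100, f_stim_hz = 130, ifact = 1
    ),
    analysis = list(
      window_s = 1, overlap = 0.5, band_low_hz = 240, band_high_hz = 400,
      snr_db = 20, n_realizations = 15, record_stride = 2
    ),
    fitting = list(
      mesh0 = 0.25, expansion = 2, contraction = 0.5, tol = 1e-3,
      max_evals = 500, constrain_omega = FALSE
    )
  )
}

check_range <- function(cfg, section, key, lo, hi) {
  v <- cfg[[section]][[key]]
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi) {
    abort(sprintf("config %s.%s = %s violates the constraint [%g, %g].",
                  section, key, format(v), lo, hi),
          class = "ernasim_config_error")
  }
  invisible(TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration with sections `model`, `vesicle`, `protocol`,
#' `analysis` and `fitting`. Every field has a documented default (an empty
#' file yields the full default configuration: 50 oscillators, 0.1 ms
#' timestep, 130 Hz stimulation, `Ifact = 1`, the reference fitted
#' parameters and the calibrated vesicle pools). Unknown keys are rejected;
#' physical quantities carry their units in the key names (`omega_hz`,
#' `dt_s`, ...). Validation errors name the offending key and constraint.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list with class `erna_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file '%s' does not exist.", path),
            class = "ernasim_config_error")
    }
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    for (section in names(user)) {
      if (!section %in% names(cfg)) {
        abort(sprintf("unknown config section '%s'.", section),
              class = "ernasim_config_error")
      }
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]])) {
          abort(sprintf("unknown config key '%s.%s'.", section, key),
                class = "ernasim_config_error")
        }
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    }
  }
  check_range(cfg, "model", "n_oscillators", 2, 1e6)
  check_range(cfg, "model", "sigma_hz", 0, Inf)
  check_range(cfg, "model", "zeta", 0, Inf)
  check_range(cfg, "model", "dt_s", 1e-12, 1)
  check_range(cfg, "protocol", "ifact", 0.8, 1.1)
  check_range(cfg, "protocol", "f_stim_hz", 1, 1000)
  if (cfg$model$dt_s >= 1 / cfg$protocol$f_stim_hz) {
    abort(sprintf("config model.dt_s = %g must be below the stimulation period %g s.",
                  cfg$model$dt_s, 1 / cfg$protocol$f_stim_hz),
          class = "ernasim_config_error")
  }
  check_range(cfg, "analysis", "overlap", 0, 0.999)
  check_range(cfg, "analysis", "n_realizations", 1, 1e4)
  for (k in c("tau_rrp_s", "tau_rp_s", "tau_rtp_s")) {
    check_range(cfg, "vesicle", k, 1e-9, Inf)
  }
  for (k in c("p_rrp", "p_rp", "p_rtp")) {
    check_range(cfg, "vesicle", k, 1e-12, 0.999999)
  }
  structure(cfg, class = c("erna_config", "list"))
}

#' @rdname load_config
#' @param config An `erna_config`.
#' @return `config_parameters()`: the `erna_parameters` encoded by a config;
#'   `config_pools()`: its `erna_pools`.
#' @export
config_parameters <- function(config) {
  m <- config$model
  model_parameters(
    n_oscillators = m$n_oscillators, omega_hz = m$omega_hz,
    sigma_hz = m$sigma_hz, kmu = m$kmu, zeta = m$zeta,
    stim_amplitude = m$stim_amplitude,
    coupling = c(m$f0, m$f1, m$f2, m$f3, m$f4),
    prc_kind = m$prc_kind, dt_s = m$dt_s, seed = m$seed)
}

#' @rdname load_config
#' @export
config_pools <- function(config) {
  v <- config$vesicle
  vesicle_pool_parameters(
    tau_s = c(v$tau_rrp_s, v$tau_rp_s, v$tau_rtp_s),
    p_release = c(v$p_rrp, v$p_rp, v$p_rtp),
    M = c(v$m_rrp, v$m_rp, v$m_rtp))
}

#' Write / read a feature series table
#'
#' CSV with header `time_s,value,sem,n`, numbers serialized with 17
#' significant digits so the write/read round trip is lossless for doubles.
#' The SEM column is empty for single-realization series.
#'
#' @param series A feature-series tibble (`time_s`, `value`, `sem`, `n`).
#' @param path Output path.
#' @return `path` invisibly (writer); the tibble (reader).
#' @export
write_feature_table <- function(series, path) {
  stopifnot(all(c("time_s", "value", "sem", "n") %in% names(series)))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- c("time_s,value,sem,n",
             paste(fmt(series$time_s), fmt(series$value), fmt(series$sem),
                   series$n, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric",
                                             "numeric", "integer"))
  as_tibble(df)
}

#' Write a run manifest
#'
#' JSON manifest carrying the configuration snapshot, master and child seeds,
#' package version, timestamps and an inventory of emitted files with
#' checksums — sufficient to reproduce the run bit-identically on the same
#' platform.
#'
#' @param path Manifest output path.
#' @param config The `erna_config` (or any serializable list) of the run.
#' @param master_seed Master seed used.
#' @param files Character vector of emitted file paths.
#' @param started,finished POSIXct timestamps.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, master_seed, files = character(0),
                           started = Sys.time(), finished = Sys.time()) {
  inventory <- lapply(files, function(f) {
    list(path = f, bytes = file.info(f)$size,
         checksum = unname(tools::md5sum(f)))
  })
  manifest <- list(
    package = "ernasim",
    version = as.character(utils::packageVersion("ernasim")),
    master_seed = master_seed,
    child_seeds = as.list(seed_tree(master_seed,
                                    c("natural_frequencies", "initial_phases",
                                      "dynamical_noise", "measurement_noise"))),
    config = unclass(config),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    files = inventory
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
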