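#' Stimulation protocols
#'
#' A stimulation protocol is an ordered table of segments, each with a
#' duration, a mode (`off`, `continuous`, or `burst`), a stimulation
#' frequency, an amplitude factor `Ifact`, and (for burst segments) a burst
#' specification. Segment helpers [seg_off()], [seg_on()] and [seg_burst()]
#' build the rows; `stim_protocol()` validates and assembles them.
#'
#' @param ... Segment rows created by the `seg_*()` helpers (or a single
#'   data frame of such rows).
#' @return A tibble of class `erna_protocol` with columns `duration_s`,
#'   `mode`, `f_stim_hz`, `ifact`, `burst_pulses`, `burst_rate_hz`,
#'   `burst_period_s`.
#' @export
#' @examples
#' fit_protocol() # 20 s off then 100 s of continuous 130 Hz stimulation
stim_protocol <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.data.frame(parts[[1]])) {
    segs <- as_tibble(parts[[1]])
  } else {
    segs <- dplyr::bind_rows(parts)
  }
  if (nrow(segs) == 0) {
    abort("a protocol needs at least one segment.",
          class = "ernasim_invalid_argument")
  }
  if (any(segs$duration_s <= 0)) {
    abort("segment durations must be positive.",
          class = "ernasim_invalid_argument")
  }
  bursts <- segs$mode == "burst"
  if (any(bursts)) {
    bad <- bursts & (segs$burst_pulses / segs$burst_rate_hz > segs$burst_period_s)
    if (any(bad)) {
      abort("burst pulses must fit within the burst period.",
            class = "ernasim_invalid_argument")
    }
  }
  if (any(segs$mode != "off" & (segs$ifact < 0.8 | segs$ifact > 1.1))) {
    abort("Ifact must lie in [0.8, 1.1] (validity range of the linear amplitude model).",
          class = "ernasim_invalid_argument")
  }
  class(segs) <- c("erna_protocol", class(segs))
  segs
}

seg_row <- function(duration_s, mode, f_stim_hz = NA_real_, ifact = NA_real_,
                    burst_pulses = NA_integer_, burst_rate_hz = NA_real_,
                    burst_period_s = NA_real_) {
  tibble(duration_s = duration_s, mode = mode, f_stim_hz = f_stim_hz,
         ifact = ifact, burst_pulses = burst_pulses,
         burst_rate_hz = burst_rate_hz, burst_period_s = burst_period_s)
}

#' @rdname stim_protocol
#' @param duration_s Segment duration in seconds.
#' @export
seg_off <- function(duration_s) {
  seg_row(duration_s, "off")
}

#' @rdname stim_protocol
#' @param f_stim_hz Stimulation frequency in Hz.
#' @param ifact Amplitude modulation factor (1 = fitted operating point).
#' @export
seg_on <- function(duration_s, f_stim_hz = 130, ifact = 1) {
  seg_row(duration_s, "continuous", f_stim_hz, ifact)
}

#' @rdname stim_protocol
#' @param pulses_per_burst Number of pulses in each burst.
#' @param intra_burst_rate_hz Pulse rate within a burst, in Hz.
#' @param burst_period_s Time between burst onsets, in seconds.
#' @export
seg_burst <- function(duration_s, pulses_per_burst = 10,
                      intra_burst_rate_hz = 130, burst_period_s = 1,
                      ifact = 1) {
  seg_row(duration_s, "burst", intra_burst_rate_hz, ifact,
          as.integer(pulses_per_burst), intra_burst_rate_hz, burst_period_s)
}

#' @rdname stim_protocol
#' @param settle_s Off-stimulation settling period before stimulation onset.
#' @param on_s Duration of the continuous stimulation period.
#' @export
fit_protocol <- function(settle_s = 20, on_s = 100, f_stim_hz = 130,
                         ifact = 1) {
  stim_protocol(seg_off(settle_s), seg_on(on_s, f_stim_hz, ifact))
}

#' Pulse schedule of a protocol on the integration grid
#'
#' Expands a protocol into the 0-based integration-step indices at which
#' stimulation pulses fire, together with each pulse's amplitude factor.
#' Within a segment, pulse j of a continuous segment fires at the first grid
#' step whose time (relative to segment start) reaches `j / f_stim`, matching
#' the pulse-train definition `t mod (1/f_stim) < dt` on the grid; burst
#' segments fire `pulses_per_burst` pulses at the intra-burst rate at the
#' start of each burst period.
#'
#' @param protocol An `erna_protocol`.
#' @param dt Integration timestep (s).
#' @return A list with `n_steps` (total steps), `pulse_steps` (0-based,
#'   sorted), `pulse_ifact`, `segment_starts_s`, and a function
#'   `stim_on_at(t)` giving the on/off indicator at arbitrary times.
#' @export
pulse_schedule <- function(protocol, dt) {
  if (!inherits(protocol, "erna_protocol")) {
    abort("`protocol` must be an erna_protocol.", class = "ernasim_invalid_argument")
  }
  n_seg <- nrow(protocol)
  seg_steps <- as.integer(round(protocol$duration_s / dt))
  seg_start <- cumsum(c(0L, seg_steps[-n_seg]))
  pulses <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    mode <- protocol$mode[s]
    if (mode == "off") next
    if (mode == "continuous") {
      f <- protocol$f_stim_hz[s]
      if (dt >= 1 / f) {
        abort("`dt` must be smaller than the stimulation period.",
              class = "ernasim_invalid_argument")
      }
      n_p <- floor((protocol$duration_s[s] - 1e-12) * f) + 1
      times <- (seq_len(n_p) - 1) / f
    } else { # burst
      per <- protocol$burst_period_s[s]
      n_bursts <- ceiling(protocol$duration_s[s] / per)
      offs <- (seq_len(protocol$burst_pulses[s]) - 1) / protocol$burst_rate_hz[s]
      times <- as.vector(outer(offs, (seq_len(n_bursts) - 1) * per, `+`))
      times <- sort(times[times < protocol$duration_s[s] - 1e-12])
    }
    steps <- seg_start[s] + as.integer(ceiling(times / dt - 1e-9))
    pulses[[s]] <- tibble(step = steps, ifact = protocol$ifact[s])
  }
  pt <- dplyr::bind_rows(pulses)
  n_steps <- sum(seg_steps)
  if (!is.null(pt) && nrow(pt) > 0) {
    pt <- pt[pt$step < n_steps, , drop = FALSE]
    pt <- pt[order(pt$step), , drop = FALSE]
  } else {
    pt <- tibble(step = integer(0), ifact = numeric(0))
  }
  seg_start_s <- seg_start * dt
  seg_end_s <- (seg_start + seg_steps) * dt
  on_seg <- protocol$mode != "off"
  stim_on_at <- function(t) {
    out <- logical(length(t))
    for (s in which(on_seg)) {
      out <- out | (t >= seg_start_s[s] - 1e-12 & t < seg_end_s[s] - 1e-12)
    }
    out
  }
  list(n_steps = n_steps, pulse_steps = pt$step, pulse_ifact = pt$ifact,
       segment_starts_s = seg_start_s, segment_ends_s = seg_end_s,
       stim_on_at = stim_on_at)
}
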