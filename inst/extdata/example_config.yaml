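# Example ernasim configuration. Every key is optional; omitted keys take the
# documented defaults (the reference fitted parameters and the calibrated
# vesicle pools). Units are embedded in key names.
model:
  n_oscillators: 50
  dt_s: 1.0e-4
  seed: 1
protocol:
  settle_s: 20
  on_s: 100
  f_stim_hz: 130
  ifact: 1
analysis:
  window_s: 1
  overlap: 0.5
  band_low_hz: 240
  band_high_hz: 400
  snr_db: 20
  n_realizations: 15
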