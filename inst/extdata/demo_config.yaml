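# Demo pipeline configuration: a blind-like three-stage network analysed
# end-to-end (synthesis -> SNR selection -> contrasts -> scalograms -> MI
# -> influence diagram). Sizes are moderate so the demo runs in about a
# minute on one core.
network: blind_like
seed: 42
noise_sd: 0.5
jitter_ms: 3
condition: Motor
side: left
design:
  trials_per_run: 60
  motor_trials: 60
snr:
  threshold: 0.2
  window: [0, 100]
tfr:
  freqs: [5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95]
mi:
  window_ms: 24
  alpha: 4
  n_bins: 10
  t_range: [-60, 110]
  tau_range: [-30, 30]
  t_step: 1.6
  tau_step: 1.6
links:
  threshold: 0.4
  delay_band: [5, 20]
  t_range: [-50, 100]
contrast:
  grid_shape: [9, 9, 9]
  grid_spacing: 8
  epoch: [0, 48]
  n_trials: 24
  noise_sd: 1
  alpha: 1.0e-4
  scales:
    Motor1: 1
    Motor2: 1
    Supra1: 0.5
    Supra2: 0.5
  sources:
    - position: [32, 32, 32]
      direction: [0, 0, 1]
      amplitude: 2.5
      window_ms: [15, 35]
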