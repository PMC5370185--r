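# Demonstration scenario: GluA2Q-like synaptic conductance with matched
# FRAP kinetics (all values synthetic).
name: glua2q-demo
seed: 7
n_events: 120
channel:
  n_channels: 30
  i: -1.524
  p_peak: 0.6
  tau_rise_ms: 0.5
  tau_decay_ms: 9
  sigma_b: 2
frap:
  plateau: 0.63
  tau_rec_s: 197.3
  k_acq: 0.998
  frame_interval_s: 30
  noise_sd: 0.03
iv:
  g: 1
  v_half: 10
  slope: 20
config:
  n_bins: 15
  min_events: 20
  rise_cutoff_ms: 0.9
  threshold: 4
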