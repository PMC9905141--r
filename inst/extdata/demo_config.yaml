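# Demo configuration for run_pipeline(): a small coupled two-channel
# recording plus a synthetic cortical volume. All analysis defaults mirror
# the standard parameters (300 ms burst-breaking ISI, 3 spikes minimum,
# 750 ms jitter, 99th percentile, 5x SD threshold, 200-5000 Hz band).
seed: 1
ephys:
  n_channels: 3
  span_s: 600
  couplings:
    - source: ch1
      target: ch2
      prob: 0.7
      lag_mean_s: 0.15
bursts:
  isi_max_ms: 300
  min_spikes: 3
  jitter_ms: 750
  n_surrogates: 200
  percentile: 99
anatomy:
  area: S1Bf
  n_neurons: 2000
  alpha: 0.05
  backlabel_prob: [0, 0.05, 0.05, 0.05, 0.05]
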