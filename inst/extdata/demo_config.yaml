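# Demo configuration: a ten-cluster, nine-step trial with two-monthly steps
# (20 periods), a protective intervention (OR 0.7) and implementation
# measures weakly coupled to the per-site benefit.
seed: 20
design:
  n_clusters: 10
  n_steps: 9
  periods_per_step: 2
sim:
  baseline_event_rate: 0.01
  treatment_log_or: -0.357
  centre_effect_sd: 0.3
  centre_trend_sd: 0.005
  deliveries_mean: 800
  deliveries_cluster_cv: 0.4
implementation:
  coupling: 0.5
  noise_sd: 0.3
  censor_adoption: true
meta:
  knapp_hartung: false
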