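# Example pdtraj pipeline configuration.
# cohort: arguments of cohort_config(); analysis: arguments of analysis_config().
cohort:
  n_patients: 100
  seed: 2026
  window_days: 4383
  hd_sessions_per_week: 3
  dropout_rate: 0.0
analysis:
  mixed_max_days: 30
  mixed_min_run: 3
  hybrid_min_days: 90
  hybrid_week_len: 7
  hd_gap_tolerance: 7
  sankey_max_states: 4
  registry_min_days: [30, 60, 90, 180]
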