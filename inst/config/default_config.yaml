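# Default pipeline configuration.
# generator: arguments to cohort_params(); omitted keys use the package
# defaults (matched-cohort baseline structure, group-dependent incident
# comorbidity rates, 3-year capped log-normal follow-up, delta-score-driven
# stroke risk).
generator:
  n_per_group: 4101
matching:
  caliper_multiplier: 0.2
scores:
  - chads_vasc
  - a2c2s2_vasc
min_stratum: 20
seed: 1
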