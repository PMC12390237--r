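# Dual-tracer Cd exposure of Anodonta woodiana: analysis configuration.
# Waterborne route labelled with Cd-112, dietary route (Chlorella vulgaris)
# with Cd-113.  Concentration units: ug/L (water), ug/g dry weight (tissue,
# algae); times in days.
tracers:
  waterborne:
    label: Cd112
    route: waterborne
    natural_abundance: 0.2413
    spike_purity: 0.9870
  dietary:
    label: Cd113
    route: dietary
    natural_abundance: 0.1222
    spike_purity: 0.9335
design:
  groups:
    - {name: T0, waterborne_conc: 0.0, dietary_conc: 0.8}
    - {name: T1, waterborne_conc: 2.5, dietary_conc: 1.9}
    - {name: T2, waterborne_conc: 5.3, dietary_conc: 3.7}
    - {name: T3, waterborne_conc: 10.8, dietary_conc: 6.2}
  tanks_per_group: 3
  mussels_per_tank: 15
  sampled_per_group_time: 6
  sample_days: [10, 20, 30]
  feeding_hours_per_day: 3
  day_hours: 24
regression_through_origin: false
bootstrap_reps: 0
rng_seed: 1
qc_tolerance: 0.10
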