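# Ground truth for the simulated A. woodiana Cd dual-tracer experiment.
# Backgrounds are the control-group tracer levels (ug/g dw); influx rates
# are ug/g/d, dietary on the daily-equivalent scale.  This file is synthetic:
# it encodes the generator's stated world, not any measured data set.
background_w: 1.52
background_d: 0.87
influx_w: {T0: 0.0, T1: 0.23, T2: 0.38, T3: 1.25}
influx_d: {T0: 0.0, T1: 0.02, T2: 0.05, T3: 0.07}
noise_cv: 0.10
growth:
  shell_mean: 7.0
  shell_sd: 0.3
  weight_mean: 1.05
  weight_sd: 0.20
tank_cv: 0.0
noise_law: lognormal
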