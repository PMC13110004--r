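time_unit: months
lod: 0.0001
noise_mode: additive
subgroups:
- name: CR
  'n': 40
  beta0_meanlog: -2.9957323
  beta0_sdlog: 0.6
  beta1_meanlog: -11.5129255
  beta1_sdlog: 0.8
  te: 6.0
  relapse_prob: 0.15
  relapse_mean: 18.0
  relapse_sd: 4.0
  beta2: 0.35
  sigma: 0.002
- name: PR
  'n': 30
  beta0_meanlog: -2.5257286
  beta0_sdlog: 0.6
  beta1_meanlog: -7.6009025
  beta1_sdlog: 0.8
  te: 6.0
  relapse_prob: 0.4
  relapse_mean: 14.0
  relapse_sd: 3.0
  beta2: 0.3
  sigma: 0.002
- name: SD
  'n': 20
  beta0_meanlog: -2.3025851
  beta0_sdlog: 0.5
  beta1_meanlog: -3.912023
  beta1_sdlog: 0.5
  te: 6.0
  relapse_prob: 0.7
  relapse_mean: 10.0
  relapse_sd: 2.0
  beta2: 0.25
  sigma: 0.005
- name: PD
  'n': 10
  beta0_meanlog: -1.89712
  beta0_sdlog: 0.5
  beta1_meanlog: -2.5257286
  beta1_sdlog: 0.4
  te: 4.0
  relapse_prob: 0.95
  relapse_mean: 6.0
  relapse_sd: 1.0
  beta2: 0.4
  sigma: 0.005
hazard:
  baseline_family: exponential
  baseline_params:
    rate: 0.25
  gamma:
    tp53_mut: 0.4
  alpha1: 0.6
  alpha2: 0.0
  alpha3: 0.0
  link_scale: log10
  t_max: 36.0
  dropout_rate: 0.005
schedule:
  mode: regular
  interval: 3.0
  horizon: 36.0
  jitter_sd: 0.2
  miss_prob: 0.05
covariates:
- name: tp53_mut
  kind: binary
  prob: 0.35
- name: age
  kind: continuous
  mean: 62.0
  sd: 9.0
- name: treatment
  kind: categorical
  levels:
  - 'on'
  - 'off'
  probs:
  - 0.7
  - 0.3
  time_variant:
    window_starts:
    - 0.0
    - 6.0
    - 12.0
    - 18.0
    - 24.0
    - 30.0
colormaps:
  tp53_mut:
  - '#1B9E77'
  - '#D95F02'
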