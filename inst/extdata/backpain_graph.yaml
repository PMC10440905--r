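# Default causal graph for the simulated chronic nonspecific low back pain
# study. Treatment effects on pain (-2, -4) are the study's headline
# parameters; all other weights are package defaults of moderate size.
# Lagged treatment edges (temporal treatment-covariate effects) are only
# activated in scenarios with the activity interaction; scenario_graph()
# switches them and the carry-over parameters.
schema: 1
treatment_effects: [-2.0, -4.0]
carry_over:
  tau: [1.0, 1.0]
  gamma: [1.0, 1.0]
activity_modifier:
  weight: 0.0
  node: activity
  center: 0.0
nodes:
  - {name: demographics, role: constant, distribution: gaussian, params: [0.0, 1.0]}
  - {name: education, role: constant, threshold: 0.0, noise: {mean: 0.0, sd: 1.0}}
  - {name: work, role: constant, threshold: 0.0, noise: {mean: 0.0, sd: 1.0}}
  - {name: prev_diagnosis, role: constant, threshold: 0.5, noise: {mean: 0.0, sd: 1.0}}
  - {name: chronic_diseases, role: constant, threshold: 0.8, noise: {mean: 0.0, sd: 1.0}}
  - {name: medication, role: time_varying, threshold: 0.8, noise: {mean: 0.0, sd: 1.0}}
  - {name: activity, role: time_varying, noise: {mean: 0.0, sd: 0.6}}
  - {name: stress, role: time_varying, noise: {mean: 0.0, sd: 0.6}}
  - {name: quality_sleep, role: time_varying, noise: {mean: 0.0, sd: 0.6}}
  - {name: treatment, role: treatment}
  - {name: pain, role: outcome, noise: {mean: 6.0, sd: 0.4}}
  - {name: underlying_state, role: drift, distribution: gaussian, params: [0.0, 0.05]}
edges:
  - {from: demographics, to: education, weight: 0.5}
  - {from: demographics, to: work, weight: 0.5}
  - {from: demographics, to: activity, weight: 0.3}
  - {from: demographics, to: prev_diagnosis, weight: 0.4}
  - {from: demographics, to: medication, weight: 0.3}
  - {from: demographics, to: chronic_diseases, weight: 0.4}
  - {from: treatment, to: stress, weight: -0.2}
  - {from: treatment, to: quality_sleep, weight: 0.2}
  - {from: treatment, to: activity, weight: 1.0, lag: 1}
  - {from: treatment, to: quality_sleep, weight: 0.3, lag: 1}
  - {from: activity, to: pain, weight: 0.3}
  - {from: stress, to: pain, weight: 0.2}
  - {from: quality_sleep, to: pain, weight: -0.2}
  - {from: medication, to: pain, weight: -0.3}
  - {from: prev_diagnosis, to: pain, weight: 0.3}
  - {from: chronic_diseases, to: pain, weight: 0.3}
  - {from: education, to: pain, weight: -0.1}
  - {from: work, to: pain, weight: 0.1}
  - {from: underlying_state, to: pain, weight: 1.0}
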