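n_parties: 3
seed: 11
secure_aggregation: true
label: "y"
proportions: [0.3, 0.3, 0.4]
workflow:
  - app: cv
    params:
      k: 3
  - app: normalization
  - app: logistic_regression
    params:
      max_iter: 25
  - app: eval_classification
dataset:
  task: classification
  n_samples: 300
  n_features: 5
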