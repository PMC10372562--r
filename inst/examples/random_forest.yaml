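n_parties: 5
seed: 7
secure_aggregation: false
label: "y"
proportions: [0.10, 0.15, 0.15, 0.30, 0.30]
workflow:
  - app: cv
    params:
      k: 5
  - app: normalization
  - app: random_forest
    params:
      task: classification
      n_trees: 100
  - app: eval_classification
dataset:
  task: classification
  n_samples: 300
  n_features: 10
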