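# Default pipeline configuration: plant-scale synthetic dataset, tuned
# model hyperparameters, 12-week operation campaign.
seed: 1
generator:
  n_records: 10000
  fault_rate: 0.023
preprocess:
  split_mode: chronological
models:
  svm:
    C: 10
    gamma: 0.05
    epsilon: 0.1
  rf:
    n_trees: 100
    max_depth: 18
    mtry: 2
  ann:
    hidden_sizes: [128, 64]
    learning_rate: 0.001
    batch_size: 64
    l2_lambda: 0.001
    max_epochs: 500
    early_stop_patience: 20
entropy:
  n_perm: 10
operation:
  weeks: 12
  gain: 1.0
  lead_hours: 1
tea:
  capex: 1.5e6
  operating_saving: 13.5
  capacity: 100
  energy_intensity: 100
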