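# Example workflow configuration for the command-line front end.
# Keys mirror the arguments of run_config(); seed is required.
seed: 1
n_train: 401
n_test: 234
k_folds: 10
threshold: 126
ba_mode: percent
filter_window: 5
training:
  learning_rate: 0.1
  batch_size: 64
  epochs: 20000
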