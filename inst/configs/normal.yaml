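# Full-scale single-objective optimization preset: 10,000 steps per seed,
# seed replacement every 2,000 steps in "multi" mode; seeds are typically
# the lowest-scoring molecules of a corpus' validation split.
config_version: 1
score: qed
mode: multi
steps: 10000
cycle_interval: 2000
delta: 0.4
c_p: 0.70710678118654746
expansion_samples: 10
max_fragment_len: 35
invalid_reward: 0.0
max_removal_len: 10
max_partial_len: 35
epochs: 20
hidden_size: 256
learning_rate: 0.001
batch_size: 128
seed: 1
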