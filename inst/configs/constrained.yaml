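# Similarity-constrained optimization preset: 4 cycles x 50 steps per seed
# at delta = 0.4; run it per delta in {0.2, 0.4, 0.6} over the lowest-scoring
# molecules of the corpus.
config_version: 1
score: constrained_plogp
mode: multi
steps: 200
cycle_interval: 50
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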