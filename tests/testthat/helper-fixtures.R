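# Shared fixtures, computed lazily once per test run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, make) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, make(), envir = .fx)
  }
  get(name, envir = .fx)
}

# 60-molecule corpus for unit tests
fx_corpus <- function() fx_get("corpus60", function() {
  generate_fixture_corpus(60, seed = 207)
})

# 200-molecule corpus for the heavier acceptance checks
fx_corpus200 <- function() fx_get("corpus200", function() {
  generate_fixture_corpus(200, seed = 4211)
})

fx_dataset <- function() fx_get("dataset", function() {
  build_partial_dataset(fx_corpus(), max_len = 10, quiet = TRUE)
})

# small trained policy shared across policy/search tests
fx_policy <- function() fx_get("policy", function() {
  train_policy(fx_dataset(), epochs = 3, hidden_size = 48,
               batch_size = 128, seed = 99, quiet = TRUE)
})

# build a well-formed records data frame from parallel vectors
make_records <- function(smiles, valid, raw, step = seq_along(smiles),
                         cycle = 1L, similarity = NA_real_) {
  valid <- rep_len(valid, length(smiles))
  raw <- rep_len(raw, length(smiles))
  data.frame(step = as.integer(step), cycle = as.integer(cycle),
             replacement_start = 0L, replacement_length = 0L,
             fragment = "", smiles = smiles, valid = valid,
             raw_score = ifelse(valid, raw, NA_real_),
             normalized_reward = ifelse(valid, pmin(1, pmax(0, raw)), 0),
             similarity_to_seed = similarity,
             stringsAsFactors = FALSE)
}
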