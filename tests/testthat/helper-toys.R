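# Enumerable toy landscapes used to check search behaviour against brute
# force.
#
# Construction: tri-aziridine rings ("N1NN1", and one "N1CN1" carrying a
# protected carbon) are immune to any contiguous removal of <= 2 tokens --
# every such window orphans a ring digit or creates a two-membered ring, so
# the product fails to parse.  Exposed "CC" windows between the rings are
# the only removable carbon sites.  With reward = nitrogen fraction, the
# global optimum of the single-edit space is then provably "delete an
# exposed CC, insert NNN", and the full reachable set is small enough to
# enumerate.

toy_vocab <- function() fx_get("toy_vocab", function() {
  smiles_vocabulary(c("C", "N", "O"))
})

# nitrogen fraction over heavy-atom tokens of the product string
nitrogen_fraction <- function(smiles) {
  toks <- smiles_tokens(smiles)
  atoms <- sum(!(toks %in% c("(", ")", "=", "#", "1", "2", "3")))
  if (atoms == 0) return(list(raw = 0, normalized = 0))
  f <- sum(toks == "N") / atoms
  list(raw = f, normalized = f)
}

toy_config <- function(...) {
  search_config(max_fragment_len = 3L, max_removal_len = 2L,
                compute_similarity = FALSE, ...)
}

# one protected carbon ring + one removable CC window
toy_seed_single_cc <- function() {
  paste0("N1CN1", strrep("N1NN1", 3), "CC", strrep("N1NN1", 4))
}

# two removable CC windows, far apart: no single contiguous edit (removal
# <= 2 tokens) can eliminate both carbon pairs
toy_seed_two_cc <- function() {
  paste0("N1CN1", strrep("N1NN1", 3), "CC", strrep("N1NN1", 3), "CC",
         strrep("N1NN1", 2))
}

# terminal-heavy, carbon-biased rollout policy (the qualitative shape of a
# language model trained on carbon-dominated SMILES corpora)
toy_biased_policy <- function() {
  categorical_policy(toy_vocab(),
                     c("$end$" = 0.55, "C" = 0.21, "O" = 0.12, "N" = 0.12))
}

# brute force over the full reachable single-edit set
toy_brute_force <- function(seed) {
  specs <- enumerate_replacements(seed, 2L)
  frags <- c("", unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(c("C", "N", "O")), L)), 1, paste0,
          collapse = "")
  })))
  prods <- unique(unlist(lapply(specs, function(sp) {
    vapply(frags, function(f) splice_smiles(seed, sp, f), character(1))
  })))
  ok <- is_valid_smiles(prods)
  vals <- vapply(prods[ok], function(s) nitrogen_fraction(s)$raw, numeric(1))
  list(best = max(vals), best_smiles = prods[ok][which.max(vals)],
       n_candidates = length(prods), n_valid = sum(ok))
}

# tree-less baseline: same policy, uniformly random replacement window
toy_random_baseline <- function(seed, policy, steps) {
  specs <- enumerate_replacements(seed, 2L)
  sp <- sample.int(length(specs), steps, replace = TRUE)
  frags <- vapply(seq_len(steps), function(i) {
    smiles_detokenize(rollout_completion(policy, character(0), 3L))
  }, character(1))
  prods <- unique(vapply(seq_len(steps), function(i) {
    splice_smiles(seed, specs[[sp[i]]], frags[i])
  }, character(1)))
  ok <- is_valid_smiles(prods)
  max(vapply(prods[ok], function(s) nitrogen_fraction(s)$raw, numeric(1)))
}

toy_best <- function(run) {
  r <- run$records
  max(r$raw_score[r$valid], na.rm = TRUE)
}
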