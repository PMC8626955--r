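# Molecular objectives against independent reference computations.

test_that("QED is in range and matches the desirability recompute", {
  corpus <- fx_corpus()
  qeds <- vapply(corpus, function(s) qed_score(s)$raw, numeric(1))
  expect_true(all(qeds >= 0 & qeds <= 1))
  expect_equal(unname(qeds), oracle_qed(corpus), tolerance = 1e-6)
  r <- qed_score("CCO")
  expect_identical(r$raw, r$normalized)
  expect_error(qed_score("C("), "invalid SMILES")
})

test_that("penalized logP components match their reference implementations", {
  corpus <- fx_corpus()[1:40]
  res <- lapply(corpus, plogp_score)
  logps <- vapply(res, function(r) r$components[["logp"]], numeric(1))
  sas <- vapply(res, function(r) r$components[["sa"]], numeric(1))
  expect_equal(logps, oracle_logp(corpus), tolerance = 1e-6)
  expect_equal(sas, oracle_sa(corpus), tolerance = 1e-6)
})

test_that("ring penalty follows max(0, largest ring - 6)", {
  expect_identical(plogp_score("CCCCCC")$components[["ring_penalty"]], 0)
  expect_identical(plogp_score("C1CCCCC1")$components[["ring_penalty"]], 0)
  expect_identical(plogp_score("C1CCCCCCC1")$components[["ring_penalty"]], 2)
  # two rings: only the largest counts
  expect_identical(
    plogp_score("C1CC1C1CCCCCCCC1")$components[["ring_penalty"]], 3)
})

test_that("sign conventions combine the components as documented", {
  s <- "c1ccccc1CC(=O)NC1CCCCCCC1"
  pen <- plogp_score(s, sign_convention = "penalize")
  lit <- plogp_score(s, sign_convention = "as-printed")
  cmp <- pen$components
  expect_equal(pen$raw, cmp[["logp"]] - cmp[["sa"]] - cmp[["ring_penalty"]])
  expect_equal(lit$raw, cmp[["logp"]] + cmp[["sa"]] + cmp[["ring_penalty"]])
  expect_true(pen$normalized >= 0 && pen$normalized <= 1)
})

test_that("penalized logP is invariant to SMILES rewriting", {
  pairs <- list(c("OCC", "CCO"), c("c1ccccc1C", "Cc1ccccc1"),
                c("C(C)(C)O", "OC(C)C"))
  for (p in pairs) {
    expect_equal(plogp_score(p[1])$raw, plogp_score(p[2])$raw,
                 tolerance = 1e-9)
  }
})

test_that("Tanimoto similarity is a proper set statistic", {
  expect_equal(tanimoto_similarity("CCO", "CCO"), 1)
  expect_equal(tanimoto_similarity("OCC", "CCO"), 1)  # same molecule
  corpus <- fx_corpus()[1:12]
  a <- corpus[1:6]; b <- corpus[7:12]
  expect_equal(tanimoto_similarity(a, b), tanimoto_similarity(b, a))
  sims <- tanimoto_similarity(a, b)
  expect_true(all(sims >= 0 & sims <= 1))
  # matches the toolkit's own similarity routine
  for (i in seq_along(a)) {
    expect_equal(sims[i], oracle_tanimoto(a[i], b[i]), tolerance = 1e-12)
  }
  expect_error(tanimoto_similarity("C(", "CCO"), "invalid SMILES")
})

test_that("the constrained reward gates on similarity", {
  seed <- "CCCCCCCCCC"
  # candidate = seed: similarity 1, so plain penalized-logP reward
  r <- constrained_reward(seed, seed, delta = 0.9)
  expect_equal(r$normalized, plogp_score(seed)$normalized)
  expect_equal(unname(r$components[["similarity"]]), 1)

  # delta = 0 reduces to the unconstrained reward for any valid candidate
  cand <- "c1ccccc1O"
  expect_equal(constrained_reward(cand, seed, delta = 0)$normalized,
               plogp_score(cand)$normalized)

  # a pair straddling the threshold: rewarded under the loose delta only
  far <- "c1ccncc1O"
  sim <- tanimoto_similarity(far, seed)
  expect_true(sim < 0.6)
  loose <- constrained_reward(far, seed, delta = min(0.2, sim / 2))
  tight <- constrained_reward(far, seed, delta = 0.6)
  expect_gt(loose$normalized, 0)
  expect_identical(tight$normalized, 0)

  # chemistry failure maps to invalid_reward, never an error
  expect_identical(constrained_reward("C(", seed, delta = 0.4)$normalized, 0)
})

test_that("reward normalization is linear with clipping", {
  expect_identical(normalize_reward(-15, -15, 15), 0)
  expect_identical(normalize_reward(15, -15, 15), 1)
  expect_identical(normalize_reward(0, -15, 15), 0.5)
  expect_identical(normalize_reward(99, -15, 15), 1)
  expect_identical(normalize_reward(-99, -15, 15), 0)
  expect_error(normalize_reward(0, 2, 2), "lo must be < hi")
  # monotone
  x <- sort(runif(20, -30, 30))
  expect_true(all(diff(normalize_reward(x, -15, 15)) >= 0))
})

test_that("normalized rewards fed to the tree stay inside [0, 1]", {
  set.seed(404)
  stress <- c(fx_corpus200(),
              vapply(1:100, function(i) {
                paste0(sample(c("C", "N", "O", "c", "1", "(", ")"),
                              sample(3:12, 1), replace = TRUE),
                       collapse = "")
              }, character(1)))
  stress <- stress[is_valid_smiles(stress)]
  for (fn in list(score_function("qed"), score_function("plogp"))) {
    vals <- vapply(stress, function(s) fn(s)$normalized, numeric(1))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("custom scorers can be registered and retrieved by name", {
  register_score("heavy_atoms", function(...) function(smiles) {
    n <- sum(!smiles_tokens(smiles) %in% c("(", ")", "1", "2", "=", "#"))
    list(raw = n, normalized = normalize_reward(n, 0, 50))
  })
  fn <- score_function("heavy_atoms")
  expect_identical(fn("CCO")$raw, 3L)
  expect_error(score_function("no_such_score"), "unknown score")
})
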