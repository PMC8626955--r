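# Outer protocols and evaluation metrics.

test_that("select_next_seed takes the best valid record, earliest on ties", {
  rec <- make_records(c("CCO", "CCN", "CCC"), valid = c(TRUE, TRUE, TRUE),
                      raw = c(0.2, 0.9, 0.5))
  expect_identical(select_next_seed(rec), "CCN")

  rec <- make_records(c("CCO", "CCN"), valid = c(FALSE, FALSE), raw = c(1, 1))
  expect_error(select_next_seed(rec), "no valid record")

  rec <- make_records(c("CCO", "CCN", "CCC"), valid = TRUE,
                      raw = c(0.9, 0.9, 0.1), step = c(3, 1, 2))
  expect_identical(select_next_seed(rec), "CCN")
})

test_that("run_multi with a single cycle reproduces run_single exactly", {
  pol <- toy_biased_policy()
  seed <- toy_seed_two_cc()
  cfg <- toy_config()
  a <- run_single(seed, pol, nitrogen_fraction, 150, cfg, seed_rng = 5)
  b <- run_multi(seed, pol, nitrogen_fraction, 150, cycle_interval = 150,
                 config = cfg, seed_rng = 5)
  expect_identical(a$records, b$records)
})

test_that("multi-cycle search carries the best seed forward", {
  pol <- uniform_policy(toy_vocab())
  seed <- toy_seed_two_cc()
  run <- run_multi(seed, pol, nitrogen_fraction, 400, cycle_interval = 100,
                   config = toy_config(), seed_rng = 3)
  r <- run$records
  expect_identical(max(r$cycle), 4L)
  expect_length(run$seed_history, 4L)
  # per-cycle seed scores never decrease
  seed_scores <- vapply(run$seed_history,
                        function(s) nitrogen_fraction(s)$raw, numeric(1))
  expect_true(all(diff(seed_scores) >= 0))
  # best-so-far at cycle boundaries is non-decreasing and the next seed is
  # the argmax of everything generated so far
  for (cy in 2:4) {
    prior <- r[r$cycle < cy & r$valid, ]
    expect_identical(run$seed_history[cy],
                     prior$smiles[order(-prior$raw_score, prior$step)][1])
  }
})

test_that("single-protocol products are one-edit reconstructible", {
  pol <- fx_policy()
  seed <- fx_corpus()[3]
  run <- run_single(seed, pol, score_function("qed"), 60,
                    config = search_config(max_fragment_len = 8,
                                           max_removal_len = 5),
                    seed_rng = 31)
  r <- run$records
  expect_identical(nrow(r), 60L)
  for (i in seq_len(nrow(r))) {
    rebuilt <- splice_smiles(
      seed, replacement_spec(r$replacement_start[i], r$replacement_length[i]),
      r$fragment[i])
    expect_identical(rebuilt, r$smiles[i])
  }
  # similarity recorded for valid products
  expect_true(all(!r$valid | !is.na(r$similarity_to_seed)))
})

test_that("metric fractions follow their definitions", {
  # validity 3/10
  rec <- make_records(
    smiles = c("CCO", "CCO", "CCN", rep("C(", 7)),
    valid = c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
    raw = c(0.5, 0.5, 0.7, rep(NA, 7)))
  m <- compute_metrics(rec)
  expect_equal(m$validity, 0.3)
  # uniqueness 2/3 (CCO twice, canonicalized)
  expect_equal(m$uniqueness, 2 / 3)
  # novelty 1/2 against a corpus containing one of the two
  m2 <- compute_metrics(rec, training_corpus = "CCO")
  expect_equal(m2$novelty, 0.5)
  # canonicalization-aware: OCC and CCO are duplicates
  rec2 <- make_records(c("OCC", "CCO"), valid = TRUE, raw = c(0.2, 0.4))
  expect_equal(compute_metrics(rec2)$uniqueness, 0.5)
  # top-k over distinct molecules
  rec3 <- make_records(c("CCO", "CCN", "CCC", "OCC"), valid = TRUE,
                       raw = c(0.9, 0.6, 0.3, 0.9))
  expect_equal(compute_metrics(rec3, k = 2)$top_k_mean, 0.75)
})

test_that("degenerate metric denominators are reported as missing", {
  m <- compute_metrics(make_records("C(", valid = FALSE, raw = NA))
  expect_equal(m$validity, 0)
  expect_true(is.na(m$uniqueness))
  expect_true(is.na(m$novelty))
  expect_true(is.na(m$top_k_mean))
})

test_that("constrained evaluation applies the strict-improvement rule", {
  seed <- "CCCCCCCCCC"
  seed_plogp <- plogp_score(seed)$raw
  # the seed itself as a product: similarity 1 but improvement 0 -> no success
  rec <- make_records(seed, valid = TRUE, raw = seed_plogp, similarity = 1)
  ev <- constrained_eval(rec, seed, delta = 0.4)
  expect_false(ev$success)
  expect_equal(ev$improvement, 0)

  # no valid products at all
  ev0 <- constrained_eval(make_records("C(", FALSE, NA), seed, delta = 0.4)
  expect_false(ev0$success)
  expect_true(is.na(ev0$improvement))
  expect_identical(ev0$n_qualifying, 0L)

  # hand-built five-record set: manual enumeration picks CCCCCCCCCCCC
  cands <- c("CCCCCCCCCCCC",   # similar, higher plogp -> qualifies, improves
             "c1ccncc1",       # dissimilar -> never qualifies
             "CCCCCCCCO",      # similar, lower plogp
             "C(",             # invalid
             "CCCCCCCCCC")     # the seed itself
  valid <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  raws <- ifelse(valid, vapply(cands, function(s)
    if (is_valid_smiles(s)) plogp_score(s)$raw else NA_real_, numeric(1)), NA)
  rec5 <- make_records(cands, valid, raws,
                       similarity = ifelse(valid,
                                           tanimoto_similarity(
                                             ifelse(valid, cands, seed), seed),
                                           NA))
  ev5 <- constrained_eval(rec5, seed, delta = 0.4)
  expect_true(ev5$success)
  expect_identical(ev5$best_smiles, "CCCCCCCCCCCC")
  expect_equal(ev5$improvement,
               plogp_score("CCCCCCCCCCCC")$raw - seed_plogp)
  expect_identical(ev5$n_qualifying, 3L)

  # similarities are recomputed when the records lack them
  rec5$similarity_to_seed <- NA_real_
  ev5b <- constrained_eval(rec5, seed, delta = 0.4)
  expect_equal(ev5b$improvement, ev5$improvement)
})
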