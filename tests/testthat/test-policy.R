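# Vocabulary, encoding, and next-token policies.

test_that("vocabulary is a bijection with sentinels", {
  v <- smiles_vocabulary(c("C", "N", "O"))
  expect_length(v$tokens, 5L)
  expect_identical(sort(unname(v$index)), 1:5)
  expect_true(all(c(v$begin, v$terminal) %in% v$tokens))
  expect_error(smiles_vocabulary(c("C", "C", "^")), "sentinel")
})

test_that("one-hot encoding prepends the begin sentinel", {
  v <- smiles_vocabulary(c("C", "N", "O"))
  m0 <- encode_tokens(character(0), v)
  expect_identical(dim(m0), c(1L, 5L))
  expect_identical(unname(which(m0[1, ] == 1)), unname(v$index[v$begin]))

  m <- encode_tokens(c("C", "O"), v)
  expect_identical(dim(m), c(3L, 5L))
  expect_identical(unname(rowSums(m)), rep(1, 3))
  expect_identical(unname(apply(m, 1, which.max)),
                   unname(c(v$index[v$begin], v$index["C"], v$index["O"])))
  expect_error(encode_tokens("Zz", v))
})

test_that("next-token distribution is the softmax of the read-out logits", {
  pol <- fx_policy()
  for (prefix in list(character(0), "C", c("C", "C", "O"))) {
    p <- next_token_distribution(pol, prefix)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    # independent naive softmax on the same logits
    y <- predict(pol, prefix, type = "logits")
    y <- y[names(y) != pol$vocab$begin]
    expect_equal(unname(p[names(y)]), unname(exp(y) / sum(exp(y))),
                 tolerance = 1e-9)
    expect_equal(unname(p[pol$vocab$begin]), 0)
  }
})

test_that("hand-set logits reproduce closed-form softmax values", {
  # zero the recurrent read-out so logits equal the output bias exactly
  pol <- train_policy("C", epochs = 1, hidden_size = 8, seed = 5,
                      quiet = TRUE)
  v <- pol$vocab  # tokens: C, ^, $end$
  pol$net$Wy[] <- 0
  pol$net$by <- numeric(3)
  pol$net$by[v$index[["C"]]] <- log(2)
  p <- next_token_distribution(pol)
  expect_equal(unname(p[["C"]]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(p[[v$terminal]]), 1 / 3, tolerance = 1e-12)
  # uniform logits: exact symmetry over the emittable tokens
  pol$net$by[] <- 0.7
  p <- next_token_distribution(pol)
  expect_equal(unname(p[c("C", v$terminal)]), c(0.5, 0.5))
})

test_that("token sampling is reproducible and respects the distribution", {
  pol <- fx_policy()
  set.seed(12)
  a <- sample_tokens(pol, "C", k = 10)
  set.seed(12)
  b <- sample_tokens(pol, "C", k = 10)
  expect_identical(a, b)
  expect_lte(length(a), 10L)
  expect_false(anyDuplicated(a) > 0)
  expect_lte(length(sample_tokens(pol, "C", k = 1)), 1L)

  # degenerate distribution: all mass on one token
  v <- smiles_vocabulary(c("C", "N"))
  deg <- categorical_policy(v, c(N = 1))
  expect_identical(sample_tokens(deg, character(0), k = 25), "N")

  # empirical first-draw frequencies match the distribution (chi-square)
  unif <- uniform_policy(v)  # uniform over N, C, terminal
  set.seed(77)
  draws <- vapply(1:6000, function(i) sample_tokens(unif, k = 1),
                  character(1))
  tab <- table(factor(draws, levels = c("C", "N", v$terminal)))
  expect_gt(stats::chisq.test(tab, p = rep(1 / 3, 3))$p.value, 0.01)
})

test_that("rollout completes fragments and respects the length cap", {
  v <- smiles_vocabulary(c("C", "N"))
  stop_now <- categorical_policy(v, stats::setNames(1, v$terminal))
  out <- rollout_completion(stop_now, c("C", "N"), max_len = 10)
  expect_identical(as.character(out), c("C", "N"))
  expect_false(attr(out, "truncated"))

  never_stop <- categorical_policy(v, c(C = 1))
  out <- rollout_completion(never_stop, character(0), max_len = 7)
  expect_identical(as.character(out), rep("C", 7))
  expect_true(attr(out, "truncated"))

  pol <- fx_policy()
  set.seed(3)
  r1 <- rollout_completion(pol, "C", max_len = 15)
  set.seed(3)
  r2 <- rollout_completion(pol, "C", max_len = 15)
  expect_identical(r1, r2)
  expect_lte(length(r1), 15L)
  expect_identical(r1[1], "C")
})

test_that("simulate() draws fragments from the policy", {
  pol <- fx_policy()
  frags <- simulate(pol, nsim = 5, seed = 21, max_len = 12)
  expect_length(frags, 5L)
  expect_true(all(vapply(frags, function(f)
    length(smiles_tokens(f)) <= 12, logical(1))))
  expect_identical(frags, simulate(pol, nsim = 5, seed = 21, max_len = 12))
})
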