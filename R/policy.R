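# Next-token policies over the fragment vocabulary.
#
# Two policies share one small interface (start a state, advance it by a
# token, read logits): the trained two-layer LSTM ("smiles_policy", see
# train_policy) and a uniform reference policy useful for baselines and for
# enumerable toy searches.  The begin sentinel is input-only: its logit is
# masked to -Inf so it can never be emitted.

#' Policy interface
#'
#' The minimal interface a next-token policy must implement to drive the
#' search: `policy_vocab` returns its [smiles_vocabulary()]; `policy_start`
#' the state after consuming the begin sentinel; `policy_advance` the state
#' after one more token (given by vocabulary index); `policy_probs` the
#' probability vector over the vocabulary at a state.
#'
#' @param policy A policy object.
#' @param state A policy state.
#' @param token_index 1-based vocabulary index of the consumed token.
#' @name policy-interface
NULL

#' @rdname policy-interface
#' @export
policy_vocab <- function(policy) UseMethod("policy_vocab")

#' @rdname policy-interface
#' @export
policy_start <- function(policy) UseMethod("policy_start")

#' @rdname policy-interface
#' @export
policy_advance <- function(policy, state, token_index) UseMethod("policy_advance")

#' @rdname policy-interface
#' @export
policy_probs <- function(policy, state) UseMethod("policy_probs")

#' @export
policy_vocab.smiles_policy <- function(policy) policy$vocab

#' @export
policy_start.smiles_policy <- function(policy) {
  st <- lstm_state0(policy$net)
  step <- lstm_step(policy$net, st, policy$vocab$index[[policy$vocab$begin]])
  list(state = step$state, logits = step$logits)
}

#' @export
policy_advance.smiles_policy <- function(policy, state, token_index) {
  step <- lstm_step(policy$net, state$state, token_index)
  list(state = step$state, logits = step$logits)
}

#' @export
policy_probs.smiles_policy <- function(policy, state) {
  logits <- state$logits
  logits[policy$vocab$index[[policy$vocab$begin]]] <- -Inf
  p <- .softmax(logits)
  names(p) <- policy$vocab$tokens
  p
}

#' Uniform next-token policy
#'
#' Assigns equal probability to every chemical token and the terminal token
#' (the begin sentinel is never emitted), regardless of the prefix.  Used as
#' the default rollout/expansion policy in enumerable toy searches and as
#' the random baseline.
#'
#' @param vocab A [smiles_vocabulary()].
#' @return An object of class `"uniform_policy"`.
#' @export
uniform_policy <- function(vocab) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  structure(list(vocab = vocab), class = "uniform_policy")
}

#' @export
policy_vocab.uniform_policy <- function(policy) policy$vocab

#' @export
policy_start.uniform_policy <- function(policy) list()

#' @export
policy_advance.uniform_policy <- function(policy, state, token_index) state

#' @export
policy_probs.uniform_policy <- function(policy, state) {
  v <- policy$vocab
  p <- rep(1, length(v$tokens))
  p[v$index[[v$begin]]] <- 0
  p <- p / sum(p)
  names(p) <- v$tokens
  p
}

#' Fixed categorical next-token policy
#'
#' Emits tokens from a fixed, prefix-independent distribution.  Useful as a
#' reference policy with a controlled shape — e.g. terminal-heavy and
#' carbon-biased, the qualitative profile of language models trained on real
#' SMILES corpora — and as a random-sampling baseline.
#'
#' @param vocab A [smiles_vocabulary()].
#' @param probs Named numeric vector of probabilities (tokens absent from
#'   `probs` get 0; the begin sentinel is always 0); normalized internally.
#' @return An object of class `"categorical_policy"`.
#' @export
categorical_policy <- function(vocab, probs) {
  stopifnot(inherits(vocab, "smiles_vocab"), !is.null(names(probs)),
            all(names(probs) %in% vocab$tokens), all(probs >= 0))
  p <- numeric(length(vocab$tokens))
  names(p) <- vocab$tokens
  p[names(probs)] <- probs
  p[vocab$index[[vocab$begin]]] <- 0
  if (sum(p) <= 0) stop("categorical_policy: all probabilities are zero")
  structure(list(vocab = vocab, probs = p / sum(p)),
            class = "categorical_policy")
}

#' @export
policy_vocab.categorical_policy <- function(policy) policy$vocab

#' @export
policy_start.categorical_policy <- function(policy) list()

#' @export
policy_advance.categorical_policy <- function(policy, state, token_index) state

#' @export
policy_probs.categorical_policy <- function(policy, state) policy$probs

# walk a chemical-token prefix from the start state
policy_state_for <- function(policy, prefix) {
  st <- policy_start(policy)
  if (length(prefix)) {
    idx <- vocab_index(policy_vocab(policy), prefix)
    for (i in idx) st <- policy_advance(policy, st, i)
  }
  st
}

#' Next-token probability distribution
#'
#' The probability of each vocabulary token following a fragment prefix:
#' the softmax of the recurrent model's final-position logits,
#' \eqn{P(i) = \exp(y_i) / \sum_j \exp(y_j)} (with the input-only begin
#' sentinel masked out).
#'
#' @param policy A trained [train_policy()] model or a [uniform_policy()].
#' @param prefix Character vector of chemical tokens (may be empty).
#' @return Named numeric vector over the vocabulary; non-negative, sums to 1.
#' @export
next_token_distribution <- function(policy, prefix = character(0)) {
  policy_probs(policy, policy_state_for(policy, prefix))
}

#' Sample candidate next tokens
#'
#' Draws `k` samples from [next_token_distribution()] and returns the
#' distinct tokens in order of first draw — the candidate actions offered to
#' the tree's expansion step.
#'
#' @inheritParams next_token_distribution
#' @param k Number of draws (`k >= 1`).
#' @return Character vector of at most `k` distinct tokens.
#' @export
sample_tokens <- function(policy, prefix = character(0), k = 10L) {
  stopifnot(k >= 1L)
  p <- next_token_distribution(policy, prefix)
  draws <- sample(names(p), size = k, replace = TRUE, prob = p)
  unique(draws)
}

#' Complete a fragment by policy rollout
#'
#' Repeatedly samples one token from the policy until the terminal token is
#' drawn or the fragment reaches `max_len` tokens.  The terminal token is not
#' part of the returned fragment.
#'
#' @inheritParams next_token_distribution
#' @param max_len Maximum fragment length in tokens.
#' @return Character vector of chemical tokens beginning with `prefix`, with
#'   attribute `truncated = TRUE` when the length cap cut the rollout short.
#' @export
rollout_completion <- function(policy, prefix = character(0), max_len = 35L) {
  stopifnot(length(prefix) <= max_len)
  vocab <- policy_vocab(policy)
  st <- policy_state_for(policy, prefix)
  out <- prefix
  truncated <- FALSE
  repeat {
    if (length(out) >= max_len) { truncated <- TRUE; break }
    p <- policy_probs(policy, st)
    tok <- sample(names(p), 1L, prob = p)
    if (tok == vocab$terminal) break
    out <- c(out, tok)
    st <- policy_advance(policy, st, vocab$index[[tok]])
  }
  attr(out, "truncated") <- truncated
  out
}
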