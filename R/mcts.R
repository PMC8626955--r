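# Monte Carlo tree search over partial-SMILES edits of a seed molecule.
#
# The tree has a fixed first layer of "replacement" nodes, one per
# (start, length) window of the seed; each fixes which seed tokens are
# deleted before the generated fragment is inserted.  Fragment tokens grow
# from the grandchildren of the root downward, proposed by the next-token
# policy.  One search iteration is the classic UCT cycle: descend by UCB
# score to a leaf, expand it once it has been visited, complete the fragment
# by policy rollout, splice it into the seed, score the product, and
# propagate the (normalized, [0,1]) reward back up the path.
#
# Nodes are environments: the tree is mutated in place during a search.

new_search_node <- function(kind, parent = NULL, token = NULL, spec = NULL,
                            frag_len = 0L, terminal = FALSE) {
  node <- new.env(parent = emptyenv())
  node$kind <- kind          # "root" | "replacement" | "token"
  node$token <- token
  node$spec <- spec
  node$parent <- parent
  node$frag_len <- frag_len  # fragment tokens on the path (terminal excluded)
  node$terminal <- terminal
  node$Q <- 0
  node$N <- 0L
  node$children <- list()
  class(node) <- "search_node"
  node
}

#' Search configuration
#'
#' Bundles the tree-search hyperparameters.
#'
#' @param c_p Exploration constant of the UCB tree policy (default
#'   \eqn{1/\sqrt{2}}).
#' @param expansion_samples Number of policy draws per expansion; the
#'   distinct tokens drawn become the new children.
#' @param max_fragment_len Cap on generated fragment length, in tokens.
#' @param invalid_reward Reward assigned to products that do not parse
#'   (default 0, the bottom of the reward range).
#' @param max_removal_len Cap on the number of seed tokens a replacement
#'   window may delete.
#' @param cycle_interval Steps per cycle in the "Multi" protocol.
#' @param compute_similarity Record the ECFP4 Tanimoto similarity of each
#'   valid product to the original seed.
#' @return A list of class `"search_config"`.
#' @export
search_config <- function(c_p = 1 / sqrt(2), expansion_samples = 10L,
                          max_fragment_len = 35L, invalid_reward = 0,
                          max_removal_len = 10L, cycle_interval = 2000L,
                          compute_similarity = TRUE) {
  stopifnot(c_p > 0, expansion_samples >= 1L, max_fragment_len >= 1L,
            invalid_reward >= 0, invalid_reward <= 1, max_removal_len >= 0)
  structure(list(c_p = c_p, expansion_samples = as.integer(expansion_samples),
                 max_fragment_len = as.integer(max_fragment_len),
                 invalid_reward = invalid_reward,
                 max_removal_len = max_removal_len,
                 cycle_interval = as.integer(cycle_interval),
                 compute_similarity = isTRUE(compute_similarity)),
            class = "search_config")
}

#' Build the replacement layer of a search tree
#'
#' Creates the root node and one child per (start, length) deletion window
#' of the seed (see [enumerate_replacements()]).  Fragment generation starts
#' from the grandchildren of the root.
#'
#' @param seed Seed SMILES.
#' @param max_removal_len Cap on tokens removed.
#' @return The root `"search_node"`, with the replacement nodes as children.
#' @export
build_replacement_layer <- function(seed, max_removal_len = 10L) {
  specs <- enumerate_replacements(seed, max_removal_len)
  root <- new_search_node("root")
  root$children <- lapply(specs, function(sp)
    new_search_node("replacement", parent = root, spec = sp))
  root
}

#' UCB child selection
#'
#' Returns the child maximizing the upper confidence bound
#' \deqn{Q(s_i) + 2 C_p \sqrt{\ln N(s_p) / N(s_i)},}
#' the tree policy of the search.  Unvisited children score \eqn{+\infty}
#' and are therefore taken first, in insertion order; exact ties also break
#' by insertion order.
#'
#' @param parent A `"search_node"` with at least one child.
#' @param c_p Exploration constant.
#' @return The selected child node.
#' @export
ucb_select <- function(parent, c_p = 1 / sqrt(2)) {
  kids <- parent$children
  if (length(kids) == 0L) stop("ucb_select: node has no children")
  scores <- vapply(kids, function(ch) {
    if (ch$N == 0L) Inf
    else ch$Q + 2 * c_p * sqrt(log(parent$N) / ch$N)
  }, numeric(1))
  kids[[which.max(scores)]]
}

#' Descend from the root to a leaf by UCB
#'
#' @param root Root `"search_node"`.
#' @param c_p Exploration constant.
#' @return List of nodes from the root to the first childless node.
#' @export
select_path <- function(root, c_p = 1 / sqrt(2)) {
  path <- list(root)
  node <- root
  while (length(node$children) > 0L) {
    node <- ucb_select(node, c_p)
    path[[length(path) + 1L]] <- node
  }
  path
}

# fragment tokens along the path from the replacement node down to `node`
node_fragment <- function(node) {
  toks <- character(0)
  while (!is.null(node) && identical(node$kind, "token")) {
    if (!node$terminal) toks <- c(node$token, toks)
    node <- node$parent
  }
  toks
}

# replacement spec governing `node` (itself or an ancestor)
node_spec <- function(node) {
  while (!is.null(node)) {
    if (identical(node$kind, "replacement")) return(node$spec)
    node <- node$parent
  }
  stop("node has no replacement ancestor")
}

#' Expand a leaf with policy-proposed children
#'
#' Draws `k` next tokens from the policy at the leaf's fragment prefix and
#' adds the distinct draws as fresh children (Q = 0, N = 0).  The terminal
#' token may be among them, marking a complete fragment.  A leaf whose
#' fragment already reached `max_fragment_len` receives only the terminal
#' child; terminal leaves are never expanded.
#'
#' @param leaf A childless, non-terminal `"search_node"` under (or equal to)
#'   a replacement node.
#' @param policy Next-token policy.
#' @param k Number of policy draws.
#' @param max_fragment_len Fragment length cap.
#' @return Invisibly, the list of new children (also attached to `leaf`).
#' @export
expand <- function(leaf, policy, k = 10L, max_fragment_len = 35L) {
  if (leaf$terminal) return(invisible(list()))
  vocab <- policy_vocab(policy)
  prefix <- node_fragment(leaf)
  toks <- if (leaf$frag_len >= max_fragment_len) vocab$terminal
          else sample_tokens(policy, prefix, k)
  kids <- lapply(toks, function(tok) {
    term <- identical(tok, vocab$terminal)
    new_search_node("token", parent = leaf, token = tok,
                    frag_len = leaf$frag_len + if (term) 0L else 1L,
                    terminal = term)
  })
  leaf$children <- kids
  invisible(kids)
}

#' Roll out, splice and score one leaf
#'
#' Completes the leaf's fragment by policy rollout (terminal leaves skip the
#' rollout — their fragment is already complete), splices it into the seed
#' at the governing replacement window, checks the product with the parser,
#' and scores it: the normalized reward of `reward_fn` when valid,
#' `invalid_reward` otherwise.  Every chemistry failure maps to
#' `invalid_reward`; the function does not throw on bad products.
#'
#' @param leaf The node to evaluate.
#' @param policy Next-token policy.
#' @param seed Seed SMILES being edited.
#' @param reward_fn Function `smiles -> score_result` (see
#'   [score_function()]).
#' @param config A [search_config()].
#' @param cache Optional environment memoizing product scores.
#' @return List with `reward` in `[0, 1]` and `record` (a one-row data frame
#'   of the generated molecule).
#' @export
simulate_leaf <- function(leaf, policy, seed, reward_fn, config,
                          cache = new.env(parent = emptyenv())) {
  spec <- node_spec(leaf)
  prefix <- node_fragment(leaf)
  frag <- if (leaf$terminal) prefix
          else rollout_completion(policy, prefix, config$max_fragment_len)
  frag_str <- smiles_detokenize(frag)
  product <- splice_smiles(seed, spec, frag_str)
  key <- paste0("s:", product)  # non-empty even for an all-deleting edit
  sc <- if (exists(key, envir = cache, inherits = FALSE))
    get(key, envir = cache) else NULL
  if (is.null(sc)) {
    valid <- tryCatch(is_valid_smiles(product), error = function(e) FALSE)
    sc <- if (!valid) {
      list(valid = FALSE, raw = NA_real_, reward = config$invalid_reward)
    } else {
      res <- tryCatch(reward_fn(product), error = function(e) NULL)
      if (is.null(res)) {
        list(valid = FALSE, raw = NA_real_, reward = config$invalid_reward)
      } else {
        list(valid = TRUE, raw = res$raw, reward = res$normalized)
      }
    }
    assign(key, sc, envir = cache)
  }
  record <- data.frame(
    replacement_start = spec$start, replacement_length = spec$length,
    fragment = frag_str, smiles = product, valid = sc$valid,
    raw_score = sc$raw, normalized_reward = sc$reward,
    stringsAsFactors = FALSE)
  list(reward = sc$reward, record = record)
}

#' Backpropagate a reward along a path
#'
#' Applies the incremental-mean update to every node on the path:
#' \eqn{Q \leftarrow (Q N + r) / (N + 1)}, then \eqn{N \leftarrow N + 1}.
#' Mutates the nodes in place.
#'
#' @param path List of `"search_node"`s (root to evaluated node).
#' @param r Reward; finite number.
#' @return Invisibly, `NULL`.
#' @export
backpropagate <- function(path, r) {
  stopifnot(is.finite(r))
  for (node in path) {
    node$Q <- (node$Q * node$N + r) / (node$N + 1L)
    node$N <- node$N + 1L
  }
  invisible(NULL)
}

#' Run a Monte Carlo tree search from a seed molecule
#'
#' Executes `steps` UCT iterations (select, expand, simulate, backpropagate)
#' on a fresh tree whose first layer enumerates the replacement windows of
#' the seed.  Every simulated product is recorded, including invalid ones.
#'
#' @param seed Seed SMILES (must parse).
#' @param policy Next-token policy ([train_policy()] model or
#'   [uniform_policy()]).
#' @param reward_fn Function `smiles -> score_result`, e.g. from
#'   [score_function()].
#' @param steps Number of search iterations (each yields one record).
#' @param config A [search_config()].
#' @param seed_rng Optional integer seed for the session RNG.
#' @param cycle Cycle index stamped on the records (used by [run_multi()]).
#' @param original_seed Molecule similarity is measured against (defaults to
#'   `seed`).
#' @param score_cache Optional score-memoization environment shared across
#'   cycles.
#' @return An object of class `"mcts_run"`; see [run_single()] for the
#'   record format.
#' @export
run_search <- function(seed, policy, reward_fn, steps,
                       config = search_config(), seed_rng = NULL,
                       cycle = 1L, original_seed = seed,
                       score_cache = new.env(parent = emptyenv())) {
  stopifnot(steps >= 1L)
  if (!is.null(seed_rng)) set.seed(seed_rng)
  if (!is_valid_smiles(seed)) stop("seed is not a valid SMILES: '", seed, "'")
  root <- build_replacement_layer(seed, config$max_removal_len)
  records <- vector("list", steps)
  for (step in seq_len(steps)) {
    path <- select_path(root, config$c_p)
    leaf <- path[[length(path)]]
    if (leaf$N > 0L && !leaf$terminal) {
      kids <- expand(leaf, policy, config$expansion_samples,
                     config$max_fragment_len)
      if (length(kids)) {
        leaf <- ucb_select(leaf, config$c_p)  # all fresh: first child
        path[[length(path) + 1L]] <- leaf
      }
    }
    sim <- simulate_leaf(leaf, policy, seed, reward_fn, config, score_cache)
    backpropagate(path, sim$reward)
    rec <- sim$record
    rec$step <- step
    rec$cycle <- cycle
    records[[step]] <- rec
  }
  records <- do.call(rbind, records)
  records$similarity_to_seed <- NA_real_
  if (config$compute_similarity && any(records$valid)) {
    uq <- unique(records$smiles[records$valid])
    sims <- tanimoto_similarity(uq, original_seed)
    records$similarity_to_seed[records$valid] <-
      sims[match(records$smiles[records$valid], uq)]
  }
  records <- records[, c("step", "cycle", "replacement_start",
                         "replacement_length", "fragment", "smiles", "valid",
                         "raw_score", "normalized_reward",
                         "similarity_to_seed")]
  structure(list(records = records, seed = seed, original_seed = original_seed,
                 config = config, steps = steps,
                 root_visits = root$N),
            class = "mcts_run")
}
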