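# Outer optimization protocols: "Single" (fixed seed) and "Multi" (seed
# replaced each cycle by the best molecule generated so far).

#' Single-seed optimization
#'
#' One tree search of `total_steps` iterations on a fixed seed.  Every
#' product differs from the seed by exactly one contiguous token-region
#' edit.
#'
#' @param seed Seed SMILES.
#' @param policy Next-token policy.
#' @param reward_fn Scorer, e.g. `score_function("qed")`.
#' @param total_steps Search iterations.
#' @param config A [search_config()].
#' @param seed_rng Optional integer RNG seed.
#' @return An `"mcts_run"` whose `records` data frame has one row per step:
#'   `step`, `cycle`, `replacement_start`, `replacement_length`, `fragment`,
#'   `smiles`, `valid`, `raw_score`, `normalized_reward`,
#'   `similarity_to_seed`.
#' @export
run_single <- function(seed, policy, reward_fn, total_steps,
                       config = search_config(), seed_rng = NULL) {
  run <- run_search(seed, policy, reward_fn, total_steps, config,
                    seed_rng = seed_rng)
  run$protocol <- "single"
  run$seed_history <- seed
  run
}

#' Multi-cycle optimization with seed replacement
#'
#' Splits the step budget into cycles of `cycle_interval` steps.  Each cycle
#' builds a fresh tree; before every cycle after the first, the seed is
#' replaced by the valid molecule with the highest raw score among all
#' records so far ([select_next_seed()]).  If no valid molecule exists yet,
#' the seed is retained with a warning.  Similarities are always measured
#' against the original seed.  With `cycle_interval = total_steps` and the
#' same `seed_rng`, the result is identical to [run_single()].
#'
#' @inheritParams run_single
#' @param cycle_interval Steps per cycle (defaults to
#'   `config$cycle_interval`); the last cycle is truncated if it does not
#'   divide `total_steps`.
#' @return An `"mcts_run"` with a `cycle` column in the records and the
#'   per-cycle `seed_history`.
#' @export
run_multi <- function(seed, policy, reward_fn, total_steps,
                      cycle_interval = config$cycle_interval,
                      config = search_config(), seed_rng = NULL) {
  stopifnot(total_steps >= 1L, cycle_interval >= 1L)
  cycle_interval <- as.integer(cycle_interval)
  total_steps <- as.integer(total_steps)
  if (!is.null(seed_rng)) set.seed(seed_rng)
  n_cycles <- ceiling(total_steps / cycle_interval)
  current <- seed
  all_records <- list()
  seed_history <- character(0)
  cache <- new.env(parent = emptyenv())
  for (cy in seq_len(n_cycles)) {
    steps <- min(cycle_interval, total_steps - (cy - 1L) * cycle_interval)
    if (cy > 1L) {
      prior <- do.call(rbind, all_records)
      if (any(prior$valid)) {
        current <- select_next_seed(prior)
      } else {
        warning("cycle ", cy, ": no valid molecule yet; seed retained")
      }
    }
    seed_history <- c(seed_history, current)
    run <- run_search(current, policy, reward_fn, steps, config,
                      cycle = cy, original_seed = seed, score_cache = cache)
    rec <- run$records
    rec$step <- rec$step + (cy - 1L) * cycle_interval
    all_records[[cy]] <- rec
  }
  structure(list(records = do.call(rbind, all_records), seed = seed,
                 original_seed = seed, config = config,
                 steps = total_steps, protocol = "multi",
                 cycle_interval = cycle_interval,
                 seed_history = seed_history),
            class = "mcts_run")
}

#' Select the next seed from generated records
#'
#' The valid record with the maximal raw score; ties break by earliest
#' step.
#'
#' @param records Records data frame (or an `"mcts_run"`).
#' @return The winning SMILES string.
#' @export
select_next_seed <- function(records) {
  records <- as.data.frame(records)
  ok <- records[records$valid & !is.na(records$raw_score), , drop = FALSE]
  if (nrow(ok) == 0L) stop("select_next_seed: no valid record")
  ok <- ok[order(-ok$raw_score, ok$step), , drop = FALSE]
  ok$smiles[1]
}
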