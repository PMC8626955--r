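# Evaluation metrics for sets of generated molecules.

#' Distributional metrics of a generation run
#'
#' * validity: fraction of records whose SMILES parses;
#' * uniqueness: distinct canonical molecules among valid records, divided
#'   by the number of valid records;
#' * novelty: fraction of the distinct valid canonicals absent from the
#'   (canonicalized) training corpus;
#' * `top_k_mean`: mean raw score of the `k` best distinct valid molecules.
#'
#' Fractions whose denominator is zero are reported as `NA`.
#'
#' @param records Records data frame (or an `"mcts_run"`).
#' @param training_corpus Character vector of training SMILES (canonicalized
#'   internally); `NULL` leaves novelty `NA`.
#' @param k Number of top molecules averaged (default 3).
#' @return A list of class `"metrics_report"`: `n_records`, `n_valid`,
#'   `validity`, `uniqueness`, `novelty`, `top_k_mean`, `top_k`,
#'   `best_smiles`.
#' @export
compute_metrics <- function(records, training_corpus = NULL, k = 3L) {
  records <- as.data.frame(records)
  n <- nrow(records)
  valid <- records[records$valid, , drop = FALSE]
  nv <- nrow(valid)
  validity <- if (n > 0L) nv / n else NA_real_
  if (nv > 0L) {
    canon <- canonical_smiles(valid$smiles)
    keep <- !is.na(canon)
    valid <- valid[keep, , drop = FALSE]
    canon <- canon[keep]
    first <- !duplicated(canon)
    distinct <- valid[first, , drop = FALSE]
    distinct$canonical <- canon[first]
    uniqueness <- nrow(distinct) / nv
    novelty <- if (is.null(training_corpus)) NA_real_ else {
      corpus_canon <- unique(stats::na.omit(canonical_smiles(training_corpus)))
      mean(!(distinct$canonical %in% corpus_canon))
    }
    ord <- order(-distinct$raw_score)
    top <- distinct[ord, , drop = FALSE][seq_len(min(k, nrow(distinct))), ]
    top_k_mean <- mean(top$raw_score)
    best_smiles <- top$smiles[1]
  } else {
    uniqueness <- novelty <- top_k_mean <- NA_real_
    best_smiles <- NA_character_
    top <- records[0, , drop = FALSE]
  }
  structure(list(n_records = n, n_valid = nv, validity = validity,
                 uniqueness = uniqueness, novelty = novelty,
                 top_k_mean = top_k_mean, k = k, top_k = top,
                 best_smiles = best_smiles),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("Generation metrics over", x$n_records, "records\n")
  cat(sprintf("  validity: %s | uniqueness: %s | novelty: %s\n",
              pct(x$validity), pct(x$uniqueness), pct(x$novelty)))
  if (!is.na(x$top_k_mean)) {
    cat(sprintf("  top-%d mean raw score: %.4f (best: %s)\n",
                x$k, x$top_k_mean, x$best_smiles))
  }
  invisible(x)
}

#' Constrained-optimization evaluation of one run
#'
#' A product qualifies when it is valid and its ECFP4 Tanimoto similarity to
#' the seed is at least `delta`.  The run's improvement is the penalized
#' logP of the best qualifying product minus that of the seed; the run is a
#' success when a qualifying product with strictly positive improvement
#' exists (a product identical to the seed has similarity 1 but improvement
#' 0, hence is not a success).
#'
#' @param records Records data frame (or an `"mcts_run"`).
#' @param seed The original seed SMILES.
#' @param delta Similarity threshold.
#' @param ... Passed to [plogp_score()] (e.g. `sign_convention`).
#' @return A list of class `"constrained_report"`: `improvement` (`NA` when
#'   nothing qualifies), `similarity` (of the best qualifying product),
#'   `success` (logical), `n_qualifying`, `best_smiles`, `seed_score`.
#' @export
constrained_eval <- function(records, seed, delta, ...) {
  records <- as.data.frame(records)
  seed_score <- plogp_score(seed, ...)$raw
  ok <- records$valid & !is.na(records$smiles)
  if (any(ok)) {
    sims <- records$similarity_to_seed
    missing_sim <- ok & is.na(sims)
    if (any(missing_sim)) {
      sims[missing_sim] <- tanimoto_similarity(records$smiles[missing_sim],
                                               seed)
    }
    qual <- ok & !is.na(sims) & sims >= delta
  } else {
    qual <- ok
  }
  if (!any(qual)) {
    return(structure(list(improvement = NA_real_, similarity = NA_real_,
                          success = FALSE, n_qualifying = 0L,
                          best_smiles = NA_character_,
                          seed_score = seed_score, delta = delta),
                     class = "constrained_report"))
  }
  qrec <- records[qual, , drop = FALSE]
  qscore <- vapply(qrec$smiles, function(s) plogp_score(s, ...)$raw,
                   numeric(1), USE.NAMES = FALSE)
  best <- which.max(qscore)
  improvement <- qscore[best] - seed_score
  structure(list(improvement = improvement,
                 similarity = unname(sims[qual][best]),
                 success = improvement > 0,
                 n_qualifying = sum(qual),
                 best_smiles = qrec$smiles[best],
                 seed_score = seed_score, delta = delta),
            class = "constrained_report")
}

#' @export
print.constrained_report <- function(x, ...) {
  cat(sprintf("Constrained evaluation (delta = %.2f)\n", x$delta))
  if (x$n_qualifying == 0L) {
    cat("  no qualifying product\n")
  } else {
    cat(sprintf("  improvement: %+.3f | similarity: %.3f | success: %s\n",
                x$improvement, x$similarity, x$success))
  }
  invisible(x)
}
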