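# S3 methods for search-run objects.

#' @export
print.mcts_run <- function(x, ...) {
  r <- x$records
  cat(sprintf("MCTS generation run (%s protocol): %d steps from seed %s\n",
              if (is.null(x$protocol)) "single" else x$protocol,
              x$steps, x$original_seed))
  nv <- sum(r$valid)
  cat(sprintf("  valid products: %d/%d (%.1f%%)\n", nv, nrow(r),
              100 * nv / nrow(r)))
  if (nv > 0) {
    best <- r[r$valid, ][which.max(r$raw_score[r$valid]), ]
    cat(sprintf("  best raw score: %.4f  (%s)\n", best$raw_score,
                best$smiles))
  }
  invisible(x)
}

#' @export
summary.mcts_run <- function(object, training_corpus = NULL, k = 3L, ...) {
  m <- compute_metrics(object$records, training_corpus, k)
  print(object)
  print(m)
  invisible(m)
}

#' @export
as.data.frame.mcts_run <- function(x, ...) x$records

#' Plot a generation run
#'
#' Best-so-far raw score against the step index, with valid products as
#' points; cycle boundaries of the "Multi" protocol are marked.
#'
#' @param x An `"mcts_run"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mcts_run <- function(x, ...) {
  r <- x$records
  v <- r[r$valid & !is.na(r$raw_score), ]
  if (nrow(v) == 0L) {
    warning("no valid product to plot")
    return(invisible(x))
  }
  best <- cummax(ifelse(is.na(r$raw_score), -Inf, r$raw_score))
  graphics::plot(r$step, best, type = "s", xlab = "step",
                 ylab = "raw score", main = "Best score so far", ...)
  graphics::points(v$step, v$raw_score, pch = ".", col = "grey40")
  if (!is.null(x$cycle_interval) && max(r$cycle) > 1) {
    graphics::abline(v = x$cycle_interval * seq_len(max(r$cycle) - 1),
                     lty = 3, col = "grey60")
  }
  invisible(x)
}
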