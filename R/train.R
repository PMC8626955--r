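# Training the recurrent next-token policy on partial-SMILES fragments.

#' Train the next-token policy
#'
#' Fits a two-layer LSTM language model over the fragment vocabulary by
#' teacher forcing: every training sequence is `begin + fragment + terminal`,
#' and the per-position cross-entropy of the next token is minimized with
#' Adam.  Given the same dataset, configuration and `seed`, two runs produce
#' identical parameters.
#'
#' @param dataset A [build_partial_dataset()] result, or a character vector
#'   of fragments.
#' @param vocab Optional [smiles_vocabulary()]; derived from the fragments
#'   when omitted.  Supplying one allows a vocabulary shared with other
#'   models.
#' @param epochs Number of passes over the dataset (default 20).
#' @param hidden_size LSTM units per layer (default 256).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Sequences per gradient step (default 128).
#' @param seed Integer seed for parameter initialization and batch
#'   shuffling; `NULL` uses the current RNG state.
#' @param validation Optional character vector of held-out fragments; when
#'   given, a per-epoch validation cross-entropy is recorded alongside the
#'   training loss.
#' @param quiet Suppress the per-epoch progress message.
#' @return An object of class `"smiles_policy"`: the trained network, the
#'   vocabulary, the configuration, and `loss_trace` (data frame with one
#'   row per epoch: `epoch`, `train_loss`, and `val_loss` when `validation`
#'   was supplied).
#' @seealso [next_token_distribution()], [rollout_completion()],
#'   [save_policy()]
#' @export
train_policy <- function(dataset, vocab = NULL, epochs = 20L,
                         hidden_size = 256L, learning_rate = 1e-3,
                         batch_size = 128L, seed = NULL,
                         validation = NULL, quiet = FALSE) {
  fragments <- if (inherits(dataset, "partial_smiles_dataset"))
    dataset$fragments else dataset
  stopifnot(is.character(fragments))
  fragments <- fragments[nchar(fragments) > 0]
  if (length(fragments) == 0L) stop("dataset is empty")
  if (is.null(vocab)) vocab <- smiles_vocabulary(fragments, from_fragments = TRUE)
  if (!is.null(seed)) set.seed(seed)

  seqs <- lapply(fragments, function(f) vocab_index(vocab, smiles_tokens(f)))
  begin_idx <- vocab$index[[vocab$begin]]
  term_idx <- vocab$index[[vocab$terminal]]
  V <- length(vocab$tokens)

  net <- lstm_init(V, hidden_size, n_layers = 2L)
  opt <- adam_init(net)

  pad_batch <- function(batch) {
    lens <- vapply(batch, length, integer(1)) + 1L  # begin + tokens
    Tm <- max(lens)
    inputs <- targets <- matrix(NA_integer_, length(batch), Tm)
    for (i in seq_along(batch)) {
      s <- batch[[i]]
      inputs[i, seq_len(lens[i])] <- c(begin_idx, s)
      targets[i, seq_len(lens[i])] <- c(s, term_idx)
    }
    list(inputs = inputs, targets = targets)
  }

  eval_loss <- function(frag_idx_list) {
    tot <- 0; n <- 0
    for (chunk in split(frag_idx_list,
                        ceiling(seq_along(frag_idx_list) / batch_size))) {
      pb <- pad_batch(chunk)
      fwd <- lstm_forward(net, pb$inputs)
      bw_loss <- 0
      for (t in seq_len(ncol(pb$targets))) {
        tg <- pb$targets[, t]
        rows <- which(!is.na(tg))
        if (!length(rows)) next
        pr <- .softmax_rows(fwd$logits[[t]][rows, , drop = FALSE])
        bw_loss <- bw_loss - sum(log(pmax(pr[cbind(seq_along(rows), tg[rows])],
                                          1e-300)))
        n <- n + length(rows)
      }
      tot <- tot + bw_loss
    }
    tot / n
  }

  val_seqs <- if (!is.null(validation)) {
    validation <- validation[nchar(validation) > 0]
    lapply(validation, function(f) vocab_index(vocab, smiles_tokens(f)))
  } else NULL

  trace <- data.frame(epoch = integer(0), train_loss = numeric(0))
  if (!is.null(val_seqs)) trace$val_loss <- numeric(0)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(length(seqs))
    epoch_nll <- 0; epoch_tok <- 0
    for (chunk in split(ord, ceiling(seq_along(ord) / batch_size))) {
      pb <- pad_batch(seqs[chunk])
      fwd <- lstm_forward(net, pb$inputs)
      bw <- lstm_backward(net, fwd, pb$targets)
      epoch_nll <- epoch_nll + bw$total_nll
      epoch_tok <- epoch_tok + bw$n_tok
      up <- adam_update(net, bw$grads, opt, lr = learning_rate)
      net <- up$net; opt <- up$opt
    }
    row <- data.frame(epoch = epoch, train_loss = epoch_nll / epoch_tok)
    if (!is.null(val_seqs)) row$val_loss <- eval_loss(val_seqs)
    trace <- rbind(trace, row)
    if (!quiet) {
      message(sprintf("epoch %d/%d  cross-entropy %.4f%s", epoch, epochs,
                      row$train_loss,
                      if (!is.null(val_seqs))
                        sprintf("  (validation %.4f)", row$val_loss) else ""))
    }
  }

  structure(list(
    net = net, vocab = vocab, loss_trace = trace,
    config = list(epochs = epochs, hidden_size = hidden_size,
                  learning_rate = learning_rate, batch_size = batch_size,
                  n_layers = 2L),
    meta = list(seed = seed, n_fragments = length(fragments),
                vocab_hash = vocab_hash(vocab),
                corpus_fingerprint = .fragments_fingerprint(fragments),
                trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "smiles_policy")
}

.fragments_fingerprint <- function(fragments) {
  s <- paste(sort(fragments), collapse = "\n")
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 2147483647
  sprintf("%d-%d", length(fragments), h)
}

#' @export
print.smiles_policy <- function(x, ...) {
  cat("Two-layer LSTM next-token policy\n")
  cat(sprintf("  vocabulary: %d tokens | hidden units: %d | epochs: %d\n",
              length(x$vocab$tokens), x$config$hidden_size, x$config$epochs))
  n <- nrow(x$loss_trace)
  if (n > 0) {
    cat(sprintf("  cross-entropy: %.4f (first epoch) -> %.4f (last epoch)\n",
                x$loss_trace$train_loss[1], x$loss_trace$train_loss[n]))
  }
  invisible(x)
}

#' @export
summary.smiles_policy <- function(object, ...) {
  print(object)
  cat("  trained on", object$meta$n_fragments, "fragments; seed:",
      if (is.null(object$meta$seed)) "(session RNG)" else object$meta$seed, "\n")
  invisible(object$loss_trace)
}

#' Next-token probabilities for fragment prefixes
#'
#' @param object A `"smiles_policy"`.
#' @param prefix Character vector of chemical tokens (single prefix), or a
#'   SMILES string to be tokenized when `tokenize = TRUE`.
#' @param type `"prob"` for the softmax distribution, `"logits"` for raw
#'   read-out scores.
#' @param tokenize Treat `prefix` as an untokenized string.
#' @param ... Unused.
#' @return Named numeric vector over the vocabulary.
#' @export
predict.smiles_policy <- function(object, prefix = character(0),
                                  type = c("prob", "logits"),
                                  tokenize = FALSE, ...) {
  type <- match.arg(type)
  if (tokenize) prefix <- smiles_tokens(prefix)
  st <- policy_state_for(object, prefix)
  if (type == "prob") return(policy_probs(object, st))
  logits <- st$logits
  names(logits) <- object$vocab$tokens
  logits
}

#' Sample fragment completions from the policy
#'
#' @param object A `"smiles_policy"`.
#' @param nsim Number of fragments to sample.
#' @param seed Optional integer seed.
#' @param prefix Fragment prefix each rollout starts from.
#' @param max_len Length cap in tokens.
#' @param ... Unused.
#' @return Character vector of `nsim` fragment strings.
#' @export
simulate.smiles_policy <- function(object, nsim = 1, seed = NULL,
                                   prefix = character(0), max_len = 35L, ...) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(nsim), function(i) {
    smiles_detokenize(rollout_completion(object, prefix, max_len))
  }, character(1))
}

#' @export
plot.smiles_policy <- function(x, ...) {
  tr <- x$loss_trace
  graphics::plot(tr$epoch, tr$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "cross-entropy",
                 main = "Policy training loss", ...)
  if (!is.null(tr$val_loss)) {
    graphics::lines(tr$epoch, tr$val_loss, type = "b", lty = 2, pch = 1)
    graphics::legend("topright", c("train", "validation"),
                     lty = c(1, 2), pch = c(16, 1), bty = "n")
  }
  invisible(x)
}

#' @export
coef.smiles_policy <- function(object, ...) {
  c(list(Wy = object$net$Wy, by = object$net$by),
    stats::setNames(object$net$layers,
                    paste0("layer", seq_along(object$net$layers))))
}

#' Save / load a policy checkpoint
#'
#' The checkpoint is a versioned RDS archive holding the network weights,
#' the vocabulary, the training configuration and metadata.  Loading
#' validates the format version and the vocabulary hash.
#'
#' @param policy A `"smiles_policy"`.
#' @param path File path.
#' @return `save_policy` returns `path` invisibly; `load_policy` the policy.
#' @export
save_policy <- function(policy, path) {
  stopifnot(inherits(policy, "smiles_policy"))
  obj <- list(format = "molsculpt-policy", version = 1L, policy = policy)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "molsculpt-policy")) {
    stop("not a molsculpt policy checkpoint: ", path)
  }
  if (obj$version > 1L) stop("checkpoint version ", obj$version,
                             " is newer than this package supports")
  policy <- obj$policy
  if (!identical(vocab_hash(policy$vocab), policy$meta$vocab_hash)) {
    stop("checkpoint vocabulary hash mismatch; file is corrupt")
  }
  policy
}
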