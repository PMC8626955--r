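# Token vocabulary for the next-token policy.
#
# The vocabulary is the ordered set of chemical tokens observed in the
# training fragments plus two sentinels: a begin-of-sequence token fed as the
# first input, and a terminal token whose emission ends a fragment.  The
# sentinels use characters outside the SMILES alphabet so they can never
# collide with a chemical token.

.BEGIN_TOKEN <- "^"
.TERMINAL_TOKEN <- "$end$"

#' Build a token vocabulary
#'
#' @param tokens Character vector of chemical tokens, or a character vector
#'   of SMILES fragments from which tokens are collected (set
#'   `from_fragments = TRUE`), or a `"partial_smiles_dataset"`.
#' @param from_fragments Tokenize the inputs and collect distinct tokens.
#' @return An object of class `"smiles_vocab"`: list with `tokens` (all
#'   tokens, sentinels last), `begin`, `terminal`, and `index` (named integer
#'   vector mapping token to 1-based position).
#' @export
smiles_vocabulary <- function(tokens, from_fragments = FALSE) {
  if (inherits(tokens, "partial_smiles_dataset")) {
    tokens <- tokens$fragments
    from_fragments <- TRUE
  }
  stopifnot(is.character(tokens))
  if (from_fragments) {
    tokens <- unique(unlist(lapply(tokens[nchar(tokens) > 0], smiles_tokens)))
  }
  tokens <- unique(tokens)
  if (any(tokens %in% c(.BEGIN_TOKEN, .TERMINAL_TOKEN))) {
    stop("chemical tokens may not equal the sentinel tokens")
  }
  all_tokens <- c(sort(tokens), .BEGIN_TOKEN, .TERMINAL_TOKEN)
  index <- seq_along(all_tokens)
  names(index) <- all_tokens
  structure(list(tokens = all_tokens,
                 begin = .BEGIN_TOKEN,
                 terminal = .TERMINAL_TOKEN,
                 index = index),
            class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  chem <- setdiff(x$tokens, c(x$begin, x$terminal))
  cat("SMILES token vocabulary:", length(x$tokens), "tokens",
      sprintf("(%d chemical + 2 sentinels)\n", length(chem)))
  cat(" ", paste(utils::head(chem, 25), collapse = " "),
      if (length(chem) > 25) "...\n" else "\n")
  invisible(x)
}

#' @export
length.smiles_vocab <- function(x) length(x$tokens)

vocab_index <- function(vocab, tokens) {
  if (length(tokens) == 0L) return(integer(0))
  idx <- vocab$index[tokens]
  if (anyNA(idx)) {
    stop("token(s) outside the vocabulary: ",
         paste(unique(tokens[is.na(idx)]), collapse = " "))
  }
  unname(idx)
}

# stable fingerprint used to validate checkpoints against a vocabulary
vocab_hash <- function(vocab) {
  s <- paste(vocab$tokens, collapse = "\n")
  # simple polynomial rolling hash; stable across sessions and platforms
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 2147483647
  sprintf("%d-%d", length(vocab$tokens), h)
}

#' One-hot encode a token sequence
#'
#' Prepends the begin sentinel and encodes each position as an indicator
#' vector over the vocabulary, the input representation consumed by the
#' recurrent policy.
#'
#' @param tokens Character vector of chemical tokens (may be empty).
#' @param vocab A [smiles_vocabulary()].
#' @return A numeric matrix with `length(tokens) + 1` rows and
#'   `length(vocab)` columns; each row has a single 1.
#' @export
encode_tokens <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  idx <- c(vocab$index[[vocab$begin]], vocab_index(vocab, tokens))
  m <- matrix(0, nrow = length(idx), ncol = length(vocab$tokens),
              dimnames = list(NULL, vocab$tokens))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}
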