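# String surgery on seed SMILES.
#
# A replacement spec (start, length) is expressed in token positions of the
# seed, 0-based as counted from before the first token: start = 0, length = 0
# inserts at the front; start = T, length = 0 appends.  The result is plain
# text; whether it is a molecule is decided later by the parser.

#' Create a replacement spec
#'
#' @param start 0-based token index of the first seed token removed (equal to
#'   the seed token count for a pure append).
#' @param length Number of seed tokens removed (0 for a pure insertion).
#' @return A `"replacement_spec"`: list with `start` and `length`.
#' @export
replacement_spec <- function(start, length) {
  start <- as.integer(start); length <- as.integer(length)
  stopifnot(length(start) == 1L, length(length) == 1L,
            !is.na(start), !is.na(length), start >= 0L, length >= 0L)
  structure(list(start = start, length = length), class = "replacement_spec")
}

#' @export
format.replacement_spec <- function(x, ...) {
  sprintf("replace %d token(s) at position %d", x$length, x$start)
}

#' @export
print.replacement_spec <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Splice a fragment into a seed SMILES
#'
#' Deletes the token window `[start, start + length)` from the seed and
#' inserts `fragment` in its place.  `length = 0` is a pure insertion, an
#' empty fragment a pure deletion.  The output is a string, not guaranteed
#' to be chemically valid (e.g. a splice may orphan a ring-closure digit);
#' invalid products are simply scored as invalid downstream.
#'
#' @param seed Seed SMILES string.
#' @param spec A [replacement_spec()] (or a list with `start` and `length`).
#' @param fragment Fragment text to insert (may be `""`).
#' @return The edited SMILES string.
#' @examples
#' splice_smiles("CCO", replacement_spec(1, 1), "N")   # "CNO"
#' splice_smiles("CCO", replacement_spec(0, 0), "C")   # "CCCO"
#' splice_smiles("CCO", replacement_spec(1, 2), "")    # "C"
#' @export
splice_smiles <- function(seed, spec, fragment) {
  stopifnot(is.character(seed), length(seed) == 1L,
            is.character(fragment), length(fragment) == 1L)
  toks <- smiles_tokens(seed)
  n <- length(toks)
  start <- as.integer(spec$start); len <- as.integer(spec$length)
  if (is.na(start) || is.na(len) || start < 0L || len < 0L ||
      start + len > n) {
    stop(sprintf("replacement spec (start=%s, length=%s) out of bounds for a %d-token seed",
                 spec$start, spec$length, n))
  }
  head <- if (start > 0L) paste0(toks[seq_len(start)], collapse = "") else ""
  tail <- if (start + len < n) {
    paste0(toks[(start + len + 1L):n], collapse = "")
  } else ""
  paste0(head, fragment, tail)
}

#' Enumerate the replacement layer for a seed
#'
#' All (start, length) windows of the seed with `0 <= length <=
#' min(max_removal_len, T - start)` and `0 <= start <= T`, where `T` is the
#' seed token count.  These become the first-layer nodes of the search tree:
#' each fixes which part of the seed is deleted before the generated fragment
#' is inserted.
#'
#' @param seed Seed SMILES (must parse).
#' @param max_removal_len Cap on the number of tokens removed; `Inf` for
#'   unbounded.
#' @return List of [replacement_spec()] objects, ordered by start then length.
#' @export
enumerate_replacements <- function(seed, max_removal_len = 10L) {
  if (!is_valid_smiles(seed)) stop("seed is not a valid SMILES: '", seed, "'")
  n <- length(smiles_tokens(seed))
  out <- list()
  for (start in 0:n) {
    for (len in 0:min(max_removal_len, n - start)) {
      out[[length(out) + 1L]] <- replacement_spec(start, len)
    }
  }
  out
}
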