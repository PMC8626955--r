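# Partial-SMILES extraction and the insertion-context validity filter.
#
# A partial SMILES is any contiguous token-substring of a molecule's SMILES.
# Most such substrings are not molecules themselves ("(C", "cc1", "=O..."),
# so validity is defined by insertion context: a fragment is kept if pasting
# it into at least one of the templates C*C or C(*)C (replacing *) yields a
# parseable molecule.  The filtered fragment set is what the next-token
# policy is trained on.

#' Enumerate the partial SMILES of one molecule
#'
#' Returns every distinct contiguous token-substring of `smiles` with between
#' 1 and `max_len` tokens.  Substrings are taken at the token level, so a
#' two-letter element or a bracket atom is never split.
#'
#' @param smiles A valid SMILES string.
#' @param max_len Maximum fragment length in tokens (default 35).
#' @return Character vector of distinct fragments.
#' @examples \dontrun{
#' extract_partials("CCO", max_len = 3)   # "C" "CC" "CCO" "CO" "O"
#' }
#' @export
extract_partials <- function(smiles, max_len = 35L) {
  stopifnot(length(max_len) == 1L, max_len >= 1L)
  if (!is_valid_smiles(smiles)) {
    stop("not a valid SMILES: '", smiles, "'")
  }
  toks <- smiles_tokens(smiles)
  n <- length(toks)
  if (n == 0L) return(character(0))
  out <- character(0)
  for (start in seq_len(n)) {
    ends <- start:min(n, start + max_len - 1L)
    # cumulative paste along the window keeps this O(total output length)
    frags <- cumpaste(toks[start:(max(ends) )])
    out <- c(out, frags)
  }
  unique(out)
}

# cumulative concatenation of a token vector: c("C","C","O") -> "C","CC","CCO"
cumpaste <- function(tokens) {
  n <- length(tokens)
  out <- character(n)
  acc <- ""
  for (i in seq_len(n)) {
    acc <- paste0(acc, tokens[i])
    out[i] <- acc
  }
  out
}

#' Context-validity of partial SMILES fragments
#'
#' A fragment is a valid partial SMILES if substituting it for `*` in at
#' least one of the two insertion contexts `C*C` and `C(*)C` produces a
#' string the parser accepts as a molecule.  The empty fragment is valid
#' (`C*C` becomes `CC`), which is what permits pure deletions downstream.
#' Any parser failure counts as "does not parse"; the function never throws.
#'
#' @param fragments Character vector of fragments (possibly empty strings).
#' @return Logical vector the same length as `fragments`.
#' @examples \dontrun{
#' is_valid_partial(c("(C)", "(", "", "cc"))
#' }
#' @export
is_valid_partial <- function(fragments) {
  stopifnot(is.character(fragments))
  if (length(fragments) == 0L) return(logical(0))
  linear <- is_valid_smiles(paste0("C", fragments, "C"))
  need <- !linear
  branch <- logical(length(fragments))
  if (any(need)) {
    branch[need] <- is_valid_smiles(paste0("C(", fragments[need], ")C"))
  }
  linear | branch
}

#' Build the partial-SMILES training dataset from a corpus
#'
#' Exhaustively extracts token-substrings (up to `max_len` tokens) from every
#' molecule in the corpus, keeps those that pass the insertion-context filter
#' of [is_valid_partial()], and deduplicates.  Unparseable corpus entries are
#' skipped with a message rather than aborting the build.
#'
#' @param corpus Character vector of SMILES strings.
#' @param max_len Maximum fragment length in tokens (default 35).
#' @param quiet Suppress the skip/progress messages.
#' @return An object of class `"partial_smiles_dataset"`: a list with
#'   `fragments` (character vector), `source_count` (molecules actually
#'   processed) and `filter_stats` (named counts: `extracted` distinct
#'   fragments before filtering, `retained` after, `skipped_molecules`).
#' @export
build_partial_dataset <- function(corpus, max_len = 35L, quiet = FALSE) {
  stopifnot(is.character(corpus))
  if (length(corpus) == 0L) stop("corpus is empty")
  ok <- is_valid_smiles(corpus)
  if (any(!ok) && !quiet) {
    message(sum(!ok), " corpus line(s) did not parse and were skipped")
  }
  frags <- character(0)
  for (smi in corpus[ok]) frags <- c(frags, extract_partials(smi, max_len))
  frags <- unique(frags)
  extracted <- length(frags)
  keep <- is_valid_partial(frags)
  retained <- frags[keep]
  if (length(retained) == 0L) {
    stop("no fragment survived the insertion-context filter")
  }
  structure(list(
    fragments = retained,
    source_count = sum(ok),
    filter_stats = c(extracted = extracted,
                     retained = length(retained),
                     skipped_molecules = sum(!ok))
  ), class = "partial_smiles_dataset")
}

#' @export
print.partial_smiles_dataset <- function(x, ...) {
  cat("Partial-SMILES dataset\n")
  cat("  source molecules:", x$source_count, "\n")
  cat("  fragments extracted:", x$filter_stats[["extracted"]],
      "| retained after context filter:", x$filter_stats[["retained"]], "\n")
  invisible(x)
}

#' Write / read a partial-SMILES dataset
#'
#' Plain-text artifact: one fragment per line, with a JSON sidecar
#' (`<path>.json`) holding the filter statistics and generating parameters.
#'
#' @param dataset A `"partial_smiles_dataset"`.
#' @param path Output path for the fragment list.
#' @param params Named list of generating parameters stored in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_partial_dataset <- function(dataset, path, params = list()) {
  stopifnot(inherits(dataset, "partial_smiles_dataset"))
  writeLines(dataset$fragments, path)
  side <- list(source_count = dataset$source_count,
               filter_stats = as.list(dataset$filter_stats),
               params = params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_partial_dataset
#' @export
read_partial_dataset <- function(path) {
  frags <- readLines(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  } else list(source_count = NA_integer_,
              filter_stats = list(extracted = NA, retained = length(frags),
                                  skipped_molecules = NA))
  structure(list(fragments = frags,
                 source_count = side$source_count,
                 filter_stats = unlist(side$filter_stats)),
            class = "partial_smiles_dataset")
}
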