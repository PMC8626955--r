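# SMILES tokenization.
#
# A "character" of a SMILES string, in the sense used throughout this package,
# is a token: bracket atoms ([nH], [C@@H], [O-]...), the two-letter halogens
# Cl and Br, and %NN two-digit ring-bond labels are single tokens, so string
# surgery can never split an atom or a ring label in half.

# Alternation order matters: longest lexemes first.
.smiles_token_regex <- paste0(
  "\\[[^\\]]*\\]",           # bracket atom (any content up to the closing ])
  "|Cl|Br",                  # two-letter organic-subset halogens
  "|%[0-9]{2}",              # two-digit ring-bond closure
  "|[BCNOPSFIbcnops0-9=#$:/\\\\().+*@~-]" # one-character tokens
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into tokens such that multi-character lexical units
#' (bracket atoms such as `[nH]`, the two-letter elements `Cl` and `Br`, and
#' `%NN` two-digit ring-bond labels) are kept whole.  The input does not have
#' to be a chemically valid molecule; tokenization is purely lexical.
#'
#' @param smiles A single character string (possibly empty).
#' @return A character vector of tokens; `character(0)` for the empty string.
#'   Concatenating the tokens reproduces the input exactly.
#' @examples
#' smiles_tokens("CCO")
#' smiles_tokens("C[nH]1cccc1Cl")
#' @seealso [smiles_detokenize()]
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (nchar(smiles) == 0L) return(character(0))
  m <- gregexpr(.smiles_token_regex, smiles, perl = TRUE)[[1]]
  toks <- if (m[1] == -1L) character(0) else regmatches(smiles, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(smiles)) {
    # locate the first character not covered by any token
    covered <- rep(FALSE, nchar(smiles))
    if (m[1] != -1L) {
      for (i in seq_along(m)) {
        covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
      }
    }
    bad <- which(!covered)[1]
    stop(sprintf("character '%s' at position %d is outside the SMILES alphabet",
                 substr(smiles, bad, bad), bad))
  }
  toks
}

#' Reassemble a SMILES string from tokens
#'
#' Inverse of [smiles_tokens()]: concatenates a token vector back into the
#' string it came from, so `smiles_detokenize(smiles_tokens(s))` is `s`.
#'
#' @param tokens Character vector of SMILES tokens (may be empty).
#' @return A single character string.
#' @export
smiles_detokenize <- function(tokens) {
  stopifnot(is.character(tokens))
  paste0(tokens, collapse = "")
}

#' Number of tokens in a SMILES string
#'
#' @param smiles A single character string.
#' @return Integer token count.
#' @keywords internal
smiles_token_count <- function(smiles) length(smiles_tokens(smiles))
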