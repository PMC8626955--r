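# Deterministic fixture-corpus generator.
#
# Stands in for a large public screening library (the reference experiments
# used ~250k ZINC molecules): assembles small drug-like-ish molecules by
# rule from a table of chemically safe building blocks — chains, branches,
# five/six-membered rings over C/N/O/S plus halogens — and keeps only
# strings the parser verifies.  The same (n, seed) pair always yields the
# same corpus.

.fixture_units <- function() {
  c("C", "CC", "CCC", "CCCC", "CCO", "CCN", "CO", "CN", "O", "N", "S",
    "C(C)C", "C(C)(C)C", "C(=O)", "C(=O)O", "C(=O)N", "C(=O)OC", "C(=O)NC",
    "C#N", "C(F)(F)F", "CCl", "CBr", "CF", "N(C)C", "OC", "NC",
    "c1ccccc1", "c1ccncc1", "c1ccncn1", "c1ccco1", "c1cccs1", "c1cc[nH]c1",
    "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "C1CCNC1", "C1CCOC1", "C1CCCC1",
    "CCCCCC", "CCCCCCCC")
}

#' Generate a deterministic fixture corpus
#'
#' @param n Number of distinct molecules to generate.
#' @param seed Integer RNG seed; the same `(n, seed)` always returns the
#'   same corpus.
#' @param max_units Maximum number of building blocks per molecule.
#' @return Character vector of `n` distinct, parser-verified SMILES.
#' @examples \dontrun{
#' corpus <- generate_fixture_corpus(100, seed = 7)
#' }
#' @export
generate_fixture_corpus <- function(n, seed = 1L, max_units = 4L) {
  stopifnot(n >= 1L, max_units >= 1L)
  set.seed(seed)
  units <- .fixture_units()
  out <- character(0)
  seen <- new.env(parent = emptyenv())
  attempts <- 0L
  max_attempts <- 400L * n
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not generate ", n, " distinct molecules within ",
           max_attempts, " attempts; lower n or raise max_units")
    }
    k <- sample.int(max_units, 1L)
    picks <- sample(units, k, replace = TRUE)
    # occasionally wrap a middle unit as a branch for shape diversity
    if (k >= 3L && stats::runif(1) < 0.4) {
      j <- sample(2:(k - 1L), 1L)
      picks[j] <- paste0("(", picks[j], ")")
    }
    smi <- paste0(picks, collapse = "")
    if (exists(smi, envir = seen, inherits = FALSE)) next
    assign(smi, TRUE, envir = seen)
    if (isTRUE(is_valid_smiles(smi))) out <- c(out, smi)
  }
  out
}
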