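# Molecular objectives and reward normalization.
#
# Scores are returned as "score_result" objects carrying the raw objective
# value (native units), named sub-components where the objective has them,
# and the normalized [0,1] reward fed to the search tree.  The tree's UCB
# guarantees assume rewards in [0,1], which is why every objective passes
# through normalize_reward (QED is already on that scale).

score_result <- function(raw, normalized, components = NULL) {
  structure(list(raw = raw, normalized = normalized, components = components),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("score: raw = %.4f, normalized = %.4f\n", x$raw, x$normalized))
  if (!is.null(x$components)) {
    cat("  components:",
        paste(sprintf("%s = %.4f", names(x$components), x$components),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Linear reward normalization onto [0, 1]
#'
#' `clip((raw - lo) / (hi - lo), 0, 1)`; monotone non-decreasing in `raw`.
#' The bounds are artifact configuration, chosen wide enough that the
#' objective rarely clips.
#'
#' @param raw Numeric vector of raw objective values.
#' @param lo,hi Bounds mapped to 0 and 1 (`lo < hi`).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_reward <- function(raw, lo, hi) {
  if (!(lo < hi)) stop("normalize_reward: lo must be < hi")
  pmin(1, pmax(0, (raw - lo) / (hi - lo)))
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' The Bickerton et al. desirability-weighted QED as computed by the
#' chemistry toolkit.  Already on the unit interval, so the normalized
#' reward equals the raw score.
#'
#' @param smiles A valid SMILES string.
#' @return A `"score_result"` with `raw = normalized` in `[0, 1]`.
#' @export
qed_score <- function(smiles) {
  q <- .chem_qed(smiles)
  if (is.na(q)) stop("qed_score: invalid SMILES '", smiles, "'")
  score_result(raw = q, normalized = q)
}

#' Penalized logP
#'
#' Combines three components: the Crippen octanol-water partition estimate
#' `logp`, the Ertl-Schuffenhauer synthetic-accessibility score `sa`, and
#' the large-ring penalty `ring_penalty = max(0, largest ring size - 6)`.
#' Under the default `"penalize"` convention the raw score is
#' `logp - sa - ring_penalty`, the form used throughout the penalized-logP
#' optimization literature; `"as-printed"` adds all three terms instead.
#'
#' @param smiles A valid SMILES string.
#' @param sign_convention `"penalize"` (default) or `"as-printed"`.
#' @param lo,hi Normalization bounds for the `[0, 1]` reward (defaults -15
#'   and 15).
#' @return A `"score_result"` with components `logp`, `sa`, `ring_penalty`.
#' @export
plogp_score <- function(smiles, sign_convention = c("penalize", "as-printed"),
                        lo = -15, hi = 15) {
  sign_convention <- match.arg(sign_convention)
  logp <- .chem_logp(smiles)
  if (is.na(logp)) stop("plogp_score: invalid SMILES '", smiles, "'")
  sa <- .chem_sa(smiles)
  rings <- .chem_ring_sizes(smiles)[[1]]
  ring_penalty <- if (length(rings) == 0L) 0 else max(0, max(rings) - 6)
  raw <- if (sign_convention == "penalize") logp - sa - ring_penalty
         else logp + sa + ring_penalty
  score_result(raw = raw, normalized = normalize_reward(raw, lo, hi),
               components = c(logp = logp, sa = sa,
                              ring_penalty = ring_penalty))
}

#' ECFP4 Tanimoto similarity
#'
#' Tanimoto coefficient of radius-2 circular (Morgan/ECFP4) fingerprints
#' hashed to 2048 bits, computed as `|bits(a) & bits(b)| / |bits(a) | bits(b)|`.
#' Vectorized over the longer argument with recycling of the shorter one.
#'
#' @param a,b Character vectors of valid SMILES.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  bits_a <- .chem_morgan_bits(a)
  bits_b <- .chem_morgan_bits(b)
  vapply(seq_len(n), function(i) {
    ba <- bits_a[[i]]; bb <- bits_b[[i]]
    if (is.null(ba)) stop("tanimoto_similarity: invalid SMILES '", a[i], "'")
    if (is.null(bb)) stop("tanimoto_similarity: invalid SMILES '", b[i], "'")
    u <- length(union(ba, bb))
    if (u == 0L) return(1)  # both fingerprints empty: identical
    length(intersect(ba, bb)) / u
  }, numeric(1))
}

#' Similarity-constrained penalized-logP reward
#'
#' The constrained-optimization objective: a candidate scores its penalized
#' logP reward only when its ECFP4 Tanimoto similarity to the reference seed
#' is at least `delta`; candidates below the threshold (or that fail any
#' chemistry step) receive `invalid_reward`.  `delta = 0` reduces to the
#' plain penalized-logP reward.
#'
#' @param candidate Candidate SMILES.
#' @param seed Reference (seed) SMILES; must be valid.
#' @param delta Similarity threshold in `[0, 1]`.
#' @param invalid_reward Normalized reward for failing candidates.
#' @param ... Passed on to [plogp_score()].
#' @return A `"score_result"`.
#' @export
constrained_reward <- function(candidate, seed, delta,
                               invalid_reward = 0, ...) {
  res <- tryCatch({
    sim <- tanimoto_similarity(candidate, seed)
    ps <- plogp_score(candidate, ...)
    if (sim < delta) {
      score_result(raw = ps$raw, normalized = invalid_reward,
                   components = c(ps$components, similarity = sim))
    } else {
      score_result(raw = ps$raw, normalized = ps$normalized,
                   components = c(ps$components, similarity = sim))
    }
  }, error = function(e) NULL)
  if (is.null(res)) {
    res <- score_result(raw = NA_real_, normalized = invalid_reward)
  }
  res
}

# ---- score registry --------------------------------------------------------

.score_registry <- new.env(parent = emptyenv())

#' Register a scoring function by name
#'
#' Any callable mapping a SMILES string to a `"score_result"` (or to a list
#' with `raw` and `normalized` fields) can be plugged into the search and
#' selected by name, e.g. from the command line.
#'
#' @param name Registry key.
#' @param factory Function `(...) -> function(smiles) -> score_result`.
#' @return Invisibly, `name`.
#' @export
register_score <- function(name, factory) {
  stopifnot(is.character(name), length(name) == 1L, is.function(factory))
  assign(name, factory, envir = .score_registry)
  invisible(name)
}

#' Look up a scoring function
#'
#' Built-in names: `"qed"`, `"plogp"` (accepts `sign_convention`, `lo`,
#' `hi`) and `"constrained_plogp"` (requires `seed` and `delta`).
#'
#' @param name Registry key.
#' @param ... Arguments bound into the returned scorer.
#' @return A function `smiles -> score_result`.
#' @export
score_function <- function(name, ...) {
  if (!exists(name, envir = .score_registry, inherits = FALSE)) {
    stop("unknown score '", name, "'; registered: ",
         paste(ls(.score_registry), collapse = ", "))
  }
  factory <- get(name, envir = .score_registry)
  factory(...)
}

# built-ins registered at load time
.register_builtin_scores <- function() {
  register_score("qed", function(...) function(smiles) qed_score(smiles))
  register_score("plogp", function(...) {
    args <- list(...)
    function(smiles) do.call(plogp_score, c(list(smiles), args))
  })
  register_score("constrained_plogp", function(seed, delta, ...) {
    args <- list(...)
    force(seed); force(delta)
    function(smiles) do.call(constrained_reward,
                             c(list(smiles, seed = seed, delta = delta), args))
  })
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_scores()
}
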