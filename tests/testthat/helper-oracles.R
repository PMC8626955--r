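# Independent reference computations used as oracles.
#
# These recompute published scoring formulas from raw molecular descriptors
# fetched from the chemistry worker, through code paths separate from the
# package's scorers.

# Bickerton-style QED: ADS desirability of each property, weighted geometric
# mean.  Parameters (published constants) are fetched once from the toolkit.
oracle_qed <- function(smiles) {
  par <- molsculpt:::.chem_call("qed_params")
  props <- molsculpt:::.chem_call("qed_detail", list(smiles = as.list(smiles)))
  ads <- function(x, p) {
    exp1 <- 1 + exp(-(x - p$C + p$D / 2) / p$E)
    exp2 <- 1 + exp(-(x - p$C - p$D / 2) / p$F)
    (p$A + p$B / exp1 * (1 - 1 / exp2)) / p$DMAX
  }
  w <- unlist(par$weights_mean)
  vapply(props, function(pr) {
    d <- vapply(seq_along(par$order), function(i) {
      nm <- par$order[[i]]
      ads(pr[[nm]], par$params[[nm]])
    }, numeric(1))
    exp(sum(w * log(d)) / sum(w))
  }, numeric(1))
}

# Crippen logP as the plain sum of per-atom contributions
oracle_logp <- function(smiles) {
  cs <- molsculpt:::.chem_call("logp_contribs", list(smiles = as.list(smiles)))
  vapply(cs, function(x) sum(unlist(x)), numeric(1))
}

# Ertl-Schuffenhauer synthetic accessibility, re-aggregated from raw
# ingredients (fragment scores, symmetry/size/stereo features)
oracle_sa <- function(smiles) {
  det <- molsculpt:::.chem_call("sa_detail", list(smiles = as.list(smiles)))
  vapply(det, function(d) {
    counts <- unlist(d$bit_counts)
    fscores <- unlist(d$fscores)
    nf <- sum(counts)
    score1 <- sum(fscores * counts) / nf
    natoms <- d$natoms
    size_penalty <- natoms^1.005 - natoms
    stereo_penalty <- log10(d$nchiral + 1)
    spiro_penalty <- log10(d$nspiro + 1)
    bridge_penalty <- log10(d$nbridge + 1)
    macro_penalty <- if (d$nmacro > 0) log10(2) else 0
    score2 <- -size_penalty - stereo_penalty - spiro_penalty -
      bridge_penalty - macro_penalty
    score3 <- if (natoms > length(counts)) {
      log(natoms / length(counts)) * 0.5
    } else 0
    sascore <- score1 + score2 + score3
    lo <- -4; hi <- 2.5
    sascore <- 11 - (sascore - lo + 1) / (hi - lo) * 9
    if (sascore > 8) sascore <- 8 + log(sascore + 1 - 9)
    min(10, max(1, sascore))
  }, numeric(1))
}

# reference Tanimoto from the toolkit's own similarity routine
oracle_tanimoto <- function(a, b) {
  molsculpt:::.chem_call("tanimoto", list(a = a, b = b))
}
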