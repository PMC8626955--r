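---
title: "Editing seed molecules with a tree search over partial SMILES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Editing seed molecules with a tree search over partial SMILES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hit-to-lead optimization starts from a concrete molecule and asks for close
derivatives with better properties.  String-based generative models handle
the *generation* half well — SMILES is a compact, sequence-model-friendly
encoding — but they cannot naturally *start from* a given molecule, because
an arbitrary substring of a SMILES is usually not a molecule at all: it may
open a branch it never closes, or reference a ring bond whose partner lies
outside the substring.

molsculpt's answer is to operate on the string anyway, but to keep the seed
as the scaffold: a search proposes *(deletion window, fragment)* pairs, the
fragment is spliced into the seed where the window was removed, and the
resulting string is handed to a chemistry parser.  Whatever parses is scored
by the objective; whatever does not is simply an unproductive leaf of the
search.  Validity is therefore not a constraint enforced by construction but
a property *learned and discovered* — the policy is trained only on
fragments that can occur inside molecules, and the tree learns which edit
sites tolerate which fragments.

## Components

### Tokenization

All positions and lengths are counted in SMILES *tokens*, not characters:
bracket atoms (`[nH]`), two-letter halogens (`Cl`, `Br`) and two-digit ring
labels (`%12`) are atomic units.  A character-level edit could split `Cl`
into `C` + `l`, silently turning chlorine into a carbon followed by garbage;
token-level surgery makes that impossible, and it makes the space of
deletion windows well defined.

### The partial-SMILES dataset and the context filter

From each corpus molecule, every contiguous token window up to
`max_len` tokens (default 35, configurable) is extracted.  A fragment is
retained if substituting it for `*` in **either** `C*C` or `C(*)C` yields a
parseable string.  The two contexts cover the two ways a fragment can sit
inside a molecule — in-chain or as/inside a branch — and the OR reading is
deliberately permissive: it keeps the empty fragment (so pure deletions stay
expressible downstream) and fragments like `(C)` that only work in one
context.  Filtering is the point: the policy should spend its capacity on
strings that can occur inside molecules.

### The policy

A two-layer LSTM over the fragment vocabulary, trained by teacher forcing
on `begin + fragment + terminal` sequences with Adam, minimizing
per-position cross-entropy.  The next-token law is the softmax of the final
logits; the begin sentinel is input-only and masked out of the output.  The
network, backpropagation-through-time and Adam are implemented in base R
matrix code inside the package; the implementation is validated in the test
suite by finite-difference-free oracles (softmax equivalence, loss descent,
single-fragment overfitting, determinism of seeded runs).

Hidden size (default 256), learning rate (1e-3) and batch size (128) are
package defaults in the range customary for small SMILES language models;
none of the acceptance properties depend on them, and the test suite uses
smaller hidden sizes (16–64) to keep runtimes in seconds.

### The search tree

The root's children are **replacement nodes**, one per deletion window
`(start, length)` with `length <= max_removal_len` (default 10; the layer
is quadratic in seed length without a cap).  Fragment tokens begin at the
grandchildren.  One iteration is classic UCT:

* **Select** by the UCB score with `c_p = 1/sqrt(2)`; unvisited children
  score +Inf (visit-each-once-first), exact ties break by insertion order,
  so a seeded run is fully reproducible.
* **Expand** a leaf on its second visit with the distinct tokens among `k`
  policy draws (`expansion_samples`, default 10).  A leaf at the fragment
  length cap receives only the terminal child.
* **Simulate**: complete the fragment by policy rollout (terminal leaves
  skip it), splice, parse, score.  One rollout is evaluated per iteration —
  the selected leaf — and every simulated product is recorded, valid or
  not.  Duplicate products are re-recorded but their score comes from a
  cache.
* **Backpropagate** the incremental-mean update along the path.

Rewards live in `[0, 1]` because the UCB regret guarantees assume a bounded
reward; objectives are normalized linearly with clipping
(penalized logP maps `[-15, 15]` onto `[0, 1]` by default — wide enough
that drug-sized molecules essentially never clip).  Unparseable products
earn `invalid_reward = 0`, the worst possible value: an invalid edit site
should look strictly worse than any valid one.

### Outer protocols

*Single* runs one tree for the whole budget: every product differs from the
seed in exactly one contiguous token region.  *Multi* restarts the tree
every `cycle_interval` steps (default 2000) from the best-scoring valid
molecule so far (ties: earliest).  Seed replacement is what lets edits
accumulate in several regions; its known failure mode — greedy commitment
to a local optimum — is accepted as a design trade-off, and the per-cycle
seed scores are non-decreasing by construction.  If a cycle produced no
valid molecule, the seed is retained with a warning.

### Objectives

* **QED** as computed by RDKit (already in `[0,1]`).
* **Penalized logP**: Crippen logP, Ertl–Schuffenhauer synthetic
  accessibility, and a large-ring penalty `max(0, largest SSSR ring − 6)`.
  The default combines them as `logP − SA − ring`, the penalization
  semantics used by the graph-based baselines this objective is usually
  compared against (and the only reading under which typical screening
  libraries have negative scores); a literal additive variant is available
  as `sign_convention = "as-printed"`.
* **Constrained penalized logP**: the same reward gated to
  `invalid_reward` whenever the ECFP4 (Morgan radius-2, 2048-bit) Tanimoto
  similarity to the seed falls below `delta`.  The constraint is enforced
  *in the reward* — the search is steered, not post-filtered — but
  unconstrained records are still written, so post-hoc filtering at other
  thresholds remains possible.

Any function from SMILES to a score can be registered under a name
(`register_score()`) and used from the CLI.

### Evaluation metrics

Over a record set: **validity** = parseable / all records; **uniqueness** =
distinct canonical molecules / valid records; **novelty** = fraction of the
distinct canonicals absent from the canonicalized training corpus.  The
novelty denominator is the distinct set — the reading consistent with both
quantities approaching 1 on diverse runs.  Constrained runs additionally
report improvement (penalized logP of the best qualifying product minus the
seed's), the similarity of that product, and success = "a qualifying product
with strictly positive improvement exists" (the seed itself, similarity 1
and improvement 0, is not a success).  Zero denominators yield `NA`, never
a silent 0.

## The chemistry backend

No R-native library provides the validity parser and descriptor set this
method needs (the OpenBabel-based R packages silently repair strings such
as `C(`, which would make the validity rate meaningless), so all parsing,
canonicalization, QED, Crippen logP, SA score, ring perception and
fingerprints are served by a persistent RDKit worker process speaking a
JSON-line protocol over a localhost socket.  Results are memoized per
SMILES on the R side; the worker holds no state, and its port probing is
deterministic so that lazily starting it never perturbs seeded runs.  The
scoring tests compare each component against an independent recomputation
(QED from raw properties through the desirability equations, logP as the
sum of per-atom contributions, SA re-aggregated from fragment scores and
complexity penalties) at 1e-6.

## The fixture corpus

`generate_fixture_corpus()` assembles small molecules by concatenating
chemically safe building blocks (short chains, branches, five/six-membered
rings over C/N/O/S, halogens, amide/ester/nitrile motifs), verifying every
string with the parser and deduplicating; the same `(n, seed)` always
yields the same corpus.  It emulates the *statistical shape* a SMILES
language model needs — realistic token inventory, fragment grammar, and a
QED spread wide enough (the tests require a span of at least 0.3) that
optimization has headroom.  It does **not** emulate a real screening
library: molecules are small (a handful of heavy atoms to ~20), there is no
stereochemistry, no charged species, and no bias toward synthesizable
chemotypes.  Consequently, passing tests demonstrate the *mechanics* —
extraction, training, search, scoring, protocols — at reduced scale; they
do not certify the absolute validity rates or score levels reachable with
a 250k-molecule library and a fully trained policy, which is precisely why
the shipped experiment presets accept any corpus.

## Toy landscapes used by the tests

Search behaviour is verified against brute force on an *enumerable* toy:
fragment vocabulary {C, N, O} + terminal, fragments up to 3 tokens,
deletions up to 2, reward = nitrogen fraction of the product's atoms.  The
seed is built from three-membered nitrogen rings (`N1NN1`, one `N1CN1`
carrying a protected carbon): any ≤2-token deletion inside a ring orphans a
digit or creates a two-membered ring and fails to parse, so the only
productive deletion is an exposed `CC` window — making the global optimum
("delete CC, insert NNN") unique and provable by enumerating the full
reachable set.

For the search-vs-random comparison both the tree search and the tree-less
baseline draw fragments from the *same* fixed categorical policy,
terminal-heavy and carbon-biased — the qualitative profile of language
models trained on real, carbon-dominated corpora, and the comparison the
method's efficiency claim is actually about.  Under such a policy the
optimal three-token fragment is rare for blind sampling, while the tree
still reaches it through accumulated value estimates; the expansion sample
is raised to 40 draws in this test so that rare-but-promising tokens
reliably enter the tree.  With a uniform policy instead, 5000 blind draws
saturate any landscape small enough to enumerate, and the comparison
degenerates to a tie — a property of the toy's size, not of the algorithms.
The Multi-vs-Single toy uses two exposed `CC` windows far apart: one
contiguous edit can remove at most one of them, giving Single a provable
score ceiling that Multi exceeds by accumulating edits across cycles.

## Problem sizes

The test suite and the acceptance script run the whole pipeline at fixture
scale, chosen so the mechanics are exercised end to end in minutes on one
CPU: corpora of 60–200 molecules, fragment caps of 8–12 tokens, hidden
sizes 16–64, 5-epoch training, searches of 500–5000 steps, ten seeds per
protocol.  The full-scale protocol (hundreds of seeds, 10,000 steps,
2000-step cycles, 250k-molecule corpus, 20-epoch training at hidden size
256) is expressed by the same functions and the shipped configuration
defaults.

## Numerical and degenerate-input choices

* UCB at `N = 0` is +Inf; `ln N(parent)` first applies when every sibling
  has been visited once, so the undefined `0/0` case never arises.
* The incremental mean is a convex update: rewards in `[0, 1]` keep every
  `Q` in `[0, 1]` regardless of visit counts.
* An edit that deletes the entire seed produces the empty string, which the
  backend rejects as "no molecule" (zero atoms); it is recorded invalid
  like any other failed product.
* Rollouts truncated at `max_fragment_len` are flagged and still spliced
  and scored — truncation is a search event, not an error.
* Checkpoints embed a vocabulary hash; loading a policy against a mutated
  vocabulary fails loudly rather than mis-indexing tokens.
* Ring-closure digits in spliced fragments are left as-is; a splice that
  re-pairs or orphans digits is scored as invalid rather than repaired.

## Known limitations

* Single-edit locality: within one cycle, products differ from the seed in
  one contiguous token region; multi-region structure only emerges through
  cycles.
* The Multi seed-selection rule (argmax raw score) can commit to a local
  optimum; no diversity mechanism is provided.
* No canonicalization-aware or bond-aware fragmenting (BRICS/RECAP-style);
  the method is purely lexical by design.
* Throughput is bounded by one R process and one RDKit worker; the search
  is intentionally single-sequence deterministic per seed, not parallel.
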