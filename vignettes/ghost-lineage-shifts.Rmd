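---
title: "Ghost lineages and the relative ordering of ancient gene transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghost lineages and the relative ordering of ancient gene transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostshift)
```

## The model

Gene transfers into the eukaryotic stem lineage are commonly ordered in
time by a branch-length proxy: the age of the donor clade's divergence
from the gene's position in the tree. When the true donor is a *ghost* —
an extinct or unsampled lineage — that proxy collapses to the age at which
the ghost diverged from its closest **sampled** sister branch, which is
systematically older than the transfer itself. `ghostshift` quantifies the
damage this does to *relative* orderings of transfer pairs.

All times are **ages before present** (larger = older), in whatever unit
the input tree uses (Ga for the intended application); a branch born at
its parent node and ending at its child node occupies `[death, birth]`.
This sign-free convention is why tip ages are snapped to exactly 0 after
the ultrametricity check: downstream filters use strict inequalities, and
a tip age of `1e-12` would otherwise make "extant" ambiguous.

Given a dated tree, the acceptor window is
`leca = age(MRCA(eukaryote tips))` and
`feca = age(MRCA(eukaryote tips ∪ archaeal sister tips))`; the **branch
space** is every donor-domain (bacterial) branch with `birth > leca` and
`death < feca`. Both inequalities are strict: a branch merely touching a
window endpoint would yield an empty sampling interval below, and on a
continuous-time tree the excluded set has measure zero. The acceptor
lineage itself can never enter the space because it is not bacterial; no
additional ancestor masking is needed.

For each simulated ghost on a sister branch `[death, birth]`:

* ghost birth `g ~ U(max(death, leca), birth]`,
* transfer age `τ ~ U(leca, min(g, feca))`.

This single rule is the unique uniform-sampling rule consistent with the
natural case analysis — a branch spanning the whole window gives
`g ~ U(leca, birth]`; a branch that died inside the window gives
`g ~ U(death, birth]`; a branch born inside the window gives
`g ~ U(leca, birth]`; and whenever `g` lands older than FECA the transfer
is drawn over the full window `U(leca, feca)`. It also covers the corner
case of a branch born after FECA *and* dead before LECA consistently. Note
that `g` may legitimately exceed `feca` (a ghost born before FECA): that
is precisely the mechanism that produces observed ages older than FECA.
The ghost's death time plays no role in the shift assessment (the model is
agnostic to whether the lineage is extinct or merely unsampled), so it is
never drawn.

Where the procedure says "randomly", we use uniform distributions — the
maximum-entropy default in the absence of further information — and the
**branch** is the sampling unit: sister branches are chosen uniformly over
the space, not weighted by duration, and with replacement (the same branch
may host both ghosts of a pair; such same-clade pairs populate the
diagonal of the clade-pair matrix).

### Classification

A pair of transfers is ordered twice: by true transfer age `τ` and by
observed age (`g` for a ghost donor, `τ` for a sampled donor). The pair is
a **shift** when the two orderings are strictly reversed; ties — a
probability-zero event under continuous uniforms, but possible after
pathological rounding — conservatively count as "no shift". For shifted
pairs, `outside_window` flags whether **any** member's observed age
exceeds `feca`: empirical studies discard gene trees whose inferred
transfer predates FECA as self-evidently artifactual, and discarding acts
on the whole pair. The per-round identity

```
confounding = shift × (1 − P(outside | shift))
```

holds by construction, and rounds with zero shifts contribute no value to
the `outside` proportion (it is undefined there) rather than a zero.

## An analytic reference point

For a single sister branch born exactly at FECA and spanning the window
(the *symmetric fixture*), rescale so the window is `(0, 1]`. Then
`g1, g2` are iid `U(0, 1]`, and `τi | gi ~ U(0, gi)`. Conditional on
`g1 > g2`, a shift requires `τ2 > τ1`, which has probability
`g2 / (2 g1)`; hence

```
P(shift) = E[ min(g1, g2) / (2 max(g1, g2)) ]
         = (1/2) · E[min/max]            with E[min/max] = 1/2
         = 1/4 .
```

The test suite re-derives this number with the independent brute-force
oracle before using it as a constant, and checks the main simulator
against it:

```{r closed-form}
space <- make_fixture_space(fixture_spec(
  feca = 2.42, leca = 1.89,
  branches = data.frame(birth = 2.42, death = 0, label = "S")))
run_round(space, n_pairs = 2e4, seed = 1)$shift_proportion
```

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `n_rounds`, `n_pairs` | counts | 1000 × 1000 | Reference experiment size: per-round proportions have SE ≈ 1.3% at p ≈ 0.2, and 1000 rounds give stable across-round quantiles. |
| `seed` | integer | none (mandatory) | No silent nondeterminism: every public entry point either takes a seed or documents that it consumes the session RNG. |
| `ultrametric_tol` | relative | `1e-6` | Tip-age deviation tolerated relative to root age; empirical dated trees carry rounding noise well below this. |
| `p_grid` | proportion | `0, 0.1, …, 1` | Bernoulli probability that a donor is a ghost; `p = 0` is an exact null (observed = true ordering), `p = 1` the worst case assumed by the main experiment. |

Reproducibility contract: round `r` of an experiment draws from an RNG
substream seeded deterministically from `(master seed, r)` (a fixed
integer hash kept below 2^31), so per-round results are independent of
execution order; the sweep reuses one set of ghost draws and one set of
per-member uniform thresholds across the whole `p_grid` (common random
numbers), which makes the curve smooth in `p` for a given seed and pins
`p = 0` at exactly zero shifts.

## The synthetic study tree

`simulate_study_tree()` emulates the study conditions the framework is
designed for, with no downloads: a bacteria-dominated dated tree of life
(default 100 bacterial, 12 archaeal, 20 eukaryotic tips) with the
eukaryote stem attached at FECA = 2.42 Ga, the eukaryote crown at
LECA = 1.89 Ga, a 3.8 Ga root, and a small organellar clade nested inside
Bacteria so that pruning is exercised. Within-domain subtree shapes come
from constant-rate birth–death simulations (`λ = 1`, `μ = 0.5` per Ga —
moderate turnover, so a realistic fraction of branches crosses the
window) rescaled to their target crown ages; bacterial "phyla" are
delimited by slicing the bacterial subtree at 2.8 Ga, each lineage
crossing that age founding one labelled clade. The window ages and root
age follow published molecular-clock estimates for these nodes; the tip
counts and rates are this package's own choice of a defensible desk-scale
configuration and were fixed once when the generator was written.

What the generator does **not** emulate: posterior uncertainty in node
dates (point ages only), lineage-specific diversification rates,
fossilised or sampled-ancestor processes, and the taxon sampling structure
of any particular empirical tree. Passing tests on synthetic trees
therefore validate the *simulation machinery and its statistics*, not any
biological claim about a specific dated tree of life; empirical trees are
supplied by the user through the same interfaces.

Extinct lineages are pruned from generated trees (only extant tips are
emitted) because the ghost model adds unsampled lineages analytically; a
ghost is never a tip.

## Validation strategy and numerical choices

* **Dual route.** Every headline probability is computed twice: by the
  vectorised simulator and by `shift_probability_oracle()`, a deliberately
  independent straight-line re-implementation that samples each
  branch/window case separately. Agreement is required within 3 combined
  Monte Carlo standard errors on randomized two-branch fixtures, the
  symmetric fixture, and all cells of a two-clade matrix.
* **Endpoint convention.** Continuous uniforms make endpoint inclusion a
  measure-zero choice; it is documented as half-open `(low, high]` for
  reproducibility, not correctness.
* **Degenerate inputs.** An empty branch space is a classed error
  (`ghostshift_empty_space`, CLI exit code 3) — simulation is impossible,
  silently returning zero would be wrong. A sister set nested inside the
  eukaryote set (zero-length acceptor) and non-ultrametric input (reported
  with the worst-offending tip) are classed input errors (exit code 2).
* **Pooling.** Pooled statistics are unweighted means across rounds; with
  equal `n_pairs` per round this equals pooling pairs, so the clade-pair
  matrix (which pools pairs) is consistent with the round summaries.
* **Problem sizes.** The default test suite uses 10^4–10^5 pairs per
  check (Monte Carlo 3·SE ≈ 0.4–1.3 percentage points) and the acceptance
  script the full 10^6-pair reference experiment; both complete in seconds
  on one CPU because sampling and classification are vectorised.

## Known limitations

* Point estimates of FECA/LECA only; propagating dating posteriors would
  require integrating over trees and is out of scope.
* Polytomies are accepted as-is but never resolved; zero-length branches
  are rejected at parse time rather than special-cased.
* Only branches passing the strict-overlap filter are eligible; branches
  whose interval merely touches the window are excluded by design.
* The framework compares dates directly in the time domain. It does not
  simulate sequences or gene trees, so method-level noise (alignment,
  gene-tree inference, stem-length normalisation) is outside the model:
  the shift proportions here isolate the *topological* effect of ghost
  placement alone.
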