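---
title: "Scoring multi-layered protein feature architectures"
author: "mlfas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multi-layered protein feature architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlfas)
```

## The problem

Orthologous proteins tend to overlap in function, but orthology alone does
not reveal *how much* two proteins have diverged. Feature annotations —
Pfam and SMART domains, transmembrane segments, low-complexity regions,
coiled coils — summarize a protein as a *multi-layered feature
architecture* (MLFA): every annotation source contributes one layer, every
layer holds positioned instances of feature types. Comparing architectures
turns "are these orthologs functionally equivalent?" into a quantitative
question.

Two complications make naive comparisons unreliable. First, annotations
from one source frequently overlap: a repeat region may be covered by
several alternative repeat models that cannot all be true at once, so the
architecture is *redundant*. Second, the common fix — keeping, among
overlapping instances, only the one with the smallest e-value — is made
per protein, before any comparison, and routinely picks *different* repeat
variants in the two proteins, producing a spurious signal of divergence.
mlfas instead resolves redundancy *during* the pairwise comparison,
choosing the non-redundant readings of both architectures that maximize
their similarity.

## The score

For a reference architecture $S$ and target $O$ the combined score is the
linear blend

$$\mathrm{FAS}(S,O) = \alpha \cdot \mathrm{MS} + (1-\alpha) \cdot \mathrm{PS},
\qquad \alpha = 0.7 \text{ by default},$$

asymmetric by design: it reaches 1 when $S$ is a positional
sub-architecture of $O$, and 0 when no feature type is shared. Raising
$\alpha$ emphasizes feature content; lowering it emphasizes feature order.

**Multiplicity score.** With $N_i^S$, $N_i^O$ the instance counts of
feature type $i$ in the two (resolved) architectures,

$$\mathrm{MS} = \sum_{i=1}^{N^S} \omega_i \cdot
  \min\!\left(\frac{N_i^S N_i^O}{(N_i^S)^2},\, 1\right),$$

so extra copies in the target saturate at 1 while missing copies (or a
missing type, contributing 0) penalize.

**Positional score.** Every instance is reduced to its relative midpoint
$P = \frac{(start+end)/2}{\text{protein length}}$ (exact arithmetic, no
rounding). Each reference instance of type $i$ is matched to the target
instance of the same type with the nearest relative midpoint:

$$\mathrm{PS} = \sum_{i=1}^{N^S} \frac{\omega_i}{N_i^S}
  \sum_{j=1}^{N_i^S}\left(1 - \min_{1 \le l \le N_i^O}
  \left|P^S_{i,j} - P^O_{i,l}\right|\right).$$

Matching is many-to-one: when the reference has more copies than the
target, several reference instances may share the same nearest target
instance. Relative midpoints live in $[0,1]$, so every term — and hence
MS, PS and FAS — is bounded by $[0,1]$.

Types present in the reference but absent from the target contribute 0 to
*both* sums (the empty minimum is assigned distance 1). This keeps
$\mathrm{PS} \le 1$ and makes FAS exactly 0 when no type is shared.

**Weights.** $\omega_i$ sums to 1 over the reference path's type set.
Uniform weighting gives $\omega_i = 1/n$. Abundance-driven weighting uses
$\omega_i \propto 1/(f(o_i)+1)$, with $o_i$ the type's instance count in a
reference proteome and $f$ one of `ln` (default when a count table is
supplied), `linear`, `log10`, `root4`, `root8` — `linear` gives abundant
types the lowest relative weight, `root8` the highest. The textbook form
of this weight carries a numerator $\sum_l(f(o_l)+1)$ that is constant in
$i$ and cancels under normalization; the implementation omits it and the
tests verify the equivalence against the literal formula. Types missing
from the count table are assigned $o_i = 1$, the most conservative
(weight-maximizing) choice, with a warning. Ad-hoc minimum weights
(`minWeights`) floor selected types — useful when common but functionally
decisive features such as transmembrane segments must not be drowned out —
and the remaining mass is redistributed over the unfloored types
proportionally to their unconstrained weights, iterating so no floor is
violated by the rescaling.

## Redundancy resolution

Within one layer, two instances are *compatible* when they share at most
`maxOverlap` residues (default 0: any shared residue counts; coordinates
are 1-based and inclusive, so instances meeting end-to-start share
nothing). An alternative reading of a layer is formalized as a **maximal
set of pairwise-compatible instances**: maximality prevents degenerate
readings that drop instances no conflict forces out, and reproduces the
intuitive notion that a reading keeps everything it can. These maximal
sets — the layer's *paths* — are enumerated with a deterministic
Bron–Kerbosch-style recursion (`enumerateLayerPaths()`); cross-layer
overlaps never create conflicts. A *resolved architecture* selects one
path per layer; the number of resolved pairs for a protein pair is the
product of all per-layer path counts (`countPathCombinations()`).

### Exhaustive search

`exhaustiveSearch()` scores **every combination of assembled resolved
architectures** and keeps the best pair. A subtle point drove this design:
because weights are normalized over the reference path's *entire* type
set, the choice of path in one layer changes the weight of every type in
every other layer. Optimizing each layer separately and recombining is
therefore not guaranteed to attain the global optimum; only the full cross
product is. The number of evaluations equals `countPathCombinations()`, which the
automatic mode caps (below), so the cross product stays small whenever it
is used. Ties are broken by the lexicographically first combination, which
makes results bit-identical across runs.

Because the e-value resolution also produces one maximal path per layer,
its score is one of the evaluated combinations — the exhaustive score can
never fall below the e-value baseline.

### Priority heuristic

The number of path combinations grows exponentially with the number of
redundant regions, so highly repetitive proteins need a shortcut.
`prioritySearch()` builds a small candidate set per protein:

* the **greedy** realization — instances are admitted left to right; at
  each junction between mutually exclusive instances the one with the
  largest weighted partial contribution against the other protein's full
  instance set wins (contribution of an instance of type $t$:
  $\frac{\omega_t}{N_t}\left[\alpha\min(N_t^O/N_t,1) +
  (1-\alpha)(1-\min_l|\Delta P|)\right]$, with weights over the full
  unresolved type set — the exact bookkeeping at a junction is a genuinely
  open design choice, and this one was picked because it is deterministic,
  cheap, and preserves the bracket below);
* one **priority** realization per feature type with at least two
  instances, in which that type wins every junction where it is present.

All candidate pairs are scored and the maximum returned. The candidate
count is $1 + \#\text{multi-instance types}$ per protein, so the cost is
linear in the amount of redundancy. By construction the bracket
$\text{greedy} \le \text{priority} \le \text{exhaustive}$ always holds;
the heuristic is *not* guaranteed to beat the e-value baseline, though in
the seeded test suite it does in the overwhelming majority of draws.

`compareArchitectures()` selects the mode automatically: exhaustive while
`countPathCombinations()` stays at or below `priorityThreshold` (default
500), priority beyond.

### Baselines

`scoreByEvalue()` reproduces the conventional pre-resolution: per layer,
repeatedly keep the instance with the smallest e-value and discard its
conflicts (instances without e-values rank last; ties break on start then
type). `scoreUnresolved()` skips resolution entirely and scores the
complete overlapping instance sets. Both directions of bias exist for the
unresolved baseline: redundant annotations that *agree* with the target
buffer a genuinely missing feature (overestimate), redundant annotations
that *disagree* dilute the shared types (underestimate). The package's
test suite constructs both cases explicitly.

## Parameters at a glance

| parameter | default | unit / range | meaning |
|---|---|---|---|
| `alpha` | 0.7 | $[0,1]$ | weight of MS vs PS |
| `maxOverlap` | 0 | residues | tolerated same-layer overlap |
| `weighting` | `auto` | scheme | uniform without counts, `ln` with |
| `minWeights` | none | $(0,1]$, sum $<1$ | per-type weight floors |
| `priorityThreshold` | 500 | path combinations | exhaustive/priority switch |
| `mergePfamSmart` | `TRUE` | — | one `pfam_smart` layer on input |

Pfam and SMART are merged by default because both are pHMM-based and their
models frequently annotate the same footprint; merging lets the overlap
resolution arbitrate between them. Type identities are kept verbatim —
merging changes only the layer assignment.

## The synthetic generator

`randomArchitecture()` draws seeded architectures (instances placed
uniformly, widths 5 up to a third of the protein, e-values only in the
pHMM-like first layer, log-uniform down to $10^{-30}$).
`perturbArchitecture()` emulates the changes observed between diverging
orthologs — type loss, instance duplication, positional drift, redundant
decoy annotation — each controlled by one probability and applied under a
fixed seed. `figure1Fixture()` is a deterministic redundant-repeat pair on
which the three strategies order as
$\text{unresolved} < \text{e-value} < \text{exhaustive}$
(0.4273 / 0.7479 / 0.9971 at defaults), the situation the score-maximizing
resolution exists for.

What the generator does **not** emulate: domain grammars (real
architectures are not uniform), correlated annotation errors across
sources, length evolution, or the heavy-tailed redundancy of extreme
repeat proteins. Passing tests on synthetic data therefore demonstrate
algorithmic correctness — attainment of the brute-force maximum, the
dominance chain, score bounds, monotone response to divergence — not
biological calibration of score thresholds.

Test problem sizes were chosen to keep the brute-force oracles exact and
the suite quick: the seeded suite holds 500 pairs (two layers, three types
and four instances per layer on 120-residue proteins, perturbed with
`pLoss = 0.2`, `pDup = 0.2`, `shiftSd = 0.03`, `pRedundant = 0.4`), each
capped at 2000 path combinations; layer-level enumeration is checked
against all $2^n$ subsets for up to 12 instances.

## Numerical choices and degenerate inputs

* Midpoints use exact (possibly half-integer) arithmetic before division.
* All orderings are deterministic: instances sort by (layer, start, end,
  type); path enumeration and tie-breaking are lexicographic; reruns are
  byte-identical.
* An **empty reference** scores 0 with the flag `"empty-reference"`
  instead of raising — pipelines must survive unannotated proteins. An
  empty target simply yields 0 through the absent-type rule.
* Score equalities are compared at $10^{-12}$–$10^{-9}$; a candidate must
  beat the incumbent by more than $10^{-12}$ to replace it, which keeps
  tie-breaking stable under floating-point noise.
* TSV output prints scores with 4 decimals — enough to distinguish
  reported score granularity while keeping diffs stable.

## Limitations

* The information in a FAS score depends on architecture complexity: in a
  type-rich architecture the loss of one feature moves the score little.
  Minimum weights can compensate case by case; a global calibration of
  per-protein significance cut-offs is out of scope.
* The priority heuristic can underestimate the optimum (it searches a
  candidate subset); the exhaustive mode is exact but exponential, which
  is why the mode switch exists.
* Scores compare annotations, not sequences: systematic annotation
  differences between proteomes (tool versions, isoform choice) propagate
  into the scores. The outlier rule (`flagOutliers()`: more than two
  sample SDs below the group mean) is a screening device, not a
  significance test.

## A worked example

```{r example}
fx <- figure1Fixture()
countPathCombinations(fx$ref, fx$tgt)
fasValue(scoreUnresolved(fx$ref, fx$tgt))
fasValue(scoreByEvalue(fx$ref, fx$tgt))
out <- exhaustiveSearch(fx$ref, fx$tgt)
out
featureTable(resolvedReference(scoreResult(out)))
```
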