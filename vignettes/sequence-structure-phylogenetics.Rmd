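---
title: "Joint sequence-structure phylogenetics: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint sequence-structure phylogenetics: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssphylo)
```

## Why sequence + structure

ITS2 and similar structured RNA markers evolve fast at the sequence level
while conserving a secondary-structure core. Treating the two jointly —
rather than aligning nucleotides alone — keeps distant taxa alignable and
adds a second, slower-evolving character layer. `ssphylo` implements this
idea end to end: a 12-letter joint alphabet, structure-aware alignment, a
12-state substitution model with ML distances, and (Profile)
Neighbor-Joining with bootstrap support.

This vignette is the package's own account of the methods: the exact
conventions, the tunable parameters with their defaults and rationale, the
numerical choices, and the limits of what the bundled simulator can
establish.

## The 12-state alphabet

Every position of a record (sequence + same-length dot-bracket structure)
maps to `state = 3*nt + context`, nucleotides ordered (A, C, G, U) and
contexts ordered (unpaired `.`, opening `(`, closing `)`); `STATE_LABELS`
lists the canonical order. Every matrix in the package — scoring,
exchangeabilities, rates, counts — uses this one order; fixing it globally
is deliberate, as silent transposition between differently-ordered matrices
is the classic failure mode of joint-alphabet code.

Input conventions: `T` is folded to `U` on input (ITS2 is a transcript; one
internal alphabet) and `U` is written on output; case is folded. IUPAC
ambiguity codes are masked as missing by default (`ambiguity_policy()`),
i.e. the site is ignored in counts and distances but the taxon is kept;
`drop_record` mode rejects the record instead. Masking is the default
because distance methods tolerate per-site missingness well, while dropping
whole taxa discards information. Non-IUPAC characters are always an error.
Pseudoknots are not representable (one bracket level, properly nested);
records with partial or unbalanced structures are rejected with a
diagnostic naming the record, since a half-annotated structure cannot be
encoded consistently.

## Scoring and alignment

The aligner is a standard three-state Gotoh global alignment with affine
gaps: a gap run of length $k$ costs `gap_open + (k-1) * gap_extend`
(defaults $-8$/$-2$), terminal gaps are charged like internal ones, and
ties are broken deterministically (diagonal, then gap in the second input,
then gap in the first), making every alignment bit-reproducible.

The default 12x12 matrix is a weighted composite
$w_{seq} S_{nt}(a,b) + w_{str} S_{st}(x,y)$ with $S_{nt}$ +2/-1 and
$S_{st}$ +2 on identical context, $-2$ between unpaired and paired, $-1$
between `(` and `)`. The published ITS2-specific matrix used by the
classical tool chain is not publicly tabulated, so this composite is an
explicit, fully specified substitute; user matrices are first-class via
`read_scoring_matrix()`, and `estimate_logodds_matrix()` derives half-bit
log-odds scores from reference alignments. In the log-odds estimator the
pseudocount is mixed in as uniform prior mass on the *frequency* scale,
$p = (f + c/144)/(1+c)$: this keeps the estimate invariant under
duplicating the reference set (a property a count-scale pseudocount would
violate) while preserving the expected asymptotics (scores shrink to zero
for random references and for $c \to \infty$).

Multiple alignment is progressive: pairwise p-distances (mismatch fraction
over non-gap aligned states) feed an NJ guide tree, rooted at the first
input taxon for determinism, and profiles are merged post-order with
"once a gap, always a gap". Profile-profile column scores are the
arithmetic mean of all residue-pair scores between two columns, gaps
contributing zero. These are declared substitutes for the classical tool's
unpublished internals: cheap, deterministic, and testable. The invariant
that de-gapping any output row recovers its input exactly is asserted on
every run. No iterative refinement or structure re-folding is attempted.

## The 12-state GTR model

`gtr_model(pi, R)` builds $Q_{ij} = R_{ij}\pi_j$ with rows summing to zero,
scaled so the expected rate at stationarity is 1 — so branch lengths and
distances are expected substitutions per site. Reversibility
($\pi_i Q_{ij} = \pi_j Q_{ji}$) holds by construction, and $P(t) = e^{Qt}$
is computed through the symmetric eigendecomposition of
$D^{1/2} Q D^{-1/2}$, cached on the model object; entries are clipped into
$[0,1]$ against $\sim 10^{-12}$ eigen-noise. Rate heterogeneity across
sites (Gamma, invariant sites) is deliberately out of scope.

ML pairwise distances maximize
$\ell(t) = \sum_{xy} F_{xy}\log(\pi_x P_{xy}(t))$ over $t \in [0, 20]$ by
Brent optimization (tolerance $10^{-9}$, tighter than the $10^{-8}$
contract). Counts $F$ use pairwise deletion — a column counts iff both rows
carry a real state — which keeps more sites than complete-column deletion
and is the standard choice for distance methods. All-diagonal counts short
circuit to $t = 0$. A solution pinned within $10^{-5}$ of the bound
(with a likelihood at the bound that is no worse) is reported as saturated
with $t = t_{max} = 20$; the $10^{-5}$ snap distance is far above the
optimizer tolerance and far below any biologically meaningful distance to
20. Under the uniform model the estimate matches the 12-state analogue of
the Jukes-Cantor closed form $d = -\tfrac{11}{12}\ln(1 - \tfrac{12}{11}p)$
to $10^{-4}$ (tested on a grid).

`estimate_gtr()` is a counting estimator, not a joint ML fit over a tree:
divergence counts pooled over all row pairs with p-distance below 0.75
(above that, pairs are effectively saturated and only add noise),
symmetrized; $\pi$ from marginal frequencies plus pseudocount;
$R_{xy} = (F_{xy} + F_{yx} + 2c)/(2\pi_x\pi_y)$. It is order-invariant and
degenerates gracefully (identical rows give a pseudocount-uniform $R$ with
a warning). The bundled fallback model is the 12-state Jukes-Cantor
analogue — uniform $\pi$, uniform $R$ — because the numeric parameters of
the classical ITS2 model file are not recoverable from the literature;
fitted or file-supplied models are the intended route
(`read_gtr_model()`/`write_gtr_model()`).

## NJ, bootstrap, profiles

`neighbor_joining()` is the Saitou-Nei agglomeration with
$Q(i,j) = (n-2)D_{ij} - \sum_k D_{ik} - \sum_k D_{jk}$ and the standard
two-point branch lengths. Two contracts matter for reproducibility:

* **Ties** are broken by the lexicographically smallest (sorted) pair of
  cluster labels, a cluster being labelled by its smallest member leaf.
  Complete ties (all-equal matrices) thus give a fixed, valid binary tree.
* **Negative branch lengths** are clamped to zero at output with the
  deficit left unredistributed — the simplest documented policy; it affects
  only near-tie datasets and never the consistency guarantee on additive
  inputs (recovery of topology and branch lengths to $10^{-9}$, verified
  against independently computed path lengths and `ape::nj`).

Bootstrap support resamples alignment columns with replacement (seeded,
deterministic stream; a replicate in which some pair shares no usable
column is redrawn, at most $10B$ times), rebuilds distances and the NJ tree,
and reports per-bipartition percentages of the original tree; defaults to
$B = 100$ replicates, the conventional choice for this marker. Splits are
canonicalized as the side not containing the alphabetically smallest leaf.
Support values are serialized as integer internal-node labels — the
FigTree-compatible Newick dialect.

Profile Neighbor-Joining collapses well-supported clades into column
frequency profiles (12 state fractions + gap fraction per column; missing
counts as gap) and iterates. Inter-profile distances use expected counts
$F_{xy} = \sum_c f_{p,x}(c) f_{q,y}(c)$ over columns where both gap
fractions are ≤ 0.5, then the same ML machinery (non-integer counts);
for singleton profiles this reduces *exactly* to the sequence distance, so
PNJ with an unreachable threshold is byte-identical to NJ. The support
threshold defaults to 70% — the conventional "well-supported" level for
bootstrap values on this marker; the classical tool's internal default is
not published. Per iteration, the bootstrap operates on the *reduced*
frequency alignment (profiles as entities), the maximal supported canonical
sides (a laminar family, hence disjoint) are frozen, and the loop stops
when nothing merges, fewer than four entities remain, or `max_iter` is hit.
The final tree re-expands each profile by splicing the NJ subtree of its
members (member-only distances from the original alignment,
midpoint-rooted — a deterministic, balanced attachment choice) onto the
profile's stem. Whether a presentation should re-expand or keep profiles
collapsed is a matter of taste; re-expansion was chosen so the output tree
always carries the full taxon set.

Outgroup rooting places the root at the midpoint of the edge separating a
monophyletic outgroup; a non-monophyletic outgroup triggers a warning and a
documented fallback (rooting on the first outgroup taxon's terminal edge)
rather than an error, since real outgroup sets frequently fail strict
monophyly.

## The simulator: what a green test establishes

`sample_tree()` draws topologies by sequential uniform joins with i.i.d.
exponential branch lengths (default mean 0.1 substitutions/site — moderate
ITS2-like divergence); `evolve_seqstruct()` evolves sites independently
down the tree under the model. Defaults mirror the marker: when no length
is given it is drawn from 128-483 nt, the observed ITS2 range across the
green algae. Two modes separate concerns:

* **free** — all 12 states accessible everywhere; decoded structures may be
  unbalanced. This mode exists to exercise the model mathematics
  (stationarity, parameter recovery, distance consistency) where structural
  validity is irrelevant.
* **structure_locked** — a balanced template fixes each column's context and
  substitution is restricted to the four nucleotides sharing it, via the
  restricted, re-diagonalized rate matrix. Outputs are always valid Vienna
  records; this is the mode behind every file-format and pipeline test.

There is **no indel process** — so the true alignment is known exactly, and
alignment correctness is tested separately on low-divergence data where the
gap-free alignment is provably optimal. Consequently a green alignment test
establishes column-level correctness under substitution-only evolution, not
indel placement quality. The simulator also does not model compensatory
base changes (paired sites evolve independently given their context),
rate heterogeneity, or pseudogene decay; conclusions about those phenomena
are outside what the test suite can support.

## Numerical and degenerate-input choices

* Optimizer: Brent on $[0, 20]$, tol $10^{-9}$; saturation snap $10^{-5}$.
* $P(t)$ entries clipped to $[0,1]$; row-sum deviation bounded by
  $10^{-10}$ in tests.
* Scoring matrices must be symmetric to $10^{-9}$; gap penalties must
  satisfy `gap_open <= gap_extend < 0`.
* Zero-length branches, empty pair tables, empty records, all-identical
  alignments, complete distance ties: all defined and tested rather than
  rejected.
* Newick branch lengths are printed with 12 significant digits via one
  shared formatter, which is what makes "byte-identical" guarantees (PNJ
  degeneracy, pipeline reproducibility) meaningful.
* All stochastic stages take explicit integer seeds and restore the
  caller's RNG state; the pipeline derives per-stage streams from one
  global seed.

## Limitations

* The scoring matrix, progressive strategy, automatic-profiling schedule
  and inter-profile distance are documented substitutes for unpublished
  internals of the classical ITS2 tool chain; results will differ in
  detail from that software even on identical input.
* The GTR estimator is a moment/counting method; for very deep or very
  sparse data a joint ML fit would be preferable.
* No rate heterogeneity, no indel model, no pseudoknots, no ML tree search
  — the treeing method is distance-based by design.
* Bootstrap and PNJ assume columns are exchangeable units; structured
  dependence between paired columns is ignored by the resampler.
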