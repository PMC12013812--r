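---
title: "Annealed molecular graph editing: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annealed molecular graph editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molanneal)
```

## The problem

Target-aware molecular generation asks for novel molecules that score
well on a *vector* of objectives — predicted binding affinity to a
receptor pocket, drug-likeness, synthetic accessibility — while staying
chemically valid and recognizably derived from a chosen starting
fragment. `molanneal` treats this as discrete stochastic optimization
over the space of heavy-atom molecular graphs: a single-walker simulated
annealing (SA) chain proposes one local graph edit per step and accepts
or rejects it by a Metropolis rule at a decreasing temperature.

## The objective and its gate

For a candidate $x^*$ and the original starting fragment $x_0$ the
score is

$$f_p(x^*) = \alpha\, f_{\text{Dock}}(x^*) + \beta\, f_{\text{syn}}(x^*)
  + \gamma\, f_{\text{QED}}(x^*),$$

gated by a validity indicator: $x^*$ counts only if it satisfies the
valence table *and* its Morgan-fingerprint Tanimoto similarity to $x_0$
strictly exceeds $\delta$. Gated-out candidates score $-\infty$, which
makes their Metropolis acceptance probability exactly zero — an invalid
molecule can never become the incumbent, and the gate always compares to
the *original* $x_0$, not the current incumbent, so a chain cannot walk
gradually away from its fragment.

Tunable parameters, defaults, and rationale:

* `alpha = 1.0`, `beta = 0.2`, `gamma = 0.2` (unitless weights). The
  affinity term is deliberately weighted most heavily; exact values are
  configuration knobs.
* `delta = 0.4` (Tanimoto units, in $[0,1]$): permits substantial
  elaboration of a small fragment while preserving its core. Raising it
  tightens fidelity to the start at the cost of exploration.
* Fingerprints: circular (Morgan-type), radius 2, 2048 bits — the
  de-facto standard parameters.
* Docking orientation: internally "larger is better", so scorers that
  report energies (lower = better, kcal/mol) are negated inside the
  objective while logs keep the native sign.

Because no cheminformatics toolkit exists in this R stack, the
drug-likeness and synthetic-accessibility terms are lightweight,
descriptor-based analogues of the usual fitted scores: `qed_score()` is
a geometric mean of Gaussian desirability functions (molecular weight,
H-bond donors/acceptors, ring count, rotatable bonds) in $[0,1]$, and
`sa_heuristic()` maps size, ring complexity, heteroatom load and triple
bonds to the familiar 1 (easy) – 10 (hard) scale, normalized by
`syn_score()` so that higher = easier. They honor the contracts
(bounded, sane orientation) but are *not* numerically interchangeable
with the fragment-contribution models in RDKit.

## The editing calculus

One edit per step, drawn from the four-operator set
$A = \{\text{insertion}, \text{replacement}, \text{deletion},
\text{cyclization}\}$ over the vocabulary
{C, N, O, F, P, S, Cl, Br} with standard neutral valences. Hydrogens are
implicit everywhere: operators touch heavy atoms only and free valence
is refilled automatically.

* **insertion** appends one atom bonded (order 1–3) to the edited
  position;
* **replacement** swaps the element at the position, keeping all bonds;
* **deletion** removes the atom and its bonds; if the molecule falls
  apart, one valence-valid component is sampled uniformly (components
  below 2 atoms are discarded when the parent had ≥ 3, preventing
  collapse to single atoms);
* **cyclization** adds one bond between two unbonded atoms whose new
  ring size (graph distance + 1) lies in a 3–8 window — "nearby in the
  graph" is our reading of ring closure between adjacent regions, and
  3–8 covers the common ring sizes.

Aromatic bonds are never created directly: edits operate on the
kekulized graph, and six-membered C/N rings with alternating bond
orders are re-perceived as aromatic at serialization and fingerprint
time. This keeps valence arithmetic local and makes both kekulé forms
of a benzene ring canonicalize identically. Five-membered
heteroaromatics and fused polycyclics are handled in kekulized form —
their common kekulé forms are related by graph automorphisms, so
canonicalization remains consistent, but they are written without
lowercase aromatic notation.

The operator set is *complete*: the test suite verifies by exhaustive
breadth-first closure that single edits starting from methane reach
every valence-valid connected molecule over {C, N, O} with up to four
heavy atoms (571 molecules, generated independently by brute force),
and `edit_path_exists()` constructs explicit edit paths between
arbitrary pairs — delete down to a maximum common substructure, then
grow with insertions and cyclizations, with a replacements-only shortcut
when the two molecules share their bond skeleton.

## Position prediction from editing history

Rather than editing uniformly random atoms, the annealer can learn
*where* edits tend to succeed. During random-position runs, every
accepted edit increments an editing-frequency counter at the edited atom
and each of its graph neighbors; counters are carried across edits by
exact index bookkeeping (inserted atoms start at zero, deleted atoms'
entries are dropped). The conservation law — total counts equal the sum
of (degree + 1) over edited positions — is tested as an exact integer
identity.

The predictor itself is a message-passing node regressor: three rounds
of GIN-style sum aggregation $h^{(l+1)} = h^{(l)} + A_w h^{(l)}$ (edge
weights = bond orders, aromatic 1.5) over base atom features (element
one-hot, degree, implicit H, ring flag, bond-order sum, aromatic flag),
with the concatenated layer outputs feeding a ridge (default) or
Poisson readout. This is a deliberate substitution: the environment has
no deep-learning stack, and a linearized GIN keeps the two properties
that matter for the contract — permutation equivariance (tested) and
deterministic, reproducible training — while recovering planted signals
easily (a model trained on ring-only editing histories places ring atoms
in its top-K on held-out molecules). Training is offline: harvest, fit,
freeze; refreshing the model during a campaign is a noted alternative we
did not take.

At generation time the top-`K` atoms by predicted frequency (ties broken
by ascending atom index, for determinism) form the candidate set, and
the editing position is sampled uniformly from it (softmax weighting is
available as a config option). `K = n` with uniform sampling *is* the
random-position ablation, exactly.

## The annealing loop and reversible sampling

Temperature follows $T(t) = \max(T_{\min}, T_{\text{init}}/(t+1))$ with
defaults $T_{\text{init}} = 1$, $T_{\min} = 0.05$, and the acceptance
probability is $\min(1, e^{(f(x^*) - f(x_t))/T})$ — equal scores are
accepted (probability 1 at $\Delta = 0$).

On rejection, the *reversible sampling* strategy grants the candidate a
second chance: one secondary edit of $x^*$ is drawn and scored, and iff
it beats the incumbent **strictly**, the original $x^*$ (not the
secondary molecule) is accepted after all. The two boundary rules are
implemented literally: the primary rule accepts at $\Delta = 0$, the
reversible rule rejects at equality. A gated ($-\infty$) primary
candidate is never rescued — resurrecting an invalid molecule would
violate the gate invariant. The secondary molecule is discarded after
the comparison; caching it for the next step is a noted alternative.

Each run owns named random substreams (position, payload, Metropolis,
reversible) derived from one seed, so ablation variants are
variance-paired: disabling a component does not shift any other
component's draws, and identical seed + config reproduce a trajectory
bit for bit (hash-compared in the tests).

## What the synthetic world does and does not establish

The offline stand-in for docking is `surrogate_dock()`: a deterministic
pharmacophore-count profile score
$-\sum_f w_f\,|\text{count}_f(x) - \text{target}_f|$ over heavy-atom
count, ring count, H-bond donors and acceptors. It is invariant under
atom relabeling, maximized at 0 on exact profile match, and piecewise
linear with steps set by the weights. The benchmark world used by the
acceptance tests starts from n-hexane and targets a two-ring profile
(10 heavy atoms, 2 rings, 0 donors, 1 acceptor; ring weight 2) — a
plausible "grow a small decorated bicycle from a chain" task chosen
once, before any acceptance measurement.

A green SA test in this world establishes that the machinery optimizes:
seeded chains improve the objective from the start fragment, best-so-far
is monotone, the gate is never violated, and runs are reproducible. It
does **not** establish docking realism: the surrogate is smooth at the
scale of single edits, with none of the "activity cliffs" of real
docking landscapes. That matters for one acceptance outcome we report
honestly: in the ablation comparison the position predictor reproduces
its advantage (full ≥ random-position), but reversible sampling is
neutral-to-slightly-harmful here — medians for the
reversible-only-disabled and position-only-disabled variants straddle
the no-component baseline within noise, and random-positions+reversible
trails it. The rescue mechanism is designed to jump cliffs; a cliff-free
landscape gives it nothing to exploit while its re-accepted suboptimal
candidates add downhill diffusion at low temperature. We did not retune
the benchmark after observing this; the corresponding acceptance checks
are left failing with this analysis as the explanation.

## Numerical and interface choices

* Canonical serialization: Morgan-style invariant refinement to a
  discrete atom ranking, branching over residual symmetry ties and
  taking the lexicographically smallest SMILES. On a 110-molecule
  edited corpus the induced equivalence classes match RDKit's
  canonicalization exactly (RDKit is used only as a test oracle, via
  the pre-installed Python).
* Implicit hydrogens: smallest allowed valence state that accommodates
  the bond-order sum (so S(VI) gets 0 H); formulas match RDKit on the
  corpus.
* Degenerate inputs: single-atom deletion raises a degenerate-input
  error; a position with no valid edit makes `propose()` raise a
  no-edit error and the annealer re-draws the position; a chain where
  no position admits any edit ends the run marked `stuck`.
* Configuration files are JSON (no YAML parser is available in this
  stack); unknown keys are rejected and a config hash over the
  scientific fields (output routing excluded) is embedded in every
  output file.
* Stereochemistry markers are stripped on parse rather than stored: the
  editing calculus is 2D, and carrying stereo state the operators never
  read would only invite inconsistency. External docking runs through a
  subprocess adapter (`external_dock()`) that validates the box and
  caches by canonical form + receptor hash + box; it requires a docking
  binary and a ligand-preparation hook and is never needed by the
  framework itself.

## Known limitations

* Formal charges are carried but never created; charged input atoms are
  rejected. The vocabulary is the common drug-like organic set.
* Aromatic perception is limited to alternating six-membered C/N rings;
  fused aromatics round-trip consistently but are written kekulized.
* `qed_score()` / `sa_heuristic()` are analogues, not reimplementations,
  of the fitted literature scores.
* The maximum-common-substructure search inside `edit_path_exists()` is
  exhaustive only up to ~10 atoms and greedy beyond, so very long paths
  between large molecules may be missed even when one exists.
* Single-walker SA only; no parallel tempering or population variants.
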