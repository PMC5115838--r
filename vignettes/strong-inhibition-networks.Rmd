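---
title: "Strong-inhibition Boolean networks: models, searches and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strong-inhibition Boolean networks: models, searches and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibnet)
```

## The model

A gene regulatory network on N Boolean genes is a signed adjacency matrix
`a`, `a[i, j] ∈ {−1, 0, +1}`, read as *the effect of source j on target i*
(this orientation is used everywhere in the package, including both file
formats). The general threshold dynamics weight activations by +1,
off-diagonal inhibitions by −γ and a diagonal −1 (self-degradation) by −1;
each gene switches to 1 on a positive input sum, to 0 on a negative sum, and
holds its value at zero sum (`threshold_step()`, with `gamma` a free
parameter ≥ 1).

Many repressive interactions in transcriptional regulation are effectively
decisive, which motivates the dominant-inhibition limit γ → ∞. There the
dynamics collapse to a purely logical update (`strong_inhibition_step()`):
with `g`/`r` the indicator matrices of activating/inhibiting edges
(`regulatory_decomposition()`),

S_i(t+1) = (⋁_{j≠i} S_j g_ij ∨ S_i r̄_ii ∨ S̄_i g_ii) ∧ ⋀_{j≠i} ¬(S_j r_ij).

Only signs matter in this limit, which is why `signed_network` stores signs
and no weights. The two models agree on every state for any network without
self-edges once γ ≥ N (this is exhaustively tested); with self-edges they can
differ, because a self-activated gene that is off with no active regulators
stays off under the threshold rule but switches on under the logical rule's
`S̄_i g_ii` term. The package follows the logical equation verbatim — it *is*
the model being analysed — and asserts the equivalence only for self-edge-free
networks.

Assumptions worth keeping in mind: updates are synchronous and deterministic;
a gene cannot both activate and inhibit the same target; singleton attractors
(fixed points) are the object of study — cyclic attractors are detected by
`trajectory()` when encountered, but not enumerated.

## The fixed-point search

Singleton attractors solve S = F(S). The search manipulates *partial states*
(entries 0, 1 or undetermined, written `?`) and alternates two moves.

**Propagation** (`propagate()`). Seven local rules read off the fixed-point
equations. For an active gene: every gene it inhibits and every gene
inhibiting it must be off (rules 1–2); if it is self-inhibited and all but
one activator are off, the last candidate activator must be on (rule 3). For
an inactive gene with no active inhibitor: all but one activator off forces
the last one off (rule 4). Without reference to the gene's own value: a
self-inhibited gene with no active activator is off (rule 5), a
self-activated gene with no active inhibitor is on (rule 6), and a gene with
an active activator and no active inhibitor is on (rule 7).

Premises use *entailment semantics*: "no active regulator in J" fires only
when every member of J is determined and 0 (vacuously when J is empty), and
existence premises need a determined witness. Rules therefore never guess:
every determination holds in *all* fixed-point completions of the current
partial state (a property the suite checks against brute force). Rules 1 and
2 are applied only across distinct gene pairs: applied to a self-loop they
would wrongly forbid a self-inhibited gene from being active, yet such a gene
may be held on by an external activator, since self-inhibition enters the
equations outside the inhibitor product.

Rules are swept over all genes repeatedly until a full pass determines
nothing (a fixpoint — unique, because all rules are monotone entailments, so
sweep order cannot matter) or a conclusion conflicts with an already
determined value (a *contradiction*, the search's pruning signal, not an
error). `l0`, the number of undetermined genes, never increases and
determined values never flip.

**Branching** (`select_branch_node()`). When propagation stalls, the search
splits on the undetermined gene with the most inhibitory connections —
inhibitory in-degree plus out-degree, a self-loop counted once (it is one
connection, and the count mirrors how hard rules 1–2 can bite once the gene's
value is fixed). Ties go to the lowest index; the heuristic affects traversal
order and speed only, never the result set. Value 1 is explored before 0,
depth-first (an explicit stack keeps memory linear in N; any traversal order
returns the same set, because the two branch values partition the completions
— which also rules out duplicates by construction).

Leaves (fully determined, contradiction-free states) are verified with one
forward step before being reported — a cheap guard against any
rule-transcription error. The algorithm's soundness and completeness
argument runs both ways: every fixed point obeys the rules (so it survives
to a leaf of some branch), and a fully determined state that obeys all rules
satisfies the fixed-point equations; the suite additionally enforces
equality with a 2^N brute-force oracle over hundreds of random networks.

`SearchStats` counters (branchings, propagation passes, contradictions) are
the package's measure of effort; they are hardware-independent, unlike CPU
seconds, which are recorded in ensembles but never asserted.

## Pre-images and basins

Predecessors of a target T solve F(S) = T, node by node. The same
branch-and-propagate skeleton runs with a different rule set
(`propagate_preimage()`): five rules for target bits equal to 1 (all
inhibitors of that gene off; forced last-candidate activators; a
self-inhibited target bit 1 with every activator off is an immediate
contradiction) and five for target bits 0 (with no active inhibitor, every
activator off and — absent self-edges — the gene itself off; a last-candidate
inhibitor forced on when the activation side is already entailed; a
self-activated gene with all inhibitors off an immediate contradiction).
One grouping decision is worth recording: the "last-candidate inhibitor"
rule for a 0-bit reads *r_ij0 = 1 ∧ (no other external inhibitor active) ∧
(self-activation or some determined active activator) ⇒ S_j0 = 1* — the only
parse that is sound, since the activation side must already be entailed
before an inhibitor can be forced. A weaker special case (self-activation
only) is kept as a separate rule for rule-level traceability, though
subsumed.

This rule set is deliberately not propagation-complete (e.g. a determined
active gene with no self-edge also entails the activation side, which no
rule exploits); branching plus leaf verification by one forward
step make the enumeration exact regardless, and the oracle tests enforce it.
A target with no pre-image (Garden-of-Eden state) returns an empty set
cleanly.

`compute_basin()` closes the pre-image relation transitively: layer 0 is the
attractor, layer d+1 the new pre-images of layer d. Because each state has
exactly one successor, a state's layer equals its exact forward hitting time,
and layers partition the basin; the suite checks both against forward
simulation of entire small state spaces.

## Random ensembles

`sample_network()` draws Erdős–Rényi-style signed networks: each ordered
pair (i, j), diagonal included, gets an edge with probability p = ⟨k⟩/N, and
each edge is inhibitory with probability r, activating otherwise. Self-edges
draw from the same sign distribution as other edges — the generator has one
two-point sign law, with no special diagonal casing. Biological regulatory
networks typically show ⟨k⟩ ≈ 2–4 and a minority of inhibitory edges, hence
the conventional operating point ⟨k⟩ = 3, r = 0.4 used in examples and
defaults.

Reproducibility: every sample's RNG stream is derived from
(root seed, sample index) by a Lehmer step, so sample m is identical whether
drawn alone, in order, or after any other sample, and the caller's RNG state
is left untouched. `run_ensemble()` records, per sample, the attractor count
NS, branchings and wall-clock seconds; a per-sample cap on enumerated
attractors (default 10^6) guards against pathological sparse draws (an
edgeless network has 2^N fixed points) — capped samples are flagged and
excluded from the aggregates (avS, MinS, MaxS, avT), never silently dropped.

What the ensembles emulate — and what they do not: homogeneous random
wiring reproduces the characteristic *trends* of the search (average and
maximum attractor counts growing roughly exponentially with N, avS falling
steeply with ⟨k⟩ and rising with r, search effort tracking NS nearly
linearly), but real regulatory networks have broad degree distributions,
motif structure and signed feedback organisation that Erdős–Rényi sampling
lacks; passing ensemble tests says nothing about those features.

## Numerical and design choices

* **Problem sizes.** Brute-force oracles refuse networks above 24 nodes by
  default (the scan is exponential and meant for validation, not
  production). The test suite validates oracle equivalence on a few hundred
  random networks at N = 4–12, model equivalence exhaustively up to N = 10,
  basins exhaustively up to N = 10, and ensemble trends at N = 14 and N = 20
  with M = 200 samples per condition — sizes chosen so the full suite
  completes comfortably on one CPU while leaving every claim tested at the
  scale where its exhaustive ground truth is computable.
* **Canonical output.** Result sets are deduplicated and sorted
  lexicographically as bitstrings (node 1 leftmost), so equal sets compare
  equal; JSON payloads are schema-tagged and deterministic.
* **Degenerate inputs.** One-node networks, empty networks (every state
  fixed; every state its own unique pre-image), fully inhibitory networks
  and contradictory partial assignments are all legal inputs with defined
  results; contradiction is a normal propagation outcome.
* **1-based node indexing** everywhere in APIs and file formats, matching
  the field's tuple notation for states.
* **The cell-cycle fixture** is defined in code (`yeast_cell_cycle_network()`)
  and shipped as a matrix file; the transcription from the published model is
  cross-validated in the suite against its known seven fixed points, the
  known pre-image structure of the G1 state, and the documented inhibitory-
  degree ordering of its nodes.

## Known limitations

* Cyclic attractors are out of scope: `trajectory()` reports a cycle when it
  runs into one, but there is no cycle enumeration.
* The search is worst-case exponential (the underlying decision problems are
  NP-hard); effort scales with the number of solutions, so dense, weakly
  inhibited networks are fast and near-empty networks are the hard case —
  the cap exists precisely for them.
* Only the strong-inhibition update is searched; for finite γ the threshold
  model's fixed points coincide only in the self-edge-free case described
  above.
* Asynchronous and probabilistic schedules, ODE refinements, and SBML-qual /
  BoolNet / GINsim interchange formats are not supported (the plain matrix
  and edge-list readers are deliberately minimal).
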