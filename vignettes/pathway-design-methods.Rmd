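---
title: "Methods: balanced subnetwork extraction and pathway enumeration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balanced subnetwork extraction and pathway enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathweaver)
```

This vignette documents the model behind `pathweaver`, the assumptions it
makes, the parameters that matter, and the numerical and design choices taken
where the problem admits more than one sensible answer.

## The problem

Producing a non-native chemical in a host organism requires more than a
linear sequence of reactions from a native precursor to the target: every
cosubstrate consumed along the way must be producible by the host, and every
byproduct must be consumable, or the pathway cannot carry steady-state flux.
`pathweaver` therefore works in two regimes. A *graph* regime finds candidate
linear routes quickly over a reactant–product-pair (RP-pair) network, and a
*stoichiometric* regime — flux balance analysis (FBA) over the host's
genome-scale model with the candidate reactions added — certifies which
reaction sets actually support production, via mixed-integer enumeration.

The graph regime is deliberately lossy: an RP-pair edge keeps only a scalar
conserved atom ratio (CAR) and a list of attached reactions with their
cosubstrates. No atom mapping is tracked during search; the CAR is the only
atom-conservation signal. The stoichiometric regime restores exactness: mass
balance, flux bounds and (optionally) thermodynamics are enforced on the
integrated model, so no pathway is reported on graph evidence alone.

## Graph construction and search

Compounds are nodes; each retained RP-pair is a directed edge. Edges whose
CAR falls below the `car_threshold` are dropped, as are excluded species
(metal cofactors, listed gases — shipped as an editable table in
`inst/extdata/excluded_species.tsv`) and any user-listed compounds. RP-pairs
whose attached reactions include a reversible one get a reverse edge.

Edge weights are `β^[known] · CAR^(−λ)`:

| parameter | default | meaning |
|---|---|---|
| `lambda` (λ ≥ 0) | 1 | exponent of the inverse-CAR transform; 0 = hop count |
| `beta` (β ∈ (0,1]) | 1 | multiplicative preference for edges with ≥1 known reaction |
| `car_threshold` | 0 | minimum CAR per step |

The literature behind CAR-weighted searches describes an "exponential
transformation" of graph distances without printing the formula; this package
fixes the form above because it is monotone in atom conservation, reduces to
hop counting at λ = 0, and exposes the known-reaction preference as a
separate, orthogonal factor. Whether CAR and known-ness should combine
multiplicatively or additively is genuinely open; the multiplicative form was
chosen and both knobs are user-visible.

k-shortest loopless paths use Yen's algorithm over igraph's Dijkstra. Paths
longer than `max_len` edges are skipped but enumeration continues, so results
are exhaustive up to `k` within the length bound. Equal-weight ties are
broken by length (shorter first), then lexicographically on the edge-id
sequence — arbitrary, but deterministic, which the test suite relies on.

## Precursor selection

Candidates default to the host-mapped metabolites; a user list overrides.
Filtering removes candidates with more carbons than the target (they cannot
be incorporated without carbon loss) and, when a SMARTS pattern is given,
candidates lacking the substructure. Ranking uses the maximum common
substructure (MCS) with the target, computed on heavy atoms as a maximum
clique of the modular product of the two molecular graphs (bond orders must
match; structures parsed from SMILES via ChemmineR/ChemmineOB). MCS is
NP-hard; the clique search is capped, and unresolvable structures fall back
to a common-element-count heuristic with a warning. Carbon filtering commutes
with substructure filtering, so their order is immaterial.

## Boundary metabolites, expansion, convergence

The concept "boundary metabolite" needed an operational rule, which this
package fixes as: a non-host, non-excluded compound that appears as a
substrate of a subnetwork reaction with no subnetwork reaction producing it
(production needed), or as a product with no consumer (consumption needed).
Reversible reactions count as both producer and consumer of all their
participants. The target itself is exempt — its consumption is the demand
reaction added at integration. When a compound needs both directions, each
needed direction must be connected; if either cannot be, the compound is
omitted.

Expansion iterates: collect boundaries, search connection pathways between
the host set and each boundary (length ≤ shortest + `extra_steps`), keep up
to `k_cosub` (default 3) per boundary, preferring connections that introduce
the fewest new non-host cosubstrates, append, recompute. Iteration order is
sorted compound ids, so expansion is reproducible without seeds. The
per-round boundary counts are recorded; the trace is finite and ends at zero
because every compound is either connected or omitted exactly once.

Convergence removes reactions referencing omitted or unconnected compounds
and cascades until a fixed point. Only forced removals occur, so the result
is the maximal closed subset; convergence is idempotent. If the cascade
leaves the target without a producer the run fails explicitly rather than
returning an empty design.

## Integration

Host metabolites map to database compounds if and only if the first block of
their hashed 2D-structure identifier matches; compartments are ignored, and
the cytosolic copy is preferred when several compartmental copies map to one
compound. A full-key mode would be the natural extension for stereochemistry
but is not implemented. Subnetwork reactions enter the cytosol with fresh
`NN_`-prefixed ids; native stoichiometry and bounds are never altered. The
demand reaction has bounds [0, 1000] mmol/gDW/h — production is enforced by
the enumeration-time θ constraint, not by the demand bound, since no default
lower bound is obviously right before Vmax is known.

Excluded species that reach the integrated model without a host counterpart
receive a free exchange reaction (bounds ±1000). Rationale: these species are
deliberately never connected by a pathway, yet a steady-state model would
otherwise assign zero flux to any reaction touching them; a free exchange
encodes the assumption that the cell supplies cofactors such as Mg²⁺
independently of the designed pathway.

## Enumeration

The MILP minimizes `Σ w_j y_j` over binary activity indicators for the
non-native reactions, subject to mass balance, native bounds, big-M-free
coupling `y_j·LB_j ≤ v_j ≤ y_j·UB_j`, and the production requirement
`θ·Vmax ≤ v_product`. One binary controls both directions of a reversible
non-native reaction. After each optimum the integer cut
`Σ_{j∈A}(1−y_j) ≥ 1` is added; because each cut excludes a found set *and all
its supersets*, and smaller feasible sets are always found first, the
enumeration emits exactly the inclusion-minimal feasible supports in
objective order — a property the acceptance tests verify against exhaustive
subset enumeration. Enumeration stops at `K` alternatives (default 100), at
infeasibility, or when the objective exceeds the first optimum by more than
`slack` (default unbounded, i.e. enumerate to K).

Every returned pathway is re-verified by an independent LP with only its
active reactions open. At θ = 0 a small positive production floor
(10⁻³·Vmax) replaces the vacuous bound so that the empty support is returned
only when the host alone already makes the target.

Weight mode uses `w_j = W − s_j` over reaction scores `s_j ∈ [0,1]`;
`W ∈ {1.1, 2}` are the conventional settings (small `W` chases well-scored
enzymes, large `W` chases short pathways). Missing scores get the worst case
`w_j = W`. Yields are reported at a substrate uptake of 10 mmol·gDW⁻¹·h⁻¹:
molar yield `v_product/v_substrate`, carbon yield scaled by the carbon counts
of target and substrate.

## Thermodynamics

Reaction Gibbs energies follow the standard transformed convention with
R = 8.31·10⁻³ kJ/K/mol and T = 298 K. Formation energies are consumed as
input (with estimation errors); when they arrive untransformed, the
pH/ionic-strength adjustment applies the extended Debye–Hückel form
`ΔfG'° = ΔfG° + N_H·RT·ln(10)·pH − 2.91482·(z² − N_H)·√I/(1 + 1.6√I)`
(constants from the standard biothermodynamics literature, since no formula
is fixed by the inputs themselves).

TFA couples each constrained reaction's flux sign to the sign of its ΔrG'
through one binary and two big-M rows, with log-concentration variables
bounded to 11–50 mM (intracellular) or 10 nM–100 mM (extracellular). The
intracellular range is strikingly narrow; it is kept as the working default
because it is the printed convention this package follows, and it is
configurable. Big-M values are computed per reaction from the ΔrG'° range
plus the maximum attainable log-term magnitude, keeping the formulation
tight. The propagated (root-sum-square) estimation error relaxes the
directionality constraint by ±error — uncertain steps are given the benefit
of the doubt; set `dfg_error_policy = "ignore"` for point estimates.
Transport, exchange, demand and any reaction with a missing formation energy
carry no thermodynamic constraint, which is standard TFA practice and
guarantees TFA feasibility ⊆ FBA feasibility. A pre-screen that drops
reactions with hopeless ΔrG'° before assembly exists but is off by default,
since it trades completeness for size.

Energies are kJ/mol internally; kcal/mol inputs convert at 4.184.

## Numerical choices

All flux problems are solved by a dense two-phase primal simplex with Bland's
anti-cycling rule, and the MILPs by depth-first branch and bound over the
binaries (most-fractional branching, zero branch first — fully
deterministic). A dense, pure-R solver is appropriate here because every
problem this package builds is small (tens of variables); the solver is
cross-checked in the test suite against an independent simplex implementation
on random LPs and against exhaustive binary enumeration on random MILPs.
Feasibility tolerance is 10⁻⁹, integrality tolerance 10⁻⁶; the θ constraint
is relaxed by 10⁻⁷ to avoid knife-edge infeasibility at θ = 1.
Stoichiometric coefficients are stored as doubles; the integer and dyadic
coefficients used throughout are exact in binary floating point.

## What the synthetic fixtures emulate

The toy host H1 (6 metabolites, 7 reactions) captures the minimal features a
host contributes: a bounded carbon source (glucose uptake 10 mmol/gDW/h),
precursor supply at two carbon sizes with a recombination reaction, and
byproduct secretion. The scenario databases plant, by construction, one
phenomenon each: alternative routes of different length (F1), carbon loss vs
conservation (F2 — branched carbon yield exactly 1.0 vs linear 0.75),
a condensation target needing two precursor branches (F3), an orphan cofactor
whose removal cascades (F4), and a +95.2 kJ/mol step (the kcal-printed value
22.75 × 4.184) that concentration ranges cannot rescue (F5). The
`random_network()` generator builds compounds as CH₂O-unit chains so every
sampled reaction is balanced by construction, and guarantees a precursor-to-
target route.

What passing tests on these systems shows: the machinery — balance checking,
search, expansion, convergence, integration, MILP enumeration with cuts, TFA
— is correct on problems where the ground truth is enumerable. What it does
not show: behaviour at the scale of real reaction databases (10⁵–10⁶
reactions), where the exhaustive expansions used here would need the
large-scale search heuristics of the underlying graph libraries; nor the
quality of real CAR, score, or formation-energy inputs, which are consumed as
given. Test problem sizes were chosen so the whole suite enumerates its
oracles exactly: random instances use ≤ 12 non-native reactions (2¹²
subsets), search graphs ≤ 10 nodes, and 50–100 replicates per property.

## Known limitations

- No atom-transition tracking inside the search; a high-CAR route can still
  lose the "wrong" atoms, which only the carbon-yield computation exposes.
- The MCS clique search is exact but exponential; very large molecules fall
  back to the element-count heuristic.
- Gene–protein–reaction rules pass through untouched; no knockout or
  growth-coupling design.
- The SBML reader covers the Level 3 + flux-bounds subset this package
  writes, not the full specification.
- One binary per reversible non-native reaction means a pathway may use the
  reaction in either direction; per-direction control would double the
  binary count for little gain at these sizes.
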