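---
title: "The FA-CHKREC Boolean network: model, dynamics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FA-CHKREC Boolean network: model, dynamics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fachkrec)
```

## The model and its assumptions

The package centres on a 25-node Boolean model of the crosstalk between
three processes in a cell that has suffered DNA interstrand crosslinks
(ICLs):

* **Damage and repair.** The ICL node activates the FA/BRCA pathway
  (FAcore → FANCD2I → the SLX4-associated nucleases, NUC1), whose unhooking
  of the lesion generates a resected double-strand break (R-DSB) destined
  for homologous recombination (HRR).  Direct breaks (DSB) are handled by
  KU-53BP1/NHEJ, with PARP-1 and γH2AX shaping pathway choice.  An
  alternative unhooking route (RNF4/PLK1 → NUC2) can collapse stalled forks
  when the canonical pathway is absent.
* **The G2/M checkpoint.** ATM/ATR signal damage to p53 → p21 and to
  WEE1/MYT1, all of which converge on keeping the Cyclin B/CDK1 complex
  (CycB-CDK1) — the commitment point of mitosis — off.
* **Checkpoint recovery (CHKREC).** The WIP1 and PP2A-B55 phosphatases
  silence the damage signal, and the CDK1-AurA → PLK1 → CDC25 kinase cascade
  reactivates CycB-CDK1.

Modelling assumptions, inherited from the logical-modelling tradition:
states are binary (a node is active or not), time is implicit and
synchronous (every node updates simultaneously from the current state), and
there is no stochasticity — the update map is a function, so every
trajectory ends in a cycle (an attractor), and the 2^25 state space
partitions exactly into basins of attraction.  Asynchronous and
probabilistic updating are out of scope.

Two transcription choices in the rule set deserve explicit notice, because
the attractor landscape depends on them:

* The `CDK1-AurA` and `CycB-CDK1` rules are stored fully parenthesized as
  `CycB-CDK1 | CDC25 | (!(p21 & PP2A-B55) & !(WEE1 | MYT1 | ATM | ATR))`
  and `CycB-CDK1 | ((CDC25 & PLK1 & CDK1-AurA) & !p21)` — i.e. standard
  precedence (NOT > AND > OR) applied to the published strings.  Every rule
  in `faChkrecNetwork()` is parenthesized so that no reader ever re-derives
  grouping from typography.
* `FANCD2I` retains its printed self-negation (`FAcore & (ATM | ATR) &
  !FANCD2I`), although it forces an active FANCD2I to oscillate; fidelity
  to the published logic was preferred over smoothing it away.

Note that `CycB-CDK1` is self-sustaining (its own value is a disjunct of
its rule): once the mitotic switch is on, only a knockout turns it off.
This matters for protocol design below.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `clamps` | none | nodes held fixed (0 = null mutant, 1 = constitutive); a clamp overrides the rule at every step |
| `protocolSpec(exposure=)` | `"pulse"` | `"pulse"` sets the damage node(s) to 1 at t = 0 only; `"persistent"` clamps them to 1; `"none"` leaves them free |
| `protocolSpec(damageNodes=)` | `"ICL"` | which lesion carries the exposure |
| `protocolSpec(start=)` | `"canonical"` for pulse/persistent, `"all"` otherwise | `"canonical"` = the single state with every node 0 except the exposed damage nodes (lesion hitting a resting cell); `"all"` = every initial state |
| `maxInputs` (truth tables, edge derivation) | 16 | guard against 2^k context explosion |
| `maxSteps` (`simulateTrajectory`) | 2^n | explicit budget; can never bind for the default |

Units are dimensionless: one step is one synchronous update, activity is
0/1.

**Why the canonical start is the default for exposure protocols.**  Because
CycB-CDK1 is self-sustaining, any initial state with the mitotic switch
already on trivially yields a "division with damage" attractor under a
damage clamp.  The biologically meaningful question — does a *resting* cell
facing damage arrest, adapt, or divide? — is the trajectory from the
all-zero state with the lesion applied, which is also what the model's
published simulation panels show.  The ensemble mode (`start = "all"`)
remains available and is what the wild-type attractor census uses.

A related boundary case: knocking out a damage node and simultaneously
exposing it (e.g. `knockout("ICL")` under persistent ICL) is treated as a
vacuous exposure — the lesion cannot form in that mutant — rather than an
error, so screens over *all* null mutants stay complete.

## The attractor engine

`enumerateAttractors()` compiles each rule to a truth table over its
regulators, bit-packs states (bit *i* = node *i* in model order), builds
the synchronous successor map over all assignments of the free (unclamped)
nodes in C++, and extracts the cycles of that functional graph by iterative
path-walking with per-walk marking: each state is visited O(1) times
amortized, so the full 2^25 sweep runs in well under a minute.  Above 25
free nodes the engine refuses outright — it never silently subsamples.
Initial states that conflict with a clamp are projected onto the clamp, so
under clamping "all initial states" means all assignments of the free
nodes, and basin sizes always sum to the size of that projected space.

Attractor identity is canonical: the cycle is rotated so its smallest
bit-encoded state comes first, and sets are sorted by that code, making
repeated runs byte-identical.  The test suite checks the compiled engine
against a deliberately naive per-state R simulator on random networks
(exhaustively for n ≤ 8, with and without clamps), and checks the basin
partition, cycle validity and determinism properties on top.

## Phenotype decision rule

Classification is an ordered rule (first match wins):

1. **CCP** — every cycle state has all four division promoters ON and every
   other node OFF.  Strictness matters: CCP is the clean-division fate.
2. **CCP_DDA** — CycB-CDK1 ON somewhere *and* a damage node ON somewhere:
   division with unrepaired damage.
3. **CCA** — CycB-CDK1 OFF everywhere while damage and arrest nodes are
   active somewhere.
4. **OTHER** — anything else (e.g. the all-off state).

Testing CCP before CCP_DDA resolves the overlap between the two
progression-type signatures: the damage-carrying variant is only reported
when strict CCP fails.  "Active" in a cyclic attractor means ON in at least
one cycle state, because the arrest attractors show recurrent, not
constant, activation of the repair and checkpoint machinery.  The damage
set is the full {ICL, DSB, R-DSB} (the narrower two-lesion variant that
appears in one summary table is subsumed by it), and the arrest set is
{ATM, ATR, p53, p21, WEE1, MYT1}; "PIKK-CHK" style summaries are read as
the ATM/ATR nodes, since the model folds the CHK kinases into them.  All
sets are arguments, so the classifier applies to variant models.

## Interaction removal

`removeInteraction(net, source, target)` excises the source's literal from
the target's rule: an activating conjunct disappears (the rest of the
conjunction survives), a negated occurrence makes the inhibition term
vanish, and a rule consisting solely of the removed regulator becomes the
constant 0.  The obvious alternative — substituting the source by the
constant 0 — was rejected because it does *not* make activating conjuncts
inert: zero-substituting RNF4 out of the NUC2 rule would kill the whole
alternative-unhooking route (`NUC2` would become constant 0) instead of
removing one arrow from it.  Excision is the unique local operation that
treats both arrow polarities as "delete this arrow from the wiring
diagram", and it is what makes the inferred-interaction ablation below
behave sensibly.

## The inferred-interaction set

Fifteen of the model's interactions had no direct experimental report when
the network was assembled; they are shipped as an editable table
(`novelInteractions()`), not hard-coded truth.  Twelve are named outright
in the accompanying text (RNF4/PLK1 → NUC2; PLK1 and CycB-CDK1 ⊣ HRR and
NHEJ; PLK1 and KU-53BP1 ⊣ ATM and ATR; CycB-CDK1 ⊣ MYT1 and WEE1); the
remaining three — the wild-type guards of the alternative unhooking route
(R-DSB ⊣ NUC2, NUC1 ⊣ NUC2, FAcore ⊣ RNF4) — are described only as circuit
context and are flagged `confidence = "inferred"`.  With this 15-edge set,
`removeInteractions()` followed by exhaustive enumeration drives **every**
one of the 2^25 initial states into the strict CCP fixed point: without the
inferred wiring the network cannot represent damage signalling reaching
the cell-cycle machinery, which is the in-silico argument for including
these edges.  Every listed edge is cross-checked against the
witness-derived signed graph in the test suite.

## Signed-graph derivation

`deriveSignedEdges()` defines an edge u → v *semantically*: it exists iff
some assignment of v's other regulators witnesses the rule output changing
when u flips, and the sign (positive / negative / dual) records which
directions have witnesses.  Literal occurrences with no witness are inert
and reported separately rather than counted.  This choice is deliberate:
the two published interaction totals for this network disagree with each
other (123 vs 122, and neither sign split sums consistently), so the
package treats its own derived, witness-verified counts as the reproducible
ground truth and pins no test to either printed number.

## What the random-network generator emulates

`randomNetwork(n, k, seed)` draws uniform truth tables over k uniformly
chosen regulators per node.  It exists to validate the engine against an
independent oracle, not to model biology: real regulatory networks have
heterogeneous in-degree, canalizing functions and structural correlations
that uniform sampling lacks.  A green engine-vs-oracle test therefore
establishes that the bit-packed dynamics are computed correctly — nothing
more.

## Numerical and degenerate-input choices

* State codes are doubles; exactness holds to 2^53, far above the 2^25
  contract, and the engine guards its 25-free-node limit explicitly.
* `parseRules()` accepts both operator dialects, fixes precedence as
  NOT > AND > OR, reports syntax/duplicate errors with line numbers, and
  (by default) declares referenced-but-untargeted variables as
  identity-rule input nodes; `implicitInputs = FALSE` restores the strict
  closed-world behaviour.  Constants 0/1 are legal expressions so that
  rules degraded by interaction removal stay in-type.
* Serialization is parenthesis-minimal and round-trips truth tables
  exactly; BoolNet output maps the hyphenated canonical names (PARP-1,
  R-DSB, KU-53BP1, CDK1-AurA, CycB-CDK1, PP2A-B55) through the documented
  identifier-safe name map.
* Ties never arise: dynamics are deterministic, and attractor ordering is
  by canonical state code.

## Known limitations

* Synchronous updating only; attractors of the asynchronous model may
  differ (cyclic attractors especially).
* The model abstracts entire pathways into single nodes; CHK1/CHK2, MDM2,
  Claspin, Bora and MAST-L are folded into existing nodes and cannot be
  perturbed individually.
* Chemical inhibitors are represented as clean knockouts: dose, kinetics
  and off-target effects are outside the formalism.
* The 15-edge inferred-interaction list is a reconstruction; three of its
  members rest on circuit context rather than explicit text, which is why
  the table is configuration and the ablation result is stated relative to
  the configured set.
* No SBML-qual export: no SBML library is available in the supported
  dependency set, so BoolNet text is the interchange format.
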