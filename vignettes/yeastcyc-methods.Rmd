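---
title: "Methods: the yeastcyc cell-cycle model and its simulation suites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the yeastcyc cell-cycle model and its simulation suites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastcyc)
```

## The modeling formalism

`yeastcyc` is a multivalued logical (qualitative) model engine. Each of the
67 nodes holds an integer level, usually 0–3, read as absence, low, normal
and high abundance or activity; phenomenological milestone nodes (MASS, BUD,
DNA_Replication, Spindle, MITOSIS_EXIT) and checkpoint nodes use narrower
ranges with their own readings (e.g. MASS: pre-growth, growing, peak mass;
checkpoints: inactive, active-tolerated, active-arresting), and a few
sparsely characterized proteins (Cak1, Mih1) plus the Mating signal are
Boolean. A node's rule is an ordered clause list `condition → target`;
conditions are AND/OR/NOT combinations of threshold comparisons on regulator
levels. The first clause that holds supplies the target; no firing clause
means target 0, so unsupported levels always decay. Updates are synchronous
with unit steps: every node moves at most one level per step toward its
target, so activation from 0 to 3 passes through the intermediate levels and
takes three steps. The dynamics are therefore deterministic, and attractor
detection reduces to first state recurrence: the segment between the first
and second visit of the recurring state is the attractor.

Three assumptions are worth making explicit. First, synchrony: all proteins
update on a common clock, which compresses kinetic differences into clause
thresholds. Second, unit steps: level changes are gradual, so rule timing
races (who reaches a threshold first) are meaningful and are used
deliberately in the G2/M morphogenesis branch. Third, complexes take the
smallest level of their components (the pre-replication complex and the
mitotic checkpoint complex are modeled this way), a standard qualitative
stand-in for stoichiometric assembly.

## The cell-cycle network

The network couples seven functional blocks: the G1 transcription program
(Mcm1/ECB at peak mass, Cln3, SBF/MBF with the Whi5 repressor, SCB/MCB
elements, Cln1,2); replication licensing and firing (ORC, Cdc6, Tah11, MCM,
ARS assembling pre_RC; Cdc7-Dbf4 and Cdc45 with S-phase drivers and
Clb5,6); the Sic1/SCF-Cdc4 gate on S entry; the G2/M morphogenesis branch
(Swe1 opposed by Mih1, with the septin kinases Hsl1, Gin4, Kcc4 limiting
Swe1); mitotic progression and exit (Clb3,4 and spindle assembly, Clb1,2,
securin Pds1 and separase Esp1, APC/C with Cdc20 or Cdh1, the FEAR and MEN
routes of Cdc14 release, Swi5 and Sic1 re-accumulation); the four
checkpoints (DNA damage via Mec1/Chk1/Rad53, kinetochore attachment and
spindle alignment via Mps1/Bub1/Bub3/Mad3/Mad1-Mad2/MCC and Bfa1-Bub2,
mating via Far1/Fus3); and two lncRNA nodes that are inert until a
perturbation wires them to their protein partners (lnc9136 with Gin4/Hsl1,
lnc10883 with Mec1/Bub1). The builder self-checks 67 nodes and 144
interactions and refuses to construct anything else.

Milestone bookkeeping drives classification. MASS self-activates to 1 even
after mitotic exit and peaks at 2 to start the cycle; DNA_Replication, once
on, stays on until mitotic exit; MITOSIS_EXIT reaches 1 when all earlier
milestones and Clb1,2 are in place, and 2 only when Clb1,2 has been
destroyed — at level 2 it resets every milestone, and the cycle restarts.

A trajectory is a functional cycle when its attractor is cyclic, all five
milestones activate within it, MITOSIS_EXIT attains 2, and all milestones
(MASS included) return to 0. Anything else with persistent mass and
incomplete exit is an arrest. The phase comes from attractor markers: G1
when DNA is unreplicated; S when DNA is replicated but the S-phase driver
node is back at 0; G2 when the G2 driver is active; M when MITOSIS_EXIT
stalls at 1. When several clauses hold, the later phase wins (M > G2 > S >
G1): an M-arrest state also satisfies the G2 markers, and the most advanced
marker is the informative one. The S clause is interpreted exactly as
written (S driver at 0 with DNA replicated); under this model's wiring such
attractors are rare, and S-reported mutants are typically called G1 — a
known classification coarseness, visible in the benchmark's per-class
sensitivities. Arrest phases are read from attractor states only, not
transients, because arrests are steady outcomes; a dead attractor with
MASS = 0 matches no clause and is reported as `Unresolved` rather than
silently forced into a phase.

## Perturbation algebra

Four constraint variants cover every experiment:

* `fix` holds a node at one level for the whole run, initial state included
  (knockout = 0, overexpression = maximum). Fixes dominate all rules.
* `range` clips the rule-derived target into `[lo, hi]`; the node still
  moves by unit steps inside the band.
* `clamp_regulator` (`X[Y@v]`) evaluates X's rule with Y read at level `v`
  while Y itself evolves freely — the natural encoding for an upregulated
  checkpoint effector whose level is capped at 2 by its value semantics.
* `boost_on_activation` (`X^`) forces the target to the maximum from the
  first step at which the unmodified rule activates, until the node reaches
  the maximum; afterwards the unmodified rule governs. Under unit-step
  dynamics a one-step boost could never reach level 3, so "until the
  maximum is reached" is the only reading consistent with a node that
  climbs to high yield soon after activation and is then sustained or
  degraded by its regulators.

Conflicting constraints on one node are rejected at composition time, and
composition is order-independent for disjoint nodes.

Expression tables map to constraints by class: downregulated (negative
log2 fold-change at FDR < 0.01) → `[0,1]`; non-differentially expressed
(log2 fold-change 0) → `[0,2]`; upregulated → boost, or a regulator clamp
for the capped checkpoint effectors. One encoding choice was forced: a
Boolean node cannot express "low" as a range, so downregulation of MIH1 in
the LT set is encoded as a fix at 0 — the only Boolean gene in any set.

## LncRNA decoy semantics

LncRNAs are modeled as decoys that titrate their protein partners. The
injection rewrites each partner's clauses: as an inhibitor, every clause
target `t` becomes `max(0, t − v)` where `v` is the current lncRNA level
(full suppression at 3); as an activator, `min(max, t + v)`, plus a floor
clause so the partner is held at the lncRNA's level even when no clause
fires. The expansion enumerates the lncRNA levels inside the clause
conditions, so clause priority is preserved exactly and the dynamics with
the lncRNA at 0 are bit-identical to the base model. The subtraction
arithmetic is a documented tunable: the evidence constrains only the
endpoints (no effect at 0, full suppression at 3), and the linear
interpolation is the simplest monotone choice.

Expression regimes set the lncRNA's own behavior: `down` → range `[0,1]`,
`normal` → `[0,2]` (the base rule keeps the node at 0, so these regimes are
neutral), `up` → fixed at 3 (constitutive) or, for the G2-triggered
variant, a rule that targets 3 once the G2 driver activates, so the lncRNA
climbs 1, 2, 3 during early G2. The timing distinction matters
mechanistically: constitutive suppression of the septin kinases frees Swe1
*before* Clb1,2 activates, and with Mih1 absent (the LT ethanol state) Swe1
then vetoes mitotic entry — the arrest merely changes phase. The
G2-triggered variant frees Swe1 only after Clb1,2 is established, and the
accumulated Swe1 instead joins APC/C-Cdc20 in destroying Clb1,2, releasing
mitotic exit. This race is resolved by the unit-step timing, which is why
the septin kinases activate at replication rather than at the G2 driver.

## Experiment suites and problem sizes

* **Mutant benchmark** — 109 catalogue entries, each simulated from the
  general preset (MASS and the non-Mating checkpoints at 1) with its
  perturbation, classified and reconciled with the reported phenotype. A
  mutant reported only as "inviable" counts as correctly predicted when the
  model returns any arrest, and is relabeled Inviable before computing
  accuracy and one-vs-rest sensitivity/specificity; a reported
  phase-specific arrest is only matched by the same phase. The shipped
  catalogue is a synthetic reconstruction compiled from classical yeast
  genetics (deletion and overexpression phenotypes of the modeled genes,
  including temperature-sensitive alleles mapping to the same node); the
  file documents the notation and the `synthetic` label marks its
  provenance.
* **Random-perturbation ensembles** — 100, 1,000 and 10,000 simulations
  with every non-checkpoint node drawn uniformly over its own admissible
  levels and checkpoints started at 0, so arrests reflect the dynamics, not
  preset checkpoint signals. Drawing uniformly over 0–3 and clamping into
  narrower ranges is available behind `clamp_draw = TRUE`; it biases
  narrow nodes toward their maxima and is off by default. Runs are grouped
  by attractor to report the largest functional grouping (basin counting by
  simulation; exhaustive basins are infeasible at 2.6e36 states, where the
  enumerator refuses with a size estimate).
* **G1 scan** — 229 runs from the G1 preset (MASS, Cln3, Whi5, SBF, MBF at
  1; DNA unreplicated), each with one uniformly chosen node fixed at one
  uniformly chosen admissible level, sampled with replacement; checkpoint
  nodes are eligible. Both toggles (replacement, checkpoint eligibility)
  are exposed because the sampling design is underdetermined: 229 matches
  no exhaustive count of (node, level) pairs.
* **Checkpoint suite** — each checkpoint fixed at 1 and at its maximum
  (Mating is Boolean), plus all-at-minimum and all-at-maximum, from the
  general preset.
* **Ethanol, DNA damage and lncRNA suites** — deterministic runs of the
  named constraint sets (`LT_phenotype`, `HT_phenotype`,
  `dna_damage_<strain>`), the latter from a MASS-only initial state so that
  the damage signal enters exclusively through the expression-derived
  clamps. BMA64-1A has no differential expression of MEC1, CHK1 or RAD53
  and is reported as explicitly not analyzable.

All random suites take a single seed per run and derive their draws from
it; repeated calls with the same seed are bit-identical. The acceptance
script derives independent sub-seeds for the four reported quantities from
its master seed.

## What the ensembles do and do not emulate

The random-initial-state ensemble emulates a population of cells scattered
arbitrarily across the cycle, including biologically unreachable level
combinations; robustness here means the regulatory logic funnels arbitrary
states back into the functional cycle. It does not emulate molecular noise
(updates stay deterministic), asynchrony between cells' clocks beyond the
initial state, or graded expression changes; the ethanol and DNA-damage
suites cover the latter through constraint sets. Passing ensemble checks
therefore says the wiring is self-correcting, not that kinetic parameters
are right — the formalism has none.

## Numerical choices and degenerate inputs

* Canonical node order is declaration order; state hashing and basin counts
  depend on it, so it is fixed by the model definition.
* `max_steps` defaults to four times the recurrence bound for models of at
  most 20 nodes and to 5,000 for larger models; observed cell-cycle
  trajectories recur within ~100 steps, so the guard is generous without
  being unbounded. Exhausted budgets flag the trajectory `unresolved`;
  nothing is silently truncated.
* Ensembles run vectorized in lockstep over chunks of 512 runs (a memory /
  speed balance); the scalar simulator is the same code path with one run,
  so there is no scalar/vector divergence to test around.
* `simulate_model(..., max_steps = 0)` returns the bare initial state
  flagged unresolved; empty catalogues error; unparseable catalogue rows
  are skipped with a warning and flagged, not silently dropped.
* Range constraints admitting an initial value outside the band are
  clipped defensively on the first step.

## Known limitations

Re-replication control is absent (licensing is simply gated on the absence
of a spindle), Cdc14 release independent of Cdc15, spindle-pole-body
duplication and cytokinesis are not modeled, and Clb5,6/Clb3,4 redundancy
with the other cyclin waves is narrower than in living cells — visible as
specific benchmark mispredictions (e.g. clb5 clb6 deletions predicted
arrested). The S-arrest marker convention makes S arrests nearly
unreachable, concentrating those reports into neighboring phases. These are
properties of the model design, kept because relaxing them would break
correctly predicted mutants elsewhere; the benchmark report itemizes every
disagreement so the trade-off stays inspectable.
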