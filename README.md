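# yeastcyc

Multivalued logical modeling of the *Saccharomyces cerevisiae* cell cycle.

Ethanol stress perturbs the budding-yeast cell cycle, and different
ethanol-tolerance phenotypes arrest in different phases. `yeastcyc`
implements a 67-node, 144-interaction logical model of the yeast cell cycle
in which nodes hold discrete levels 0–3 (absent, low, normal, high) and are
updated synchronously, each node moving one level per step toward the target
prescribed by its logical rule. On top of the model, the package provides
the in-silico experiments that probe it: a 109-mutant literature benchmark,
random-perturbation robustness ensembles, checkpoint fixation scans, and
transcriptome-constrained simulations of ethanol stress, DNA damage, and two
ethanol-responsive lncRNAs (lnc9136, lnc10883) that act as protein decoys.

## The model in brief

Each node `i` carries a level `x_i ∈ {0, …, max_i}` (`max_i ≤ 3`). A rule is
an ordered list of clauses `condition → target`; the first clause whose
condition holds in the current state supplies the target `T_i(x)`, and a
state with no firing clause targets 0. All nodes update simultaneously with
unit steps:

```
x_i(t+1) = x_i(t) + sign( T_i(x(t)) − x_i(t) )
```

so a node switched from 0 to a target of 3 passes through 1 and 2. The
dynamics are deterministic; a trajectory is simulated until a state recurs,
and the segment between the two visits is the attractor (a single repeating
state is a point attractor). A simulation is a **functional cell cycle**
when its attractor is cyclic and, inside the attractor, the five
phenomenological milestone nodes (MASS, BUD, DNA_Replication, Spindle,
MITOSIS_EXIT) all activate, MITOSIS_EXIT reaches its peak level 2 (mitotic
exit), and every milestone returns to 0 so the cycle restarts. Otherwise the
attractor is an **arrest**, assigned a phase from marker levels (persistent
MASS with MITOSIS_EXIT < 2; G1 if DNA is unreplicated, S/G2 by the phase
driver nodes, M if MITOSIS_EXIT stalls at 1), with later phases taking
precedence.

Perturbations form a small algebra: `Node!` (knockout, fixed at 0),
`Node=v` (fixed level, overexpression at the maximum), `Node[lo,hi]`
(level range), `Node[Reg@v]` (the node's rule reads one regulator at a
fixed level while the regulator itself evolves), and `Node^`
(boost-on-activation: the node climbs to its maximum as soon as its rule
first activates, then follows normal regulation). Differential-expression
tables map onto these: downregulated genes → `[0,1]`, non-differentially
expressed → `[0,2]`, upregulated → boost (or a regulator clamp for
checkpoint effectors capped at level 2).

## Worked example

```r
library(yeastcyc)

model <- build_cellcycle_model()
model
#> <logic_model> yeast_cell_cycle
#>   nodes: 67  interactions: 144
#>   classes: checkpoint=4, complex=13, gene_or_lncRNA=2, phenomenological=5,
#>            protein=39, regulatory_element=4

## unperturbed cycle: cyclic attractor, milestones in order
traj <- simulate_model(model, preset_state(model, "regular"))
traj
#> <yc_trajectory> yeast_cell_cycle: 65 states, attractor cyclic (length 41)
classify_outcome(traj)
#> [1] "Viable"
autoplot(traj)   # step-by-node heat map

## ethanol stress, lower-tolerance phenotype: arrest in mitosis
run_ethanol_suite("LT", model)$outcome
#> [1] "Arrest_M"

## the 109-mutant literature benchmark
bm <- run_mutant_benchmark(model)
glance(bm)
#>   n_mutants n_skipped n_correct accuracy
#> 1       109         0        98    0.899
tidy(bm)       # per-class sensitivity/specificity

## robustness: random initial levels, checkpoints silenced
run_random_ensemble(1000, seed = 42, model = model)
#> <yc_ensemble> 1000 runs (seed 42)
#>   functional cycles: 75.1% (largest functional grouping: 751 runs)
#>   arrests: Arrest_G1=237, Arrest_M=12
```

The benchmark accuracy says how often the model's predicted outcome
(viable, or an arrest in a specific phase) matches the phenotype reported in
the genetics literature for the same perturbation; the ensemble output says
that three quarters of random initial conditions still funnel into the
functional cycle, with the remainder arresting mostly before S phase.

The model also loads and saves in a plain-text native format and SBML-qual
(`write_model_native()`, `write_model_sbmlqual()` and readers), trajectories
export as TSV, and exhaustively enumerated state-transition graphs of small
models export as GraphML. A command-line front end over the same functions
is in `inst/cli/yeastcyc.R`.

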