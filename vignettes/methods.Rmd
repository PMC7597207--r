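---
title: "Models and methods behind cellscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cellscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cellscale is a multi-scale simulation engine for bacterial cells plus a
library of mechanistic process models that compose into integrated
*E. coli* agents: cells that exchange molecules with a shared spatial
environment, express the genes of the chemotaxis machinery from sequence,
swim by run-and-tumble motility, grow, and divide. This vignette explains
the models, their assumptions, the parameters that matter, and the design
choices made where the design was genuinely open.

## The engine: processes, stores, hierarchies

A simulation is a *compartment hierarchy*: a tree of stores holding state
variables, together with a bipartite *topology* wiring mechanistic
*processes* to stores through named ports. Every variable carries a schema:
units, an *updater* declaring how process updates are applied (`accumulate`,
`set`, `nonnegative_accumulate`), a *divider* declaring how the value is
partitioned at cell division (`halve`, `binomial`, `copy`, or `split_list`
for sub-compartment stores such as flagella), and an *emitter* flag marking
it for the output time series.

Processes declare their own time-steps, so fast mechanisms (chemoreception,
motor switching, body mechanics at 0.01 s) coexist with slow ones
(metabolism, gene expression at 1.0 s). The scheduler advances a temporal
front to the earliest due process; processes due at the same instant run in
sorted name order, which makes multi-writer resolution deterministic (for
additive updates the order is irrelevant anyway; for simultaneous `set`
updates the sorted order is the package's documented tie-break). Time-steps
are validated on a 1 microsecond lattice at construction; non-commensurate
steps are rejected outright rather than allowed to drift. Dynamic (runtime)
adjustment of time-steps is deliberately out of scope; the declared schedule
is fixed at construction.

Reproducibility: a single experiment seed feeds a L'Ecuyer-CMRG stream
fountain, and each process draws from its own named substream. Results are
therefore bit-identical across runs of the same configuration and unaffected
by adding unrelated processes.

Division is a *topology update*: a process emits a `divide` message, the
engine partitions the agent's subtree with the per-variable dividers
(binomial partitions conserve counts exactly; `split_list` deals
sub-compartments out alternately, so five flagella split 3 and 2), retires
the mother's processes, and instantiates daughter processes from a
composite-supplied template. The template may also patch daughter state --
the growth composite uses this for the phylogeny color mutation (an
isotropic Gaussian step, sigma 0.08 in RGB space; the mutation distribution
is a package choice, only "a mutation in color space" being specified by the
biology) and to offset daughters half a body-length apart so that volume
exclusion separates them smoothly.

## Environment: capsule mechanics and molecular fields

Agent bodies are 2D capsules with continuous positions and orientations in a
bounded arena. At the micron scale the Reynolds number is tiny, so the
mechanics are fully overdamped: velocity is instantaneous force over damping,
`v = F / gamma`, with no inertial transient. Thermal jitter is a force of
fixed magnitude applied each step in a uniform random direction at a uniform
random point on the body axis (producing both translational and rotational
diffusion); the exact distribution of the thermal forcing is a package
choice. Volume exclusion resolves capsule-capsule overlaps by pushing pairs
apart along their closest-approach vector in a few relaxation sweeps, which
is what makes growing colonies spread. Walls reflect bodies; fields use
no-flux boundaries (the boundary conditions are package choices).

Molecular fields live on a rectangular grid of bins (concentrations in mM).
Diffusion is an explicit five-point Laplacian scheme; the stability bound
`D dt / h^2 <= 0.25` is enforced as a configuration error and the diffusion
process sub-steps internally to respect it. Total moles are conserved to
machine precision. An agent's *local environment* is the single bin
containing its centroid; uptake and secretion convert between amounts
(mM um^3) and bin concentration through the bin volume, with uptake floored
at local availability.

Damping calibration: the translational damping (0.034 pN s/um) is set so
that the four-flagellum run thrust at the model's own operating PMF drives
swimming at the measured mean speed; the rotational damping (0.075
pN um s/rad) is calibrated so that tumbles reorient the cell by about 70
degrees on average. Both are documented as calibrated constants, of the same
order as Stokes drag for a 2 um bacterium in water.

## Growth and division

The minimal agent lumps all cytoplasm into one mass that grows as
`m(t) = m0 * 2^(t / tau)` with `tau = 2400` s (the 40-minute doubling time),
starting at 1000 fg and dividing at 2000 fg. The division condition is
checked once per 1.0 s step; overshoot within a step is accepted since
nothing in the model needs sub-second event location. The `halve` divider
conserves mass at division exactly.

## Transport and metabolism (dynamic FBA)

Metabolism is flux balance analysis: maximize the biomass objective subject
to steady state (`S v = 0`) and flux bounds, re-solved every 1.0 s with
updated constraints (dynamic FBA). The biomass column drains the
objective-composition metabolites out of the steady-state network; its flux
times the composition is credited to the cell's internal pools, and summing
pools times molecular weights gives cell mass. Because every packaged
reaction is mass-balanced, environment mass loss equals cell mass gain
exactly at every step. An infeasible program is an explicit result handled
as a zero-growth step.

The LP is solved with the simplex method (`boot::simplex`), with variables
shifted to handle negative lower bounds. FBA optima can be degenerate:
the package reports the solver's optimum, and tests assert only objective
values, never individual fluxes.

Transport runs through *convenience kinetics*, a generalized
Michaelis-Menten law

$$\mathrm{rate} = k_{cat} E \prod_s \frac{s/K_s}{1 + s/K_s + \sum_i I_i / K_{I,i}}$$

over substrates and cofactors with competitive inhibitors in the
denominators; with one substrate and no inhibitors it is exactly
Michaelis-Menten. Each transport flux is written to the flux store as an
*equality* bound on the matching exchange reaction -- supply is
authoritative, and metabolism uses exactly what transport delivers.

The packaged toy network (glucose uptake, lactose uptake, hydrolysis,
precursor synthesis, biomass) is the default, no-download test substrate. A
loader for BiGG-style genome-scale JSON models is provided for users with
their own model files; genome-scale regression is deliberately not part of
the test suite. Kinetic defaults were fitted so that a 1000 fg cell on
replete glucose grows with about a 40-minute doubling time, and so that the
three diauxie regimes appear in a 700 s run: glucose-phase growth,
a lag after glucose depletion while LacY accumulates, and lactose-phase
regrowth. The LacY process is a minimal stochastic ODE -- Hill-repressed
transcription (the glucose uptake flux is the repressing signal), first-order
mRNA decay, protein synthesis proportional to mRNA, dilution by growth, and
sqrt(dt)-scaled noise; its parameters are calibrated, not measured.

## Stochastic gene expression from sequence

Transcription, translation, complexation and degradation operate on explicit
sequences with hard bookkeeping rules: RNAP binds promoters by the Gillespie
algorithm with transcription-factor-gated propensities and elongates at
50 bp/s, consuming one matching nucleotide and one ATP per base; a promoter
is occluded until its RNAP clears 30 bp. Ribosomes bind per-gene with
configurable affinities, elongate at 22 aa/s consuming matching amino acids
and two ATP each, with a 50 bp occlusion spacing on each transcript.
Degradation (endoRNAse, Michaelis-Menten in total transcript count) returns
a transcript's bases to the pools at one ATP per nucleotide. Proteins are
never degraded; they dilute by growth and division. These rules make two
exact invariants testable: free-plus-polymerized monomer totals are constant,
and ADP produced equals nucleotides transcribed plus twice amino acids
translated plus nucleotides degraded.

Within each 1.0 s engine step, binding and complexation events are drawn
stochastically (Gillespie) while elongation advances deterministically at the
fixed rates -- a hybrid chosen because the rates are fixed quantities while
binding is genuinely few-molecule stochastic. On pool exhaustion, partial
polymers stall in place and resume when monomers return.

The packaged flagellar regulon fixture has seven operons in three classes:
the constitutive master regulator `flhDC`; middle operons (`flgAMN`,
`flgBCD`, `fliFGH`, `fliAZY`) activated by the FlhDC complex at increasing
thresholds; and late operons (`fliC`, `motAB_cheAW`) activated by free FliA.
FlgM sequesters FliA by complexation; completion of a basal body triggers
FlgM export (a direct count removal -- the export mechanism itself is not
modeled), releasing FliA and enabling the late class. Complexation chains
monomers into a basal body and then a complete flagellum at the
order-of-magnitude association propensity of 1000/s. This architecture
produces "just-in-time" transcript ordering -- early before middle before
late -- as a consequence of the thresholds, and it is tested as a median
ordering over 20 seeded replicates. Polymerase counts are fixed at 10 RNAPs
and 20 ribosomes (the copy numbers estimated to support about four
flagella), are not themselves expressed, and are reset to fixture values in
daughters at division. Gene and protein sequences in the fixture are
synthetic placeholders at reduced, realistic-ordering lengths (about
100-500 bp per operon, keeping test runs to seconds); the regulatory
topology, not sequence content, carries the biology. Promoter and ribosome
affinities are calibrated so that expression is sustained with those
polymerase counts.

## The chemotaxis sensorimotor chain

**PMF.** The proton-motive force is the Goldman-Hodgkin-Katz membrane
potential over K+, Na+ and Cl- plus a constant pH term. The packaged ion
concentrations (K 200/5, Na 10/100, Cl 10/50 mM in/out; relative
permeabilities 1, 0.05, 0.05; 310 K) give -79.1 mV, and the pH term of
-54.9 mV is calibrated so the default PMF is -134 mV. Flagellar rotation
moves 1200 protons per revolution (120,000 per second at the typical
100 Hz); this flux is bookkept but assumed instantly restored by the cell's
pumps, so the PMF does not deplete.

**Receptors.** The chemoreceptor cluster is a Monod-Wyman-Changeux two-state
unit of Tar and Tsr homodimers in a 1:2 ratio (6:12 by default). Cluster
free energy in kT is

$$F = \sum_{type} n_{type} \left[\epsilon(m) + \ln\frac{1 + c/K_{off}}{1 + c/K_{on}}\right],
\qquad P_{on} = \frac{1}{1 + e^{F}}$$

with a per-dimer methylation offset `epsilon(m) = 1 - 0.5 m` and MeAsp
dissociation constants (Tar 0.02/0.5 mM off/on, Tsr effectively insensitive)
from the MWC receptor literature. Attractant raises F and so favors the off
state. Methylation integrates `dm/dt = 0.1 (a0 - P_on)` toward the baseline
activity `a0 = 1/3`, bounded to `[0, 8]`: activity returns exactly to
baseline for any sustained step within the methylation range (perfect
adaptation), and larger steps need larger methylation shifts, hence longer
adaptation times -- both are tested properties. Clusters start adapted to
their ambient concentration.

**CheY-P.** Steady-state CheY-P follows a Michaelis-type balance of
activity-proportional CheA autophosphorylation against CheZ
dephosphorylation, `Y_P = Y_max a / (a + 0.5)`, normalized so baseline
activity maps to the baseline CheY-P of 2.516 uM used by the switch.

**Motor switching.** Each flagellum is a bistable two-state Markov switch.
The free-energy barrier `dG(Y) = g0/4 - (g1/2) Y/(Y + K_M)` (g0 = g1 =
40 kT, K_M = 3.06 uM) sets `k_+ = omega e^{-dG}` (CCW to CW, increasing in
CheY-P) and `k_- = omega e^{+dG}`, with per-step switching probability
`rate x dt` at dt = 0.01 s (larger steps are rejected: the sensorimotor
chain must track the environment at this rate). The attempt frequency
omega = 0.6633/s is calibrated so that at baseline CheY-P a four-flagellum
cell has a mean run of 1.0 s (run exit rate `4 k_+` with `k_+ = 0.25/s`) and
a mean tumble of 0.7 s (the mean first-passage time of the CW-count
birth-death chain back to zero, computed in closed form as the calibration
oracle). Long-run CW occupancy matches the analytic `k_+/(k_+ + k_-)`
stationary law, which the tests use as an oracle.

**Motility.** The veto rule aggregates flagella: any CW flagellum forces a
tumble, all-CCW (one or more) is a run, no flagella is nonmotile. Run thrust
is `f0 (|PMF|/140 mV) L(n)` with a logarithmic bundling law
`L(n) = 1 + a ln n`, where `a = (0.5/0.31 - 1)/ln 4` is fixed by the two
calibration anchors -- 0.31 pN for a single flagellum and 0.5 pN for four at
the 140 mV baseline. The law's logarithmic form reflects the diminishing
contribution of each flagellum joining the bundle; anchoring it at both
printed thrusts makes the four-flagellum value exact. Runs apply thrust
along the body axis at the rear pole; tumbles apply the same magnitude at a
random angle drawn once per tumble and held, whose lever arm torque
reorients the cell (the equal-magnitude choice for tumble thrust is a
package decision; only the random application angle is specified by the
biology).

With these calibrations, a single four-flagellum agent simulated for 300 s
at dt = 0.01 s in a uniform attractant field swims at about 14.1 um/s,
with mean runs near 1.0 s, mean tumbles near 0.7 s, and mean reorientation
near 70 degrees between consecutive runs -- the four statistics the
acceptance script recomputes. Trajectory analysis attributes each sampled
displacement to the motile state labeled at that sample, drops
boundary-truncated segments from duration statistics, and measures
reorientation as the angle between net-displacement headings of consecutive
runs folded into [0, 180] degrees.

**Gradient climbing.** In an exponential attractant field
`c(y) = c0 e^{y/lambda}` (c0 = 0.02 mM, lambda = 150 um by default --
chosen so the gradient spans Tar's sensitive range; the field is kept
static, with no diffusion, to preserve the profile), receptor-bearing agents
lengthen up-gradient runs and climb, while agents with defunct receptors
(activity pinned at baseline) random-walk. The packaged chemotaxis
experiment places all agents at a common start point, half of them
receptor-less, and the test asserts greater mean upward displacement for the
receptor-bearing half across five seeds.

## Problem sizes and numerical choices

The packaged experiment scales are chosen so every integration finishes in
seconds to a few minutes on one core: colony growth to ~8 cells, diauxie
over 700 s in a single compartment, flagellar expression over ~2600 s with
one division, motility over 300 s per seed, gradient climbing with 4 agents
over 100 s. Long-horizon setups (15,000 s colonies, 8-minute 12-agent
gradient runs) are available through the experiment builders and the CLI's
`--full-scale` flag but are not part of the test suite. Other numerical
choices worth knowing: elongation advances in whole-step quanta
(`round(rate x dt)`); uptake in dynamic FBA is capped by local availability
within the step; simultaneous Gillespie bindings within one engine step use
propensities frozen at the step's start; and the emitted series records at a
configurable interval (1.0 s by default, 0.01 s in motility runs so run and
tumble segments are resolved).

## What the synthetic setups do and do not show

The synthetic fixtures emulate network *structure* (regulon topology,
stoichiometry, thresholds) and the paper-scale rate constants, not curated
genomic content: sequences are random at reduced lengths, kinetic and
affinity defaults are calibrated rather than measured, and the toy
metabolic network stands in for a genome-scale reconstruction. Passing tests
therefore demonstrate that the mechanisms compose and reproduce the intended
emergent behaviors (diauxie phases, just-in-time ordering, adaptation,
motility statistics, gradient climbing) at reduced scale; they do not
validate genome-scale flux predictions, real promoter kinetics, or
absolute colony-scale timings. Known limitations: 2D bodies only, no
hydrodynamic interactions, a single containing bin as the local
environment, no tRNA charging or protein degradation, fixed polymerase
counts, and no PMF depletion by motor load.
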