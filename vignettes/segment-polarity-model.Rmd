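---
title: "The segment polarity network model: equations, numerics, and screening protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The segment polarity network model: equations, numerics, and screening protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological system and the model

During Drosophila embryogenesis, the segment polarity genes — *wingless*
(`wg`), *engrailed* (`en`), *hedgehog* (`hh`), *cubitus interruptus*
(`ci`) and *patched* (`ptc`) — maintain a stable striped expression
pattern across each parasegment after cellularization.  The classic ODE
model of this circuit places one copy of the gene network in every cell
of a hexagonal lattice, with membrane-bound proteins mediating the
cell–cell signaling that keeps the stripes in register.  `spnsim`
rebuilds that model as an explicit reaction network, simulates it, and
reproduces the two analyses that made it famous: a random-parameter
robustness screen (how often does a random parameter set form the
stripes?) and a steady-state multistability census.

Each cell carries 33 dynamic species: the five mRNAs; the cytosolic
proteins EN, IWG (intracellular Wingless), CI, and CN (the truncated
repressor fragment cleaved from CI); and four membrane proteins — EWG
(exported Wingless), PTC, HH, and PH (the Patched–Hedgehog complex) —
each resolved into six pools, one per hexagon side.  On the standard
1×4 periodic grid this gives 132 state variables.  Cells appose each
other side-to-side (side 5 of one cell touches side 2 of its posterior
neighbor), membrane pools exchange with their two within-cell neighbor
sides, and the signaling interactions read the *apposed* pools of the
neighboring cells.

## Rate laws

Transcription uses Hill-type regulation.  With
$\phi(x;\kappa,\nu) = x^\nu/(\kappa^\nu + x^\nu)$ and
$\psi = 1-\phi$, the inducer–repressor promoters (`en`, `ptc`, `hh`)
follow

$$v = V\,\frac{(I\,\psi(R;\kappa_R,\nu_R))^{\nu_I}}
             {\kappa_I^{\nu_I} + (I\,\psi(R;\kappa_R,\nu_R))^{\nu_I}},$$

where the repressor attenuates the inducer before the activation
nonlinearity.  `wg` uses a composite promoter in which CI activation
(gated by CN repression) and IWG auto-activation compete additively,
with weights `alpha_CIwg` and `beta_WGwg`; `ci` is transcribed
constitutively (basal input `B`) under EN repression.  Translation,
decay, membrane transfer, CI cleavage (promoted by free Patched via
$\phi(\mathrm{PTC_T})$) and PTC–HH binding across apposed sides are
first- or second-order mass action.  Decay is parameterized by
half-lives, rate $\ln 2 / H$.  The totals
$\mathrm{PTC_T}$, $\mathrm{PH_T}$ (within-cell sums) and
$\mathrm{EWG_T}$ (sum of the six apposed neighbor EWG pools — what a
cell's `en` promoter actually sees) are derived quantities, not state
variables.

### Guarded exponentiation

IEEE arithmetic computes $x^\nu$ as $e^{\nu \log x}$, so any
infinitesimally negative concentration — routine for a
predictor–corrector integrator near zero — turns the right-hand side
into NaN.  Every exponentiation base that depends on the state is
therefore wrapped as $\max(\epsilon, x)$ with $\epsilon = 10^{-80}$
(configurable, and the guard can be disabled to reproduce the failure
mode).  Half-saturation constants are positive constants and are never
guarded.  The package's own measurement of the effect, over random
parameter sets integrated on the standard time course: with guards off
roughly one in ten integrations dies with an invalid state; with guards
on, none out of thousands.  Trajectories are deliberately *not* clipped
at zero: the fix belongs in the rate laws, not in the solver.

## The parameter registry

The model has 53 named global parameters shared by all cells; 48 are
sampled in the screens and 5 are fixed (`B`, `V_max`, and the three
side-to-side membrane diffusion rates, all at 1).  Sampling is
log-uniform per category:

| category | parameters | range |
|---|---|---|
| half-lives | 13 (`H_en` … `H_PH`; EWG has its own `H_EWG`) | 5–100 time units |
| half-saturations | 11 `kappa_*` | 10⁻³–1 |
| cooperativities | 11 `nu_*` | 1–10 |
| kinetic rates | `alpha_CIwg`, `beta_WGwg`, `C_CI`, `k_bind`, `r_exo_WG`, `r_endo_WG`, 5 translation rates `T_*` | 10⁻³–10³ |
| concentration scales | `PTC_0`, `HH_0` | 1–1000 |

The identity of the five non-sampled parameters is not fully settled in
the source literature; the registry above is this package's documented
choice, constrained to exactly 53 parameters with 48 sampled.  The five
translation rate constants complete the count: the network has exactly
five translation steps, and treating their rates as free parameters is
the natural way to obtain a 53-parameter registry whose remaining
structure matches the published enumeration.  The registry (names,
values, ranges, scales, sampled flags) is the normative configuration
and round-trips through JSON (`write_parameters()`).

## Numerics

Integration uses LSODA (stiff/non-stiff switching) on a compiled
right-hand side.  The reference time course runs to 1100 time units
sampled every 5, with `atol = 1e-13`, `rtol = 1e-8`; tightening to
`1e-15`/`1e-10` moves the demonstration trajectory by less than 10⁻⁴ in
max-norm.  Screening and steady-state work use `atol = 1e-12`,
`rtol = 1e-6`, the customary defaults for this kind of batch scan.
Solver failures are captured per record, never raised: a trajectory ends
`ok`, `invalid_state` (non-finite values — possible only with guards
off) or `no_convergence`.

Steady states are located by integration only (no Newton polishing)
over doubling time spans, declared at resolution 10⁻⁴ by a dual
criterion: the max-norm of the right-hand side must be below the
resolution *and* the state must have moved less than the resolution
over the last span.  Every reported state is re-checked by direct
evaluation of the right-hand side.  The census search horizon is
5 × 10⁴ time units — about 350 times the slowest admissible half-life —
after which a non-converged initial condition is counted as having no
reachable steady state (such parameter sets typically sustain
oscillations, which are out of scope).  Two converged states are the
same attractor when they differ by less than 10⁻² in max-norm, two
orders of magnitude above the resolution, so numerical jitter cannot
split an attractor and genuinely distinct states cannot merge.

## The screen

`run_screen()` samples parameter vectors (each record from its own
derived seed, so batches are order-independent and resumable), builds
the chosen initial-condition preset, integrates the standard time
course, and scores the terminal pattern.  The target places the
parasegment boundary between cells 2 and 3 of the four-cell repeat:
`wg` on in cell 2, `en` and `hh` in cell 3, `ptc` in cells 2 and 4.
Preset starting patterns translate the descriptive classes of the
source material to fixed values 0.15 ("<20%"), 0.4 ("20–60%") and 0.9
("60–100%"); the exact degraded vector was never published, so the
blurred-stripe preset here is a documented reconstruction.

The score is a contrast ratio: per scored mRNA, time-average the last
200 time units, take `m_on` = the minimum over on-cells and `m_off` =
the maximum over off-cells; the species score is `m_off / m_on` and the
total score the maximum over the four species.  A hit is a score below
0.2 — at least five-fold on/off separation for every scored gene.  This
judges the pattern only, not its amplitude, and therefore identifies
*more* parameter sets than a criterion that additionally demands strong
absolute expression (an alternative with an expression floor of 10⁻³
was evaluated and rejected: it suppresses genuine low-amplitude stripe
solutions and drives the close-to-target hit rate far below the
published value).  Failed integrations score infinity and count as
tries, not hits.

## The multistability census

`run_multistab_census()` samples parameter sets with the same rules as
the screen and, for each, draws 15 initial conditions uniform on [0,1]
for all 132 species, finds the reachable steady state from each, and
counts distinct attractors after deduplication.  The summary reports
the fraction of sets with at least one steady state and the fraction
with more than one; `compare_parameter_distributions()` contrasts the
per-parameter medians of the mono- and multistable groups (the
published full-scale census finds `kappa_CNptc` — the strength of `ptc`
repression by CN — about five-fold larger in the multistable group).

## What the defaults do and do not show

The package's test suite runs the screens and the census at reduced
Monte-Carlo sizes (1,500 crisp tries, 800 close-to-target tries, 40
census parameter sets; the published experiments used 2.4 × 10⁵ to
7.5 × 10⁵ tries and 5,000 sets) and compares observed rates through
99% binomial confidence intervals.  At these sizes the intervals are
wide; they establish consistency of order, not precision.  The model
itself is a reconstruction from the printed description of the network:
the wiring of the composite `wg` promoter, the binding scale factors,
the preset vectors and the five "extra" sampled parameters are each
documented choices where the source is silent, and each can shift the
absolute hit rates by small integer factors.  The close-to-target
screen lands close to the published 1/39; the crisp screen finds hits
several-fold more often than the published 1/236, in the permissive
direction expected of a pattern-only score.

## SBML interchange

`export_sbml()` writes SBML Level 3 Version 1: one unit compartment per
cell, cell-qualified species ids (`EWG5_0_1` — commas in the
biological labels are not legal SBML ids), all 53 parameters, the
totals as assignment rules, and full kinetic laws in MathML, with the
guard encoded as `piecewise` (L3V1 core has no `max` operator).  A JSON
sidecar records the reference time-course specification and provenance.
`import_sbml()` evaluates a document's rules and kinetic laws directly,
which gives an independent right-hand side: the export→import round
trip agrees with the compiled core to better than 10⁻⁹ relative.
Reading and writing use a purpose-built serializer over `xml2`;
validation is structural (well-formedness, identifier resolution,
parseable math), not XSD schema validation.
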