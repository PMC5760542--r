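---
title: "Modelling meiotic entry and commitment in fission yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling meiotic entry and commitment in fission yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological problem

Nitrogen starvation makes *Schizosaccharomyces pombe* cells leave the
mitotic cycle, mate, and enter meiosis. Once entered, meiosis is completed
even if nutrients return: the decision is irreversible past a commitment
point. `meioswitch` implements a deterministic ODE model of the regulatory
network behind this switch, in two layers:

* the **meiotic-entry subsystem** — Ste11, Mei2, Pat1 and the pheromone /
  conjugation cascade (PheS, Mat1-Pm, Mei3), driven by the nutrient inputs
  Tor2 and PKA; and
* the **integrated model** — the subsystem coupled to a compact fission-yeast
  cell-cycle model with division events, to study cell-cycle exit, the two
  accelerated divisions and G1 arrest under starvation.

Time is in minutes; concentrations are dimensionless activity units.

# The meiotic-entry subsystem

Eight dynamical variables: cytoplasmic and nuclear Ste11 (`ste11c`,
`ste11n`), active and Pat1-phosphorylated Mei2 (`mei2a`, `mei2p`), lumped
pheromone-signalling activity (`phes`), Mat1-Pm (`mat1pm`), free Mei3
(`mei3`) and the Pat1:Mei3 complex (`cpx`). Free Pat1 is algebraic,
`pat1_t - cpx`, so Pat1 mass conservation is structural rather than
numerical. Rst2 (the PKA-repressed transcription activator) and Rpol
(CTDK-I-dependent RNA-polymerase-II CTD activity, stimulated by Mei2) are
algebraic functions of PKA and of total Mei2 respectively; this choice is
recorded in the parameter manifest.

Kinetic forms follow the conventions of the field: Ste11-driven
transcriptional upregulation steps (PheS, Mat1-Pm, Mei2, Ste11
autoregulation) are Hill functions of nuclear Ste11, which collapse the
intermediate signalling steps; the Mei2 phosphorylation/dephosphorylation
cycle uses Michaelis–Menten kinetics with small Michaelis constants, giving
the zero-order ultrasensitivity that makes Mei2 activation switch-like;
Pat1:Mei3 complex formation is mass action.

The wiring implements the feedback structure that carries the biology:

* **Ste11 synthesis** = leak + Rpol × (Rst2 arm + autoregulation arm). The
  autoregulation arm is a sharp Hill function (`k_mste11`, `hs`) of nuclear
  Ste11 and, in the integrated model, is multiplicatively inhibited by
  Cdk1:Cdc13 (the promoter-binding coupling).
* **Ste11 localisation**: import is boosted by PheS and inhibited by active
  Pat1 and by the *product* of Tor2 and PKA activities. The product form
  implements their cooperative inhibition: lowering either input alone
  fully relieves this term, which is what lets either *pka1Δ* or *tor2-ts*
  initiate differentiation in rich medium. Export is increased by Tor2.
* **Mei2**: synthesised (mostly Ste11-dependently) in the active form,
  phosphorylated by Pat1 and by Tor2 into an inactive pool that is
  destabilised by Pat1 and Tor2; a constitutive phosphatase opposes them.
  With Pat1 fully active the cycle is pinned (active Mei2 near zero); an
  intermediate Pat1 activity — as in *mei3Δ* — still pins it, which is what
  enforces the conjugation-before-meiosis order.
* **PheS** requires both nuclear Ste11 (low threshold `j_phe`) and Mei2
  (`j_phemei2`); the Mei2 requirement encodes the observation that without
  Mei2 pheromone signalling is not mounted. **Mat1-Pm** has a much higher
  Ste11 threshold (`j_pm`), so it fires only after the PheS-driven boost of
  Ste11 import — this ordering is the spine of the sequential cascade.
* **Pat1** is inhibited two ways: stoichiometric sequestration by Mei3
  (tight binding; dissociation and complex turnover are slow) and
  activity modulation by PheS (hyperbolic, `j_iphe`). The double-negative
  loop Ste11n → Mat1-Pm → Mei3 ⊣ Pat1 ⊣ Ste11n makes commitment
  irreversible; the PheS loops alone are bistable but reversible.

## Parameters and calibration

All parameter values are the package's own calibration. They were chosen —
first by design analysis, then by an automated coordinate search — so that
the simulated dynamics reproduce, qualitatively, the published behaviour of
the wild type and of the full mutant panel in `genotype_registry()` (the
mating/meiosis phenotype table the model family was built against),
together with the ordered starvation cascade, the reversible/irreversible
return-to-growth pair, and the two-switch bifurcation structure. This
mirrors how models of this family are parameterised in the literature:
half-lives anchored to rough experimental scales (Ste11 unstable, ~7 min;
active Mei2 stable, ~1 h), everything else fitted to the qualitative mutant
panel. The defaults are shipped as plain-text `.ode` files under
`inst/extdata/` and round-trip exactly through `load_parameters()`.

Two modelling reductions are worth knowing about. The Mei2 phospho-species
are lumped into one inactive pool (no separate Pat1-site and Tor2-site
species); Tor2's action is split into a phosphorylation route and a
destabilisation weight so that Pat1-site mutants (*mei2-SATA*) are active
under rich conditions while Tor2 overexpression can still suppress
*pat1-ts* meiosis. And pheromone signalling in a heterothallic culture
without a partner is disabled at the schedule level (`phes_enabled`), since
there is no pheromone source; the registry row modelling exogenous
pheromone addition re-enables it.

## Nutrient schedules

Inputs are piecewise constant; the integrator restarts at every breakpoint,
so steps are not smoothed. The default starvation protocol sets Tor2 to 0
and PKA to 0.75, encoding the assumption that PKA activity is not
completely inhibited by nitrogen starvation — this is also what makes the
activated-Tor2 strain sterile in the model. Levels up to 1.5 are allowed
for overexpression alleles.

## Phenotype classification

`classify_phenotype()` scores a run against the wild-type starved reference
plateaus (`starved_reference()`, computed once per base parameter set and
cached). Meiosis is positive when final active Mei2 exceeds 50% of the
reference plateau. Mating is positive when both PheS and Mat1-Pm peak above
50% of their reference plateaus *before the commitment time* (the first
crossing of the active-Mei2 threshold). The pre-commitment window is the
package's own refinement of a plain peak rule: conjugation must precede
meiotic entry, so strains that activate Mei2 prematurely (*pat1-114* at
restrictive temperature, constitutive Byr2, phospho-site-free Mei2) are
scored non-mating even though the transcriptional cascade may still fire
later. Without this refinement several published "blocked mating, ectopic
meiosis" strains cannot be reproduced by any threshold choice.

## Mutant conventions

Where the literature gives a mechanism but no number, the registry applies
fixed conventions, each an editable registry entry: deletions zero the
relevant rate exactly; `nmt`/`pREP41` overexpression scales the relevant
synthesis 10-fold (macro `@mei2oe`); phospho-site-dead (A) alleles zero the
corresponding site-specific rate; phospho-mimetic (D) alleles clamp the
modified process at its kinase-saturated value (macros `@phe_sat`,
`@pat_max`); constitutive Byr2 clamps PheS high with increased potency
toward Pat1 (`@phe_hyper`); Tor2 overexpression scales Ste11 export and the
Tor2 route on Mei2; *mts2Δ* (proteasome) stabilises Mei2 **and** Ste11
10-fold — the extension to Ste11, itself a highly unstable proteasome
substrate, is what distinguishes the proteasome mutant from plain Mei2
overexpression, which the model otherwise treats symmetrically. The
*ste11-T173/S218* pair (both A and D alleles are blocked experimentally) is
encoded as loss of productive autoregulatory promoter binding (A) and as a
locked import gate (D). "Low frequency" phenotypes are treated as blocks;
a deterministic model cannot express frequencies. Two promoter-replacement
rows are marked provisional in the registry.

# The integrated model

The cell-cycle layer is a compact fission-yeast cycle in the
Novák–Tyson tradition: total Cdk1:Cdc13 synthesised in proportion to mass,
Wee1/Cdc25 inhibitory-phosphorylation switch, Rum1 stoichiometric
inhibition (rapid-equilibrium trimer), Ste9- and Slp1-mediated APC/C
degradation with an intermediary-enzyme delay, and a starter kinase under
a size-dependent transcription factor. Division halves mass exactly at the
downward crossing of Cdk1:Cdc13 through the exit threshold after the
mitotic threshold has been exceeded; events are localised by bisection to
0.01 min. The thresholds (0.4 and 0.15) were placed inside the amplitude
envelope of both the rich cycle and the reduced-amplitude starved mitoses.

Starvation machinery: growth stops when the Tor2·PKA product vanishes; an
intracellular nitrogen pool (first-order depletion, refilled under rich
conditions) sustains cyclin synthesis and the size-threshold signal; the
Greatwall branch (Igo1 phosphorylation when Tor2/PKA drop) inhibits
PP2A:B55, which both removes the Wee1-dependent S/G2 plateau (accelerated
mitosis) and boosts starter-kinase action on Ste9/Rum1 (lowering the G1/S
size threshold). The meiosis couplings are exactly two: Cdk1:Cdc13
multiplicatively inhibits the Ste11 autoregulatory synthesis term, and
PheS protects Rum1 from degradation (raising the G1/S threshold and
establishing arrest). With both couplings zeroed the cell-cycle block
reproduces the uncoupled oscillation to numerical accuracy — the test
suite asserts this equivalence.

The rich-condition cycle has a period equal to the mass-doubling time
(~165 min with the default growth rate), placing the two starvation time
points used by the division-count protocols (135 and 150 min after birth)
in mid and late G2 of the first cycle. Starvation at 150 min (larger cell)
yields two divisions before G1 arrest with high Rum1; at 135 min (smaller
cell) one division, and that arrest is PheS-dependent — disabling PheS
restores the second division.

# Bifurcation toolkit

`find_steady_states()` is the brute-force oracle: damped Newton iteration
from seeded random starts in a box, deduplicated at 1e-6 and filtered at a
residual of 1e-9; the seed is the only source of randomness in the
package. `continue_branch()` is a pseudo-arclength predictor–corrector:
tangents from a bordered linear system (previous tangent as the border
row), plain Newton corrector with divergence guards, adaptive arclength
step within [1e-5, 1e-2] of the parameter range. Folds are flagged by sign
changes of the parameter component of the tangent and refined by bisection;
Hopf points by a complex pair crossing the imaginary axis away from folds.
Corrector divergence truncates a branch with a marker instead of failing.
Jacobians are central finite differences with per-component adaptive
steps. Stability calls use a margin of 1e-8 on the leading real part.

For the import-rate scan (`scan_import_rate()`), the diagram under rich
inputs shows the sequential double switch: a lower bistable window created
by Ste11 autoregulation (the intermediate state that cycles in the
integrated model), and an upper switch created by the PheS loops whose high
branch — once Mat1-Pm and Mei3 engage — extends back across the scanned
range, making Mei2 activation irreversible. Without PheS the upper switch
is lost; without Mei3 it closes within the range and becomes reversible.
The irreversibility claim is asserted within the scanned range only.

For the cell-mass diagrams (`cellmass_diagram()`), mass is the parameter
with growth frozen, the nitrogen pool and Igo1-P held at
condition-appropriate values, and PheS frozen at 0 or at the starved
plateau. The G1/S size threshold is operationalised as the lowest-mass
saddle-node of the diagram; it moves to smaller mass under starvation
without PheS and to larger mass with PheS, relative to rich conditions,
and the preMPF-dominated S/G2 branch is absent under starvation.

# Numerical choices

* Integrator: `deSolve::lsoda` on compiled right-hand sides (`src/models.c`),
  rtol 1e-8 / atol 1e-10; the pure-R right-hand sides are retained as the
  reference implementation and the test suite checks agreement.
* Input steps and division events restart the integrator; no smoothing.
* The rich resting state is found by damped Newton from a mitotic-like
  seed, with a relaxation-integration fallback; simulations default to it,
  so runs that begin rich show the resting state before any shift.
* Commitment-window location is bisection on the reversal verdict at the
  requested resolution; an unflippable bracket is reported as a degenerate
  outcome (a *mei3Δ* cell cannot commit), not an error.
* Problem sizes used throughout the tests and the acceptance script —
  600–700 min horizons, 1-min output grids, 40–60 multi-start seeds,
  ~2000-step continuations — were chosen as the smallest sizes at which the
  reported quantities are stable to further refinement.

# What the simulated conditions do and do not show

The model is deterministic and single-cell. Passing the mutant panel shows
that the wiring and calibration jointly reproduce the qualitative genetics:
it does not validate absolute timing (experimental meiotic timing varies
between two and six hours and is asynchronous), population mating
frequencies ("low frequency" is collapsed to "blocked"), or any spatial or
stochastic aspect. The pheromone pathway is a single lumped variable, so
transient pheromone adaptation dynamics are out of scope, as is multi-site
Ste11 phosphorylation detail and the transcriptional co-factor layer
(Atf1/Pcr1/Gaf1/SAGA). The cell-cycle chassis is a compact model: it is
calibrated to reproduce the division-count and size-threshold phenomena,
not to be a quantitative cell-cycle model in its own right. One reported
kinetic ordering is not reproduced: in this calibration Mei2 activation
after PKA loss alone lags Tor2 loss alone by ~18 min (the experimental
comparison has it faster), although the accompanying Ste11-level ordering
(higher Ste11 without PKA) does hold; the levers that would flip the
timing all either break the mutant panel or move the commitment window.
Similarly, in the Mei3-free import-rate diagram the Ste11-level
pheromone-loop state remains self-sustaining down to the scanned floor
rather than closing at a fold inside the range; the functional
reversibility (a Mei3-free cell never commits, and return-to-growth always
reverses) is reproduced, the fold placement of that panel is not.

# Session-free reproduction

Every figure-level experiment is a named protocol (`protocol_registry()`),
every mutant a registry row, and the acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities from scratch
with a single seed argument; see the README for how to run it.
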