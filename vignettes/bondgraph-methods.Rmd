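---
title: "Methods: energy-based modelling of reaction networks with bondgraphr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-based modelling of reaction networks with bondgraphr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondgraphr)
```

## The model

`bondgraphr` represents a biochemical network as a bond graph: a graph of
components exchanging energy through bonds, each bond carrying a chemical
potential $\mu$ (J/mol) and a molar flow $v$ (mol/s) whose product is power.
Three component kinds appear:

* **Species** store free energy.  A species with thermodynamic constant $K$
  and amount $x$ has potential $\mu = RT\log(Kx)$.  $K$ condenses the
  standard free energy of the species: $K = e^{\mu^0/RT}/(c^0 V)$, with
  reference concentration $c^0 = 1\,$M and compartment volume $V = 1\,$L by
  default, so state is stored as concentration (M) and $K$ carries
  M$^{-1}$.
* **Reactions** dissipate.  A reaction receives the forward affinity
  $A^f = \sum_{s\in S}\mu_s$ on one port and delivers the reverse affinity
  $A^r = \sum_{p\in P}\mu_p$ on the other, and its constitutive relation
  maps $(A^f, A^r)$ to a flux.
* **Junctions** conserve.  A 0-junction imposes one potential on all its
  bonds and zero net flow (mass balance); a 1-junction imposes one flow
  and zero net potential (affinity summation).

Because species own their parameters and all coupling happens through
junctions, the ODEs follow mechanically from the wiring: flattening the
module hierarchy yields the stoichiometric matrix $N$ and the flux vector
$v(x)$, and $\dot x = N v(x)$ with chemostatted rows forced to zero.
Chemostats are species clamped at fixed amounts — they model exchange with
the environment and are what make non-equilibrium steady states possible.
They are implemented by zeroing rows of $N$ rather than deleting species,
so their potentials still drive the fluxes.

### Rate laws

Three interchangeable laws are provided, all expressed through the
dimensionless quantities $e^{\mu/RT} = Kx$:

* mass action (Marcelin–de Donder):
  $v = \kappa\,(e^{A^f/RT} - e^{A^r/RT})$, which with the logarithmic
  potential reduces to ordinary reversible mass action with
  $k^+ = \kappa\prod_S K_s$, $k^- = \kappa\prod_P K_p$;
* reversible Michaelis–Menten, for one (possibly lumped) substrate and
  product:
  $v = \bar\kappa e_0\,(e^{\mu_S/RT}-e^{\mu_P/RT})
  /(1 + e^{\mu_S/RT}/R_{b0} + e^{\mu_P/RT}/R_{b1})$;
* generalised kinetics, with one binding constant per binding **site**
  (a species of stoichiometry $n$ contributes $n$ sites):
  $v = \bar\kappa e_0\,(e^{A^f/RT}-e^{A^r/RT})
  /\bigl(-1+\prod_{s\in S}(1+e^{\mu_s/RT}/R_{b,s})
  +\prod_{p\in P}(1+e^{\mu_p/RT}/R_{b,p})\bigr)$.

For one substrate and one product the generalised law is algebraically
identical to the Michaelis–Menten law, and for unit stoichiometries it is
convenience kinetics.  Every law vanishes exactly at $A^f = A^r$ and
satisfies $(A^f - A^r)\,v \ge 0$, so dissipation is non-negative at every
state — models assembled from these laws cannot violate the second law
regardless of parameter values.

### Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| temperature $T$ | K | 310.15 | physiological; $RT \approx 2.58$ kJ/mol |
| $K$ per species | M$^{-1}$ | — | standard free energy in disguise |
| $\kappa$, $\bar\kappa$ | M/s, 1/s | — | kinetic scale, thermodynamics-free |
| $R_{b,z}$ | — | — | binding saturation; $e^{\mu_z/RT}/R_{b,z} = 1$ at half-saturation |
| $e_0$ | M | — | enzyme total; 0 switches an enzyme off |
| solver rtol/atol | — | $10^{-8}$/$10^{-12}$ | nM-scale enzyme systems are stiff |
| steady-state residual | 1/s, relative | $10^{-9}$ | $\max_s |\dot x_s|/\max(x_s,10^{-12})$ |
| detailed-balance tolerance | relative | $10^{-6}$ | cycle equilibrium products in `kinetic_to_thermo()` |

## Composition, flattening and exact structure

Modules are plain values addressed by dot-paths
(`"cascade.L2.kinase:E"`); instantiation copies deeply, so no two
instances can alias.  Positive flux runs from a bond's tail to its head,
and reactions consume through their `f` port and produce through `r`.
During stoichiometry extraction, chains of 0-junctions (and of
1-junctions) are contracted; each contracted potential group must contain
exactly one species, and a species connected to a reaction side through
$k$ parallel bonds enters with stoichiometry $k$.  Degree-2 junctions are
legal and act as pass-throughs.

Conserved moieties (left null space of the internal $N$) and steady-state
pathway vectors (right null space) are computed by Gauss–Jordan
elimination over exact rationals and scaled to minimal integer vectors
with the first nonzero entry positive, in declaration order.  This keeps
pathway weights and moiety totals free of floating-point rank decisions.
The inverse parameter map `kinetic_to_thermo()` solves the log-linear
system $\log(k^+/k^-) = -(N^T\log K)$ by least squares after rejecting
detailed-balance (Wegscheider) violations — any cycle whose
equilibrium-constant product deviates from 1 by more than the tolerance
is reported with its mismatch ratio.  The solution's gauge freedoms (one
per conserved moiety) are fixed by pinning an automatically chosen
spanning set of species at $K = 1$, overridable with explicit pins.

## Simulation and the perturbation protocol

Integration uses `deSolve::lsoda`.  Steady states come from
horizon-growing integration plus a damped Newton polish; because the
Jacobian is singular along moiety directions, the Newton step uses an
SVD pseudo-inverse and each iterate is re-projected onto the conserved
totals of the starting state.

Perturbation experiments scale one species by a factor (default 1.3,
i.e. +30%) away from a reference steady state.  The deviation series is
the Euclidean norm over the internal species, $d(t) = \sqrt{\sum_{s\in
S_i}(x_s(t)-x_{s,ss})^2}$, and the **response time** is the *last* time at
which $d$ is at or above 5% of its maximum, linearly interpolated between
samples — "return to within 5%" is read as a permanent return, so
non-monotone deviations count their final excursion.  The maximum is taken
over the whole simulated horizon including $t=0$, since for single-species
perturbations the peak need not sit at the start.  Horizons grow by
factors of 4 until the deviation has decayed below 1% of its maximum
(cap $10^7$ s, recorded in the result).  The criterion is invariant under
scaling of $d$.  Chemostat perturbations are held, so the system moves to
a new steady state; deviations are then measured from that new state and
the steady-state shift is reported separately.

## The MAPK cascade generators

Kinases use the two-state mechanism
$E + X + \mathrm{ATP} \rightleftharpoons C \rightleftharpoons
E + XP + \mathrm{ADP}$ and phosphatases
$E + XP \rightleftharpoons C \rightleftharpoons E + X + \mathrm{Pi}$,
composed into a phosphorylation-cycle template whose X/XP sides share
mass-conservation junctions.  Five cycle instances form the cascade;
double phosphorylation is distributive (two cycles sharing one kinase),
and each level's kinase is the fully phosphorylated substrate of the
level above.  ATP, ADP and Pi are shared through one global chemostatted
junction each — per-level cofactor pools would add states without
changing the steady-state structure.

Rate parameters follow the classic Huang–Ferrell regime (association
$10^9\,$M$^{-1}$s$^{-1}$, dissociation and catalysis $150\,$s$^{-1}$,
so $K_m = 0.3\,\mu$M for every enzymatic step); substrate totals come
from the standard simulation conditions (3 nM MAP3K, 1.2 μM MAP2K and
MAPK, 0.3/0.3 nM and 0.12 μM phosphatases, 0.03 nM input).  The
thermodynamic constants place $RT\log 10^8 \approx 47$ kJ/mol on ATP
hydrolysis at 1 mM cofactor clamps, split $10^4$:$10^4$ between the
kinase and phosphatase legs; every reverse rate constant then follows
from detailed balance instead of being set to zero.  "Reduced (80%) ATP
energy" is interpreted as scaling the clamped hydrolysis affinity **to**
80% of nominal (not by 80%), implemented by moving the ATP chemostat
concentration; a fraction of 0 produces a genuinely equilibrium model
whose only steady states are zero-dissipation equilibria.

Feedback rewires nothing inside the cascade: a sixth cycle instance
converts MAP4K to/from an inactive form MAP4KI with the output MAPKPP as
its kinase.  Which of the cycle's X/XP ports the active MAP4K occupies
decides the sign of the loop (positive: MAP4K is the phosphorylated
form).  The feedback cycle's rate parameters are copies of the level-1
cycle's; its phosphatase concentration is a package default of 3 nM,
chosen (once) because the deactivating leg must be strong enough to hold
the inactive branch down over an appreciable input range — with it, the
two-direction sweep shows a wide hysteresis window, the upper branch
tracking the no-feedback curve.  Both choices are overridable through
`mapk_params_default()`.

## The glycolysis generators and their calibration

The network table in `glycolysis_network()` is the single source of truth
for stoichiometry: eleven enzymes including the gluconeogenic fbp and pps
(the two futile-cycle partners), ten chemostats, eight internal species.
pps carries a stoichiometry-2 proton site, exercising the per-site
binding constants of the generalised law.

The source parameterisation of this pathway is not available as data, so
the package ships a **synthetic** parameter set,
`glycolysis_params_synthetic()`, constructed backwards from published
summary quantities: boundary potentials are fixed at plausible values
(45 kJ/mol ATP hydrolysis affinity; water, protons and redox couples at
reference), the nine per-reaction affinities of the reference free-energy
distribution are solved exactly for the internal potentials, species
constants follow from literature-scale metabolite concentrations, the
steady flux is the pathway vector times $v_0 = 10^{-4}\,$M/s (about
6 mM/min, an upper-physiological glycolytic flux that keeps relaxation
times convenient), binding constants sit at half-saturation at the
reference state, and $e_0 = 1\,\mu$M with fbp/pps at $e_0 = 0$.  By
construction the generalised-kinetics model then has an exactly known
steady state whose affinity distribution matches the reference table —
which means tests against that table validate the machinery (steady-state
solving, affinity computation, the two independent pathway-total
computations agreeing to $10^{-9}$ relative), **not** an independent
prediction of the real pathway's energetics.

Mass-action calibration sets each $\kappa_j$ so the flux matches the
reference flux at the reference state; since the $K$'s are shared,
equilibrium constants are untouched and the reference state remains a
steady state.  Michaelis–Menten calibration additionally matches
$\partial v/\partial x$ for one internal substrate and one internal
product, which determines $(\bar\kappa, R_{b0}, R_{b1})$ in closed form;
a side with no internal species keeps its half-saturating constant, and
fba — two internal products feeding one lumped denominator term — is
matched in flux and flagged (`"flux+partial"`).  For a true
one-substrate/one-product reaction this calibration recovers the
generalised-kinetics parameters exactly.  Chemostatted co-substrates are
lumped into the substrate/product exponentials automatically, because
fluxes are evaluated as products of $K_s x_s$ and clamped factors are
constants.

## What the fixture generator emulates — and what it does not

`generate_fixture()` draws chain, ring or random mass-action networks
with log-uniform $K$ and $\kappa$ over $10^{\pm 2}$, parameterised in
thermodynamic space and therefore consistent by construction (every cycle's
equilibrium product is exactly 1); the same seed reproduces the same
serialised document byte for byte.  These fixtures exercise composition,
equation assembly, conversion and simulation code on arbitrary topologies.
They do **not** emulate saturating enzymes, realistic concentration
scales, conserved enzyme totals or regulatory structure — so tests passing
on fixtures demonstrate structural and thermodynamic correctness of the
machinery, not biological fidelity of any particular model.

## Numerical choices

* Fluxes are evaluated in amount space, as products of $K_s x_s$, never
  through logarithms: $x = 0$ is a regular point (mass-action right-hand
  sides are polynomial in $x$) and moderate states cannot overflow the
  exponential form.
* Affinities are reported in kJ/mol where human-facing, J/mol internally.
* Pathway/moiety normalisation tie-breaks: reaction and species
  declaration order, first nonzero entry positive, minimal integers.
* The $x_s = 1/K_s$ equilibrium of a closed model is an exact fixed point
  of the flux form; in floating point $K\,(1/K)$ can differ from 1 by one
  ulp, so tests bound these residuals at $\sim 10^{-14}$ of the kinetic
  scale rather than asserting literal zeros.
* Problem sizes in the shipped tests were chosen to make the whole suite
  run in about a minute: 8-point input grids for cascade response curves,
  50 random fixtures for the formulation-equivalence sweep, 1000 random
  states per model for dissipation positivity.

## Known limitations

Allosteric regulation is not represented (enzyme totals $e_0$ can be
varied to imitate its effects); there is no SBML/CellML import/export;
modelling is deterministic and continuous (no stochastic or discrete
variants); only biochemical bond-graph elements exist (no transformers,
gyrators or multi-physics domains); and the Michaelis–Menten law applies
to a reaction only through the lumped substrate/product exponentials.
The MAPK and glycolysis parameter sets are package defaults constructed
as described above — faithful in mechanism and regime, but not fitted to
any particular dataset.
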